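#' Nearest-neighbor energy parameters for intermolecular duplex scoring
#'
#' Holds the stacking free energies and affine loop penalties used by
#' [duplex_mfe()]. Stack energies are keyed `"ab/cd"`: top strand
#' (transcript) 5'-`a` `b`-3' over bottom strand (miR) 3'-`c` `d`-5', with
#' pairs `a:c` and `b:d`. Canonical stack energies must be <= 0 and
#' penalties >= 0 (physical parameter sets satisfy both).
#'
#' @param stack_table Named numeric vector of stack free energies
#'   (kcal/mol), names like `"GC/CG"`.
#' @param init_penalty Duplex initiation penalty (kcal/mol, >= 0).
#' @param bulge_open,bulge_extend Affine penalty for a bulge of length L:
#'   `bulge_open + bulge_extend * (L - 1)`.
#' @param internal_open,internal_extend Affine penalty for an internal
#'   loop with `a`, `b` unpaired bases on the two strands:
#'   `internal_open + internal_extend * (a + b - 2)`.
#' @param allow_gu Allow G:U wobble pairs. Only meaningful when the stack
#'   table carries wobble entries; the shipped default table is
#'   Watson-Crick only.
#' @param max_loop Maximum unpaired stretch on either strand between
#'   consecutive pairs (0 forbids all loops and bulges).
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(stack_table, init_penalty = 0,
                          bulge_open = 3.8, bulge_extend = 0.5,
                          internal_open = 2.0, internal_extend = 0.4,
                          allow_gu = FALSE, max_loop = 15L) {
  if (is.null(names(stack_table)) || any(!grepl("^[ACGU]{2}/[ACGU]{2}$",
                                                names(stack_table))))
    stop("stack_table must be named like 'AB/CD' over ACGU")
  if (any(!is.finite(stack_table))) stop("stack energies must be finite")
  pen <- c(init_penalty, bulge_open, bulge_extend, internal_open,
           internal_extend)
  if (any(pen < 0)) stop("penalties must be >= 0")
  if (max_loop < 0) stop("max_loop must be >= 0")
  structure(list(stack_table = stack_table,
                 init_penalty = init_penalty, bulge_open = bulge_open,
                 bulge_extend = bulge_extend, internal_open = internal_open,
                 internal_extend = internal_extend,
                 allow_gu = isTRUE(allow_gu),
                 max_loop = as.integer(max_loop)),
            class = "energy_params")
}

#' Read energy parameters from a TSV file
#'
#' The file has three tab-separated columns `param`, `key`, `value`.
#' Rows with `param == "stack"` carry a stack key (e.g. `GC/CG`) and its
#' free energy; the remaining rows set `init_penalty`, `bulge_open`,
#' `bulge_extend`, `internal_open`, `internal_extend`, `allow_gu` (0/1)
#' and `max_loop` (key column empty).
#'
#' @param path Parameter file path.
#' @return An `energy_params` object.
#' @export
read_energy_params <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("param", "key", "value") %in% names(df)))
    stop("parameter file must have columns param, key, value")
  st <- df[df$param == "stack", ]
  stacks <- stats::setNames(as.numeric(st$value), st$key)
  get1 <- function(name, default) {
    v <- df$value[df$param == name]
    if (length(v) == 0L) default else as.numeric(v[1L])
  }
  energy_params(stacks,
                init_penalty = get1("init_penalty", 0),
                bulge_open = get1("bulge_open", 3.8),
                bulge_extend = get1("bulge_extend", 0.5),
                internal_open = get1("internal_open", 2.0),
                internal_extend = get1("internal_extend", 0.4),
                allow_gu = get1("allow_gu", 0) != 0,
                max_loop = as.integer(get1("max_loop", 15)))
}

#' Default duplex energy parameters
#'
#' Reads the parameter file shipped with the package: Watson-Crick
#' nearest-neighbor stacking free energies at 37 C (Xia et al. 1998 /
#' Turner rules) with the +4.09 kcal/mol duplex initiation term, and
#' affine loop penalties. G:U wobble is disabled (no wobble stack entries
#' are shipped).
#'
#' @return An `energy_params` object.
#' @export
default_energy_params <- function() {
  read_energy_params(system.file("extdata", "wc_stack_params.tsv",
                                 package = "mirtf", mustWork = TRUE))
}

#' Toy energy parameters for exact-value tests and examples
#'
#' Every canonical (and, if `allow_gu`, wobble) stack gets the same energy
#' `stack_energy`; initiation defaults to 0 and `max_loop = 0` forbids all
#' loops, so a perfect antiparallel complement of length L scores
#' `-(L - 1) * |stack_energy|`. Pass a positive `max_loop` together with
#' the loop penalties to exercise bulges and internal loops with
#' transparent arithmetic.
#'
#' @inheritParams energy_params
#' @param stack_energy Energy of every stack (kcal/mol, <= 0).
#' @return An `energy_params` object.
#' @export
toy_energy_params <- function(stack_energy = -1, init_penalty = 0,
                              bulge_open = 2, bulge_extend = 1,
                              internal_open = 2, internal_extend = 1,
                              allow_gu = FALSE, max_loop = 0L) {
  bases <- c("A", "C", "G", "U")
  comp <- list(A = "U", C = "G", G = "C", U = "A")
  if (allow_gu) {
    comp$G <- c("C", "U")
    comp$U <- c("A", "G")
  }
  keys <- character(0)
  for (a in bases) for (b in bases) for (cc in comp[[a]])
    for (d in comp[[b]]) keys <- c(keys, paste0(a, b, "/", cc, d))
  energy_params(stats::setNames(rep(stack_energy, length(keys)), keys),
                init_penalty = init_penalty, bulge_open = bulge_open,
                bulge_extend = bulge_extend, internal_open = internal_open,
                internal_extend = internal_extend, allow_gu = allow_gu,
                max_loop = max_loop)
}

# Base encoding shared with the C++ kernel: A=0, C=1, G=2, U=3.
encode_bases <- function(bases) {
  match(strsplit(bases, "")[[1]], c("A", "C", "G", "U")) - 1L
}

# 4x4 logical pairing matrix [transcript base, mir base].
pairing_matrix <- function(allow_gu) {
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                           c("A", "C", "G", "U")))
  m["A", "U"] <- m["U", "A"] <- m["C", "G"] <- m["G", "C"] <- TRUE
  if (allow_gu) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

# Flatten the stack table into the length-256 lookup the kernel indexes by
# a*64 + b*16 + c*4 + d (key "ab/cd"); missing entries become +1e9.
stack_lookup <- function(params) {
  lut <- rep(1e9, 256)
  keys <- names(params$stack_table)
  a <- match(substr(keys, 1, 1), c("A", "C", "G", "U")) - 1L
  b <- match(substr(keys, 2, 2), c("A", "C", "G", "U")) - 1L
  cc <- match(substr(keys, 4, 4), c("A", "C", "G", "U")) - 1L
  d <- match(substr(keys, 5, 5), c("A", "C", "G", "U")) - 1L
  lut[a * 64L + b * 16L + cc * 4L + d + 1L] <- params$stack_table
  lut
}
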