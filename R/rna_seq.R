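#' Construct an RNA sequence record
#'
#' Bases are uppercased and DNA-style `T` is mapped to `U`; anything
#' outside `{A, C, G, U}` is an error. A miR whose length falls outside the
#' usual mature-miR range of 18-26 nt triggers a warning, not an error.
#'
#' @param name Sequence name.
#' @param bases Character string of bases.
#' @param role `"transcript"` or `"mir"`.
#' @return A list of class `rna_seq` with fields `name`, `bases`, `role`.
#' @export
rna_sequence <- function(name, bases, role = c("transcript", "mir")) {
  role <- match.arg(role)
  bases <- chartr("acgutT", "ACGUUU", as.character(bases))
  bases <- gsub("T", "U", toupper(bases), fixed = TRUE)
  if (nchar(bases) < 1L) stop("sequence must have length >= 1")
  if (grepl("[^ACGU]", bases))
    stop("sequence '", name, "' contains non-ACGU characters")
  if (role == "mir" && (nchar(bases) < 18L || nchar(bases) > 26L))
    warning("miR '", name, "' length ", nchar(bases),
            " outside the usual 18-26 nt range")
  structure(list(name = as.character(name), bases = bases, role = role),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("rna_seq [%s] %s (%d nt)\n", x$role, x$name, nchar(x$bases)))
  invisible(x)
}

#' Read RNA sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param role Role to assign each sequence (`"transcript"` or `"mir"`).
#' @return A list of `rna_seq` objects.
#' @export
read_rna_fasta <- function(path, role = c("transcript", "mir")) {
  role <- match.arg(role)
  ss <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    rna_sequence(names(ss)[i], as.character(ss[[i]]), role))
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs A list of `rna_seq` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
  ss <- Biostrings::RNAStringSet(vapply(seqs, `[[`, character(1), "bases"))
  names(ss) <- vapply(seqs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Reverse complement of an RNA string (plain character in/out).
rna_revcomp <- function(bases) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", bases), "")[[1]]),
        collapse = "")
}
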