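#' Find candidate miR binding windows by seed complementarity
#'
#' Scans the transcript for sites exactly antiparallel-complementary to the
#' miR seed (positions 2-7 from the miR 5' end by default, extendable to
#' 2-8). Each seed match is extended to a window that can accommodate the
#' full miR plus a bulge margin on both sides; the rest of the miR pairs
#' 5' of the seed match on the transcript (antiparallel geometry), so the
#' window reaches `length(miR) - seed_end` bases upstream and covers miR
#' position 1 downstream.
#'
#' @param transcript,mir `rna_seq` objects; the transcript must be longer
#'   than the miR.
#' @param seed_span Integer pair, 1-based positions of the seed on the miR
#'   (default `c(2, 7)`).
#' @param allow_gu_in_seed Accept G:U wobble complements inside the seed
#'   (default `FALSE`).
#' @param margin Extra bases on each side of the minimal window to leave
#'   room for bulges (default 4).
#' @return A `data.frame` with columns `start`, `end` (candidate window,
#'   0-based half-open on the transcript) and `seed_start` (0-based
#'   position of the seed match), ordered 5' to 3'. Zero rows when no seed
#'   matches.
#' @export
seed_sites <- function(transcript, mir, seed_span = c(2L, 7L),
                       allow_gu_in_seed = FALSE, margin = 4L) {
  stopifnot(inherits(transcript, "rna_seq"), inherits(mir, "rna_seq"))
  L <- nchar(transcript$bases)
  m <- nchar(mir$bases)
  if (L <= m) stop("transcript must be longer than the miR")
  if (seed_span[1] < 1L || seed_span[2] > m || seed_span[1] >= seed_span[2])
    stop("invalid seed span")
  seed <- substr(mir$bases, seed_span[1], seed_span[2])
  # site read 5'->3' on the transcript = reverse complement of the seed;
  # with wobble, each miR base maps to a character class
  comp_class <- c(A = "U", C = "G", G = if (allow_gu_in_seed) "[CU]" else "C",
                  U = if (allow_gu_in_seed) "[AG]" else "A")
  rev_seed <- rev(strsplit(seed, "")[[1]])
  pattern <- paste(comp_class[rev_seed], collapse = "")
  slen <- seed_span[2] - seed_span[1] + 1L
  # scan for (possibly overlapping) matches
  starts <- integer(0)
  pos <- 1L
  repeat {
    h <- regexpr(pattern, substr(transcript$bases, pos, L), perl = TRUE)
    if (h == -1L) break
    starts <- c(starts, pos + as.integer(h) - 1L)
    pos <- pos + as.integer(h)
  }
  s <- starts  # 1-based seed-match starts
  # transcript site pairs miR seed_span[2]..seed_span[1] antiparallel;
  # miR bases 3' of the seed pair upstream, bases 1..seed_span[1]-1 pair
  # downstream of the match
  wstart <- pmax(1L, s - (m - seed_span[2]) - margin)
  wend <- pmin(L, s + slen - 1L + (seed_span[1] - 1L) + margin)
  data.frame(start = wstart - 1L, end = as.integer(wend),
             seed_start = s - 1L)
}

#' Minimum-free-energy intermolecular duplex between a window and a miR
#'
#' Computes the optimal miR:mRNA heteroduplex over all non-crossing
#' antiparallel intermolecular pairings: initiation penalty plus
#' nearest-neighbor stack energies for adjacent pairs plus affine
#' bulge/internal-loop penalties for unpaired stretches (capped at
#' `params$max_loop` per strand). No intramolecular structure is
#' considered. The empty pairing (energy 0) is always admissible, so
#' `delta_g <= 0` whenever `init_penalty = 0`. Ties prefer the pairing
#' with more paired bases, then the 5'-most chain on the transcript.
#'
#' @param window `rna_seq` transcript window (length <= `max_window`).
#' @param mir `rna_seq` miR.
#' @param params An [energy_params()] object.
#' @param max_window Maximum admissible window length (default 40).
#' @return A list of class `duplex_hit`: `transcript_window` (0-based
#'   half-open, relative to the supplied window), `pairs` (data.frame of
#'   1-based `t` window positions and `m` miR positions), `delta_g`
#'   (kcal/mol) and `energy_released` (`max(0, -delta_g)`).
#' @export
duplex_mfe <- function(window, mir, params, max_window = 40L) {
  stopifnot(inherits(window, "rna_seq"), inherits(mir, "rna_seq"),
            inherits(params, "energy_params"))
  n <- nchar(window$bases)
  m <- nchar(mir$bases)
  if (n > max_window)
    stop("window length ", n, " exceeds the maximum of ", max_window)
  x <- encode_bases(window$bases)
  r <- rev(encode_bases(mir$bases))
  res <- duplex_mfe_cpp(x, r, stack_lookup(params),
                        as.vector(t(pairing_matrix(params$allow_gu))),
                        params$init_penalty, params$bulge_open,
                        params$bulge_extend, params$internal_open,
                        params$internal_extend, params$max_loop)
  pairs <- data.frame(t = res$pairs_i, m = m + 1L - res$pairs_k)
  structure(list(transcript_window = c(0L, n), pairs = pairs,
                 delta_g = res$dg,
                 energy_released = max(0, -res$dg)),
            class = "duplex_hit")
}

#' Best miR binding site on a transcript
#'
#' Evaluates [duplex_mfe()] on every [seed_sites()] candidate window and
#' returns the hit with the lowest duplex free energy; ties go to the
#' 5'-most window. Returns `NULL` when the transcript has no seed match.
#'
#' @inheritParams seed_sites
#' @inheritParams duplex_mfe
#' @return A `duplex_hit` with `transcript_window` in transcript
#'   coordinates (0-based half-open) and `pairs$t` as 1-based transcript
#'   positions, or `NULL`.
#' @export
best_site <- function(transcript, mir, params, seed_span = c(2L, 7L),
                      allow_gu_in_seed = FALSE, margin = 4L,
                      max_window = 40L) {
  cand <- seed_sites(transcript, mir, seed_span, allow_gu_in_seed, margin)
  if (nrow(cand) == 0L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    win <- rna_sequence(
      paste0(transcript$name, ":", cand$start[i], "-", cand$end[i]),
      substr(transcript$bases, cand$start[i] + 1L, cand$end[i]),
      role = "transcript")
    hit <- duplex_mfe(win, mir, params, max_window = max_window)
    hit$transcript_window <- c(cand$start[i], cand$end[i])
    hit$pairs$t <- hit$pairs$t + cand$start[i]
    hit$mir <- mir$name
    if (is.null(best) || hit$delta_g < best$delta_g - 1e-9) best <- hit
  }
  best
}

#' Dot-bracket duplex notation for a hit
#'
#' Renders a `duplex_hit` as RNAduplex-style notation: the transcript
#' window 5'->3' with `(` at paired positions, an `&`, then the miR
#' 5'->3' with `)` at paired positions.
#'
#' @param hit A `duplex_hit`.
#' @param mir_length Length of the miR the hit was scored against.
#' @return A single string, e.g. `"((((....&))))"`.
#' @export
duplex_notation <- function(hit, mir_length) {
  stopifnot(inherits(hit, "duplex_hit"))
  wlen <- hit$transcript_window[2] - hit$transcript_window[1]
  s1 <- rep(".", wlen)
  s1[hit$pairs$t - hit$transcript_window[1]] <- "("
  s2 <- rep(".", mir_length)
  s2[hit$pairs$m] <- ")"
  paste0(paste(s1, collapse = ""), "&", paste(s2, collapse = ""))
}

#' Total sponge score of a transcript against a miR panel
#'
#' Sums the energy released (`-delta_g`, clipped at 0) of the best site of
#' each miR; a miR without a seed match contributes 0. With
#' `both_orientations = TRUE` the reverse complement of each miR is scored
#' as an additional entry (suffix `_AS`), covering antisense miR forms.
#'
#' @inheritParams best_site
#' @param mirs List of `rna_seq` miRs (non-empty).
#' @param per_mir Return the per-miR table instead of the total.
#' @param both_orientations Also score each miR's reverse complement.
#' @return Total energy released (numeric), or with `per_mir = TRUE` a
#'   `data.frame` with columns `mir`, `window_start`, `window_end`,
#'   `delta_g`, `energy_released`.
#' @export
sponge_score <- function(transcript, mirs, params, per_mir = FALSE,
                         both_orientations = FALSE, seed_span = c(2L, 7L),
                         allow_gu_in_seed = FALSE, margin = 4L,
                         max_window = 40L) {
  if (length(mirs) == 0L) stop("mirs must be non-empty")
  if (both_orientations) {
    as_mirs <- lapply(mirs, function(m) {
      out <- m
      out$name <- paste0(m$name, "_AS")
      out$bases <- rna_revcomp(m$bases)
      out
    })
    mirs <- c(mirs, as_mirs)
  }
  rows <- lapply(mirs, function(m) {
    hit <- best_site(transcript, m, params, seed_span, allow_gu_in_seed,
                     margin, max_window)
    if (is.null(hit)) {
      data.frame(mir = m$name, window_start = NA_integer_,
                 window_end = NA_integer_, delta_g = NA_real_,
                 energy_released = 0, structure = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mir = m$name, window_start = hit$transcript_window[1],
                 window_end = hit$transcript_window[2],
                 delta_g = hit$delta_g,
                 energy_released = hit$energy_released,
                 structure = duplex_notation(hit, nchar(m$bases)),
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (per_mir) tab else sum(tab$energy_released)
}

#' Shuffle a sequence preserving exact base composition
#'
#' Uniform random permutation of the base multiset (Fisher-Yates via
#' [sample()]); mononucleotide counts are preserved exactly and the result
#' is reproducible under a fixed seed. The caller's RNG state is left
#' untouched.
#'
#' @param seq An `rna_seq`.
#' @param seed Integer RNG seed.
#' @return An `rna_seq` with the same name, role and composition.
#' @export
shuffle_composition <- function(seq, seed) {
  stopifnot(inherits(seq, "rna_seq"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ch <- strsplit(seq$bases, "")[[1]]
  out <- seq
  out$bases <- paste(ch[sample.int(length(ch))], collapse = "")
  out
}

#' Shuffle a sequence preserving dinucleotide composition
#'
#' Altschul-Erickson shuffle: a uniform random Eulerian-path rearrangement
#' of the dinucleotide multigraph, preserving all dinucleotide (and hence
#' mononucleotide) counts and the first and last base. A stricter null
#' than [shuffle_composition()] for sequences with local composition
#' structure.
#'
#' @inheritParams shuffle_composition
#' @return An `rna_seq` with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(seq, seed) {
  stopifnot(inherits(seq, "rna_seq"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ch <- strsplit(seq$bases, "")[[1]]
  n <- length(ch)
  if (n <= 3L) return(seq)
  bases <- c("A", "C", "G", "U")
  v <- match(ch, bases)
  # edge lists: for each source base, the ordered targets
  edges <- lapply(1:4, function(b) v[which(v[-n] == b) + 1L])
  last <- v[n]
  present <- sort(unique(v))
  # choose a final edge per non-terminal vertex so final edges form a
  # tree into `last` (rejection sampling; <= 4 vertices, fast)
  repeat {
    final <- rep(NA_integer_, 4)
    ok <- TRUE
    for (b in present) {
      if (b == last) next
      if (length(edges[[b]]) == 0L) { ok <- FALSE; break }
      final[b] <- edges[[b]][sample.int(length(edges[[b]]), 1L)]
    }
    if (!ok) break
    reaches <- function(b) {
      seen <- integer(0)
      while (!is.na(b) && b != last && !(b %in% seen)) {
        seen <- c(seen, b)
        b <- final[b]
      }
      identical(b, last)
    }
    if (all(vapply(setdiff(present, last), reaches, logical(1)))) break
  }
  # permute the remaining edges of each vertex, final edge goes last
  for (b in present) {
    e <- edges[[b]]
    if (!is.na(final[b])) {
      drop <- which(e == final[b])[1L]
      e <- e[-drop]
    }
    e <- e[sample.int(max(length(e), 0L))]
    if (!is.na(final[b])) e <- c(e, final[b])
    edges[[b]] <- e
  }
  # walk the Eulerian path from the first base
  outp <- integer(n)
  outp[1] <- v[1]
  ptr <- rep(1L, 4)
  for (i in 2:n) {
    b <- outp[i - 1L]
    outp[i] <- edges[[b]][ptr[b]]
    ptr[b] <- ptr[b] + 1L
  }
  out <- seq
  out$bases <- paste(bases[outp], collapse = "")
  out
}

#' Sponge-out simulation against a composition-matched shuffle null
#'
#' Scores the total duplex energy released by a transcript (and,
#' optionally, its 3'UTR slice) for a miR panel, and compares it with the
#' scores of `n_shuffles` base-composition-matched random sequences of the
#' same region. The 3'UTR is scored separately because miRs
#' preferentially bind 3'UTR sequence. Empirical p uses the add-one rule
#' `(1 + #{null >= true}) / (1 + n_shuffles)`; the z-score is
#' `(true - mean(null)) / sd(null)`.
#'
#' @inheritParams sponge_score
#' @param utr3 `NULL`, or an integer pair (1-based inclusive) delimiting
#'   the 3'UTR on the transcript.
#' @param n_shuffles Number of shuffled null sequences per region
#'   (>= 10; default 100).
#' @param seed Integer seed controlling all shuffles.
#' @param shuffle `"mono"` (composition-matched, default) or `"dinuc"`
#'   (dinucleotide-preserving, stricter).
#' @return A named list (`full`, and `utr3` when given) of
#'   `sponge_null_result` objects: `region`, `true_score`, `null_scores`,
#'   `empirical_p`, `z_score`, `n_shuffles`, `seed`.
#' @export
run_sponge_null <- function(transcript, utr3 = NULL, mirs, params,
                            n_shuffles = 100L, seed = 1L,
                            shuffle = c("mono", "dinuc"),
                            both_orientations = FALSE,
                            seed_span = c(2L, 7L),
                            allow_gu_in_seed = FALSE, margin = 4L,
                            max_window = 40L) {
  shuffle <- match.arg(shuffle)
  if (n_shuffles < 10L) stop("n_shuffles must be at least 10")
  L <- nchar(transcript$bases)
  regions <- list(full = transcript)
  if (!is.null(utr3)) {
    if (length(utr3) != 2L || utr3[1] < 1L || utr3[2] > L ||
        utr3[1] > utr3[2])
      stop("utr3 must be a valid 1-based sub-interval of the transcript")
    utr_seq <- rna_sequence(paste0(transcript$name, "_3utr"),
                            substr(transcript$bases, utr3[1], utr3[2]),
                            role = "transcript")
    regions$utr3 <- utr_seq
  }
  shuf_fun <- if (shuffle == "mono") shuffle_composition else
    shuffle_dinucleotide
  score1 <- function(tx) sponge_score(
    tx, mirs, params, both_orientations = both_orientations,
    seed_span = seed_span, allow_gu_in_seed = allow_gu_in_seed,
    margin = margin, max_window = max_window)
  out <- list()
  for (ri in seq_along(regions)) {
    region <- names(regions)[ri]
    tx <- regions[[ri]]
    true_score <- score1(tx)
    null_scores <- vapply(seq_len(n_shuffles), function(s)
      score1(shuf_fun(tx, seed + 7919L * ri + s)), numeric(1))
    sdn <- stats::sd(null_scores)
    z <- if (sdn > 0) (true_score - mean(null_scores)) / sdn else
      if (true_score == mean(null_scores)) 0 else
        sign(true_score - mean(null_scores)) * Inf
    out[[region]] <- structure(
      list(region = region, true_score = true_score,
           null_scores = null_scores,
           empirical_p = (1 + sum(null_scores >= true_score)) /
             (1 + n_shuffles),
           z_score = z, n_shuffles = as.integer(n_shuffles),
           seed = as.integer(seed)),
      class = "sponge_null_result")
  }
  out
}

#' @export
print.sponge_null_result <- function(x, ...) {
  cat(sprintf(
    "sponge null [%s]: true %.2f, null %.2f +/- %.2f (n=%d), p = %.4g\n",
    x$region, x$true_score, mean(x$null_scores),
    stats::sd(x$null_scores), x$n_shuffles, x$empirical_p))
  invisible(x)
}
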