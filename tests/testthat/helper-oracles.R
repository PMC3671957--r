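# Independent brute-force oracles used by the test suite. These must not
# call the implementation paths they check.

# All-pairs interval intersection: promoter i gets cluster j iff same
# chromosome and the half-open intervals share >= min_overlap bases.
oracle_intersect <- function(promoters, clusters, min_overlap = 1L) {
  out <- stats::setNames(rep(list(integer(0)), nrow(promoters)),
                         promoters$promoter_id)
  for (i in seq_len(nrow(promoters))) {
    ov <- pmin(promoters$end[i], clusters$end) -
      pmax(promoters$start[i], clusters$start)
    out[[i]] <- which(clusters$chrom == promoters$chrom[i] &
                        ov >= min_overlap)
  }
  out
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe whose first K items are marked.
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(if (k <= 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Energy of one explicit pairing under the duplex cost model; pairs is a
# 2-column matrix of (i, k) indices into x and rev(mir), both strictly
# increasing. Returns Inf when the pairing is inadmissible.
oracle_pairing_energy <- function(pairs, xc, rc, params) {
  bases <- c("A", "C", "G", "U")
  can_pair <- function(a, b) {
    (bases[a + 1] == "A" && bases[b + 1] == "U") ||
      (bases[a + 1] == "U" && bases[b + 1] == "A") ||
      (bases[a + 1] == "C" && bases[b + 1] == "G") ||
      (bases[a + 1] == "G" && bases[b + 1] == "C") ||
      (params$allow_gu &&
         ((bases[a + 1] == "G" && bases[b + 1] == "U") ||
            (bases[a + 1] == "U" && bases[b + 1] == "G")))
  }
  if (nrow(pairs) == 0L) return(0)
  for (t in seq_len(nrow(pairs)))
    if (!can_pair(xc[pairs[t, 1]], rc[pairs[t, 2]])) return(Inf)
  e <- params$init_penalty
  if (nrow(pairs) > 1L) {
    for (t in seq_len(nrow(pairs) - 1L)) {
      a <- pairs[t + 1L, 1] - pairs[t, 1] - 1L
      b <- pairs[t + 1L, 2] - pairs[t, 2] - 1L
      if (a == 0L && b == 0L) {
        key <- paste0(bases[xc[pairs[t, 1]] + 1], bases[xc[pairs[t + 1L, 1]] + 1],
                      "/", bases[rc[pairs[t, 2]] + 1], bases[rc[pairs[t + 1L, 2]] + 1])
        s <- unname(params$stack_table[key])
        if (is.na(s)) return(Inf)
        e <- e + s
      } else {
        if (a > params$max_loop || b > params$max_loop) return(Inf)
        e <- e + if (a == 0L || b == 0L)
          params$bulge_open + params$bulge_extend * (a + b - 1L) else
            params$internal_open + params$internal_extend * (a + b - 2L)
      }
    }
  }
  e
}

# Exhaustive duplex MFE: enumerate every chain of pairs strictly
# increasing in both coordinates (feasible for lengths <= 8-9).
oracle_duplex_mfe <- function(window, mir, params) {
  xc <- match(strsplit(window, "")[[1]], c("A", "C", "G", "U")) - 1L
  rc <- rev(match(strsplit(mir, "")[[1]], c("A", "C", "G", "U")) - 1L)
  n <- length(xc); m <- length(rc)
  best <- 0  # empty pairing
  extend <- function(chain) {
    e <- oracle_pairing_energy(chain, xc, rc, params)
    if (is.finite(e) && e < best) best <<- e
    last_i <- if (nrow(chain)) chain[nrow(chain), 1] else 0L
    last_k <- if (nrow(chain)) chain[nrow(chain), 2] else 0L
    for (i in seq_len(n)) {
      if (i <= last_i) next
      for (k in seq_len(m)) {
        if (k <= last_k) next
        extend(rbind(chain, c(i, k)))
      }
    }
  }
  extend(matrix(integer(0), ncol = 2))
  best
}

# Exhaustive seed-complement scan: every transcript position whose next
# `len` bases equal the antiparallel complement of the seed.
oracle_seed_scan <- function(transcript, seed) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  site <- paste(rev(comp[strsplit(seed, "")[[1]]]), collapse = "")
  L <- nchar(transcript); w <- nchar(site)
  which(vapply(seq_len(L - w + 1L), function(p)
    substr(transcript, p, p + w - 1L) == site, logical(1)))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

base_counts <- function(bases) {
  table(factor(strsplit(bases, "")[[1]], levels = c("A", "C", "G", "U")))
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
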