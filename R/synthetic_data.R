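#' Configuration for the synthetic-data generators
#'
#' One object holds every knob of the three generators, so a whole study
#' is a pure function of its config. Defaults emulate the study
#' conditions of the motivating analysis: a few hundred non-overlapping
#' miR promoters of which a quarter are bound, ChIP cluster scores uniform
#' on \[100, 1000\] (the observed score range), a knockdown-vs-control
#' array with 3 biological replicates per arm and a 7:1 down:up split
#' among affected miRs, and a 4.3-kb transcript carrying planted
#' miR-complementary sites biased into its 3'UTR.
#'
#' @param seed Integer RNG seed; every generator result is a pure function
#'   of (config, seed).
#' @param n_promoters Number of promoters to place.
#' @param cluster_gene_fraction Probability a promoter drives a 2-6 gene
#'   pre-miR cluster (default 0.175, the 28/160 bound-promoter split).
#' @param bound_fraction Probability a promoter carries binding sites.
#' @param score_distribution `"uniform"` (integer scores uniform on
#'   \[100, 1000\]) or a numeric vector of scores to resample.
#' @param genome_length Length of the single synthetic chromosome.
#' @param n_probes Number of array probes (2 probes per gene; must be
#'   even).
#' @param de_fraction Fraction of genes carrying a planted effect.
#' @param de_down_fraction Fraction of affected genes that go down in the
#'   knockdown (default 0.875 = 63/72).
#' @param log2_effect Planted |log2 fold change|.
#' @param noise_sd SD of Gaussian noise on the log2 scale.
#' @param replicates_per_condition Samples per arm (default 3).
#' @param transcript_length Sponge transcript length (default 4300 nt).
#' @param background_composition Named probabilities for A/C/G/U, summing
#'   to 1.
#' @param planted_sites_per_mir Sites planted per miR.
#' @param site_mutation_rate Per-base mutation probability applied to each
#'   planted site (0 = perfect complements).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_promoters = 400L,
                             cluster_gene_fraction = 0.175,
                             bound_fraction = 0.25,
                             score_distribution = "uniform",
                             genome_length = 5e6,
                             n_probes = 2000L, de_fraction = 0.08,
                             de_down_fraction = 0.875, log2_effect = 2,
                             noise_sd = 0.5,
                             replicates_per_condition = 3L,
                             transcript_length = 4300L,
                             background_composition = c(A = 0.25, C = 0.25,
                                                        G = 0.25, U = 0.25),
                             planted_sites_per_mir = 1L,
                             site_mutation_rate = 0.1) {
  cfg <- as.list(environment())
  probs <- c(cluster_gene_fraction, bound_fraction, de_fraction,
             de_down_fraction, site_mutation_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(background_composition) - 1) > 1e-9)
    stop("background_composition must sum to 1")
  sizes <- c(n_promoters, genome_length, n_probes,
             replicates_per_condition, transcript_length)
  if (any(sizes <= 0)) stop("all sizes must be positive")
  if (n_probes %% 2L != 0L) stop("n_probes must be even (2 probes/gene)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "synthetic_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a promoter/binding-cluster landscape with known truth
#'
#' Places `n_promoters` non-overlapping promoters (0.8-4 kb) on one
#' synthetic chromosome. Each promoter is bound with probability
#' `bound_fraction`; bound promoters receive 1-5 overlapping clusters with
#' scores drawn from the configured distribution, unbound promoters
#' receive none. With probability `cluster_gene_fraction` a promoter
#' carries 2-6 comma-separated gene names (a pre-miR cluster promoter).
#'
#' @param config A [synthetic_config()].
#' @return A list with `promoters` and `clusters` data.frames (internal
#'   0-based half-open coordinates, ready for [intersect_binding()]) and
#'   `truth`, a logical bound flag named by `promoter_id`.
#' @export
gen_binding_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_promoters
    widths <- sample(800:4000, n, replace = TRUE)
    gap_budget <- config$genome_length - sum(widths) - 1000
    if (gap_budget < n)
      stop("genome too short to place ", n, " non-overlapping promoters")
    gaps <- stats::rmultinom(1, gap_budget - n, rep(1 / n, n))[, 1] + 1L
    starts <- cumsum(gaps) + cumsum(c(0L, widths[-n]))
    bound <- stats::runif(n) < config$bound_fraction
    is_cluster <- stats::runif(n) < config$cluster_gene_fraction
    gene_counter <- 0L
    genes <- character(n)
    for (i in seq_len(n)) {
      k <- if (is_cluster[i]) sample(2:6, 1L) else 1L
      genes[i] <- paste(sprintf("mir-s%04d", gene_counter + seq_len(k)),
                        collapse = ",")
      gene_counter <- gene_counter + k
    }
    promoters <- data.frame(
      promoter_id = sprintf("prom_%04d", seq_len(n)), chrom = "chrS",
      start = as.integer(starts), end = as.integer(starts + widths),
      strand = "*", genes = genes, stringsAsFactors = FALSE)
    clus <- list()
    for (i in which(bound)) {
      k <- sample(1:5, 1L)
      w <- sample(100:400, k, replace = TRUE)
      # cluster start anywhere keeping >= 1 bp overlap with the promoter
      cs <- as.integer(floor(stats::runif(
        k, promoters$start[i] - w + 1, promoters$end[i] - 1)))
      score <- if (identical(config$score_distribution, "uniform"))
        sample(100:1000, k, replace = TRUE) else
          sample(as.integer(config$score_distribution), k, replace = TRUE)
      clus[[length(clus) + 1L]] <- data.frame(
        chrom = "chrS", start = cs, end = cs + w, score = score,
        stringsAsFactors = FALSE)
    }
    clusters <- if (length(clus) > 0L) do.call(rbind, clus) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 score = integer(), stringsAsFactors = FALSE)
    clusters$start <- pmax(0L, clusters$start)
    list(promoters = promoters, clusters = clusters,
         truth = stats::setNames(bound, promoters$promoter_id))
  })
}

#' Generate a two-condition expression matrix with planted effects
#'
#' Log-normal-style intensities: per-gene baseline log2 level uniform on
#' \[6, 12\], a condition effect of +/-`log2_effect` for the planted
#' fraction of genes (down/up split per `de_down_fraction`), Gaussian
#' noise with `noise_sd`, and 2 probes per gene (small probe offsets) to
#' exercise the probe-collapse rule. Intensities are `2^log2value`, so the
#' matrix is non-negative.
#'
#' @param config A [synthetic_config()].
#' @param gene_ids Optional gene names (length `n_probes / 2`); generated
#'   when `NULL`.
#' @param planted Optional data.frame with columns `gene_id` and `status`
#'   (`down`/`up`/`null`) overriding the random status draw, e.g. to
#'   couple expression truth to a binding landscape.
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene_id`, `status`, `log2_effect`).
#' @export
gen_expression <- function(config, gene_ids = NULL, planted = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 1L, {
    n_genes <- config$n_probes %/% 2L
    if (is.null(gene_ids))
      gene_ids <- sprintf("mir-s%04d", seq_len(n_genes))
    if (length(gene_ids) != n_genes)
      stop("gene_ids must have length n_probes / 2")
    if (is.null(planted)) {
      status <- ifelse(
        stats::runif(n_genes) < config$de_fraction,
        ifelse(stats::runif(n_genes) < config$de_down_fraction,
               "down", "up"),
        "null")
    } else {
      status <- planted$status[match(gene_ids, planted$gene_id)]
      status[is.na(status)] <- "null"
    }
    effect <- ifelse(status == "down", -config$log2_effect,
                     ifelse(status == "up", config$log2_effect, 0))
    R <- config$replicates_per_condition
    sample_ids <- c(sprintf("kd_%d", seq_len(R)),
                    sprintf("ctrl_%d", seq_len(R)))
    condition <- rep(c("knockdown", "control"), each = R)
    baseline <- stats::runif(n_genes, 6, 12)
    probe_offset <- stats::rnorm(2L * n_genes, 0, 0.25)
    probe_gene <- rep(seq_len(n_genes), each = 2L)
    logv <- matrix(0, nrow = 2L * n_genes, ncol = 2L * R)
    for (j in seq_len(2L * R)) {
      eff <- if (condition[j] == "knockdown") effect[probe_gene] else 0
      logv[, j] <- baseline[probe_gene] + probe_offset + eff +
        stats::rnorm(2L * n_genes, 0, config$noise_sd)
    }
    probe_ids <- sprintf("%s_p%d", gene_ids[probe_gene],
                         rep(1:2, times = n_genes))
    em <- expression_matrix(2^logv, probe_ids, gene_ids[probe_gene],
                            sample_ids, condition)
    list(matrix = em,
         truth = data.frame(gene_id = gene_ids, status = status,
                            log2_effect = effect,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a sponge-simulation instance with planted miR sites
#'
#' Draws an i.i.d. background transcript from `background_composition`,
#' designates its final 40% as the 3'UTR, and plants
#' `planted_sites_per_mir` reverse-complement sites per miR (each base
#' mutated with `site_mutation_rate`), placed without overlap and with
#' probability 0.8 inside the 3'UTR (miRs preferentially bind 3'UTR
#' sequence). When `mirs` is `NULL`, a panel of 9 random 22-nt miRs is
#' generated (the size of the upregulated panel in the motivating study).
#'
#' @param config A [synthetic_config()].
#' @param mirs Optional list of `rna_seq` miRs.
#' @return A list with `transcript` (`rna_seq`), `utr3` (1-based inclusive
#'   interval), `mirs`, and `truth` (data.frame of planted site
#'   coordinates: `mir`, `start`, `end` 0-based half-open).
#' @export
gen_sponge_instance <- function(config, mirs = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 2L, {
    bases <- c("A", "C", "G", "U")
    L <- config$transcript_length
    if (is.null(mirs)) {
      mirs <- lapply(seq_len(9L), function(i)
        rna_sequence(sprintf("mir-synth-%d", i),
                     paste(sample(bases, 22L, replace = TRUE,
                                  prob = config$background_composition),
                           collapse = ""), role = "mir"))
    }
    mir_len_total <- sum(vapply(mirs, function(m) nchar(m$bases),
                                numeric(1)))
    if (L < mir_len_total * config$planted_sites_per_mir)
      stop("transcript too short for the requested planted sites")
    tx <- sample(bases, L, replace = TRUE,
                 prob = config$background_composition)
    utr3 <- c(floor(0.6 * L) + 1L, L)
    occupied <- logical(L)
    truth <- list()
    for (m in mirs) {
      site0 <- strsplit(rna_revcomp(m$bases), "")[[1]]
      w <- length(site0)
      for (s in seq_len(config$planted_sites_per_mir)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          in_utr <- stats::runif(1) < 0.8
          lo <- if (in_utr) utr3[1] else 1L
          hi <- (if (in_utr) utr3[2] else utr3[1] - 1L) - w
          if (hi <= lo) next
          pos <- sample(lo:hi, 1L)
          if (any(occupied[pos:(pos + w - 1L)])) next
          site <- site0
          mut <- stats::runif(w) < config$site_mutation_rate
          if (any(mut))
            site[mut] <- vapply(site[mut], function(b)
              sample(setdiff(bases, b), 1L), character(1))
          tx[pos:(pos + w - 1L)] <- site
          occupied[pos:(pos + w - 1L)] <- TRUE
          truth[[length(truth) + 1L]] <- data.frame(
            mir = m$name, start = pos - 1L, end = pos + w - 1L,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("cannot place planted sites without overlap for ", m$name)
      }
    }
    list(transcript = rna_sequence("synthetic_transcript",
                                   paste(tx, collapse = ""),
                                   role = "transcript"),
         utr3 = utr3, mirs = mirs,
         truth = if (length(truth) > 0L) do.call(rbind, truth) else
           data.frame(mir = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits every pipeline input as plain text: `promoters.tsv`,
#' `clusters.tsv` (1-based inclusive coordinates, the default reader
#' dialect), `expression.tsv` + `design.tsv`, `transcript.fa` + `mirs.fa`,
#' and `truth.json` with the generator ground truth. Byte-identical across
#' runs for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  land <- gen_binding_landscape(config)
  expr <- gen_expression(config)
  sponge <- gen_sponge_instance(config)
  prom_out <- land$promoters
  prom_out$start <- prom_out$start + 1L  # write 1-based inclusive
  utils::write.table(prom_out, file.path(dir, "promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clus_out <- land$clusters
  clus_out$start <- clus_out$start + 1L
  utils::write.table(clus_out, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  em <- expr$matrix
  mat_out <- data.frame(probe_id = em$probe_ids, gene_id = em$gene_ids,
                        em$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(mat_out, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = em$sample_ids, condition = em$condition),
    file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_rna_fasta(sponge$transcript, file.path(dir, "transcript.fa"))
  write_rna_fasta(sponge$mirs, file.path(dir, "mirs.fa"))
  truth <- list(bound = as.list(land$truth),
                expression = expr$truth,
                utr3 = sponge$utr3,
                planted_sites = sponge$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Study-scale coupled bundle for end-to-end enrichment recovery
#'
#' Builds a binding landscape of 781 single-gene promoters with exactly
#' 160 bound, and an expression matrix in which exactly 63 genes are
#' planted down (38 of them from bound promoters) and 9 up — the printed
#' counts of the motivating study — so the full pipeline can be checked
#' for recovering the planted enrichment.
#'
#' @param seed Integer seed.
#' @param log2_effect,noise_sd Effect size and noise for the planted
#'   genes.
#' @return A list with `promoters`, `clusters`, `matrix` (an
#'   `expr_matrix`), `truth` (expression truth), and `counts` (the planted
#'   universe/bound/selected/selected-bound counts).
#' @export
gen_coupled_bundle <- function(seed = 1L, log2_effect = 2,
                                   noise_sd = 0.5) {
  n_univ <- 781L; n_bound <- 160L; n_down <- 63L; n_down_bound <- 38L
  n_up <- 9L
  cfg_land <- synthetic_config(seed = seed, n_promoters = n_univ,
                               cluster_gene_fraction = 0,
                               bound_fraction = 0, genome_length = 6e6)
  land <- gen_binding_landscape(cfg_land)
  with_seed(seed + 10L, {
    bound_idx <- sample.int(n_univ, n_bound)
    # re-draw clusters for the chosen bound promoters
    clus <- list()
    for (i in bound_idx) {
      k <- sample(1:5, 1L)
      w <- sample(100:400, k, replace = TRUE)
      cs <- as.integer(floor(stats::runif(
        k, land$promoters$start[i] - w + 1, land$promoters$end[i] - 1)))
      clus[[length(clus) + 1L]] <- data.frame(
        chrom = "chrS", start = pmax(0L, cs), end = pmax(0L, cs) + w,
        score = sample(100:1000, k, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    clusters <- do.call(rbind, clus)
    genes <- land$promoters$genes  # single-gene promoters
    bound_genes <- genes[bound_idx]
    unbound_genes <- genes[-bound_idx]
    down <- c(sample(bound_genes, n_down_bound),
              sample(unbound_genes, n_down - n_down_bound))
    up <- sample(setdiff(genes, down), n_up)
    planted <- data.frame(
      gene_id = c(down, up),
      status = c(rep("down", n_down), rep("up", n_up)),
      stringsAsFactors = FALSE)
    cfg_expr <- synthetic_config(seed = seed, n_probes = 2L * n_univ,
                                 log2_effect = log2_effect,
                                 noise_sd = noise_sd)
    expr <- gen_expression(cfg_expr, gene_ids = genes, planted = planted)
    list(promoters = land$promoters, clusters = clusters,
         matrix = expr$matrix, truth = expr$truth,
         counts = list(n_universe = n_univ, n_bound = n_bound,
                       n_selected = n_down,
                       n_selected_bound = n_down_bound))
  })
}
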