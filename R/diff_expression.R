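#' Construct a two-condition expression matrix
#'
#' Container for probe-level intensities from a knockdown-vs-control miR
#' array experiment. Several probes may map to the same gene (many-to-one);
#' intensities must be finite and non-negative with no missing values.
#'
#' @param values Numeric matrix, probes x samples, non-negative.
#' @param probe_ids Character vector, one id per row.
#' @param gene_ids Character vector mapping each probe to a gene.
#' @param sample_ids Character vector, one id per column.
#' @param condition Character/factor per sample, levels `knockdown` and
#'   `control`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, probe_ids, gene_ids, sample_ids,
                              condition) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("intensities must be finite numbers with no missing values")
  if (any(values < 0)) stop("intensities must be non-negative")
  if (length(probe_ids) != nrow(values) ||
      length(gene_ids) != nrow(values))
    stop("probe_ids and gene_ids must match the number of rows")
  if (length(sample_ids) != ncol(values) ||
      length(condition) != ncol(values))
    stop("sample_ids and condition must match the number of columns")
  condition <- as.character(condition)
  if (!all(condition %in% c("knockdown", "control")))
    stop("condition labels must be 'knockdown' or 'control'")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, probe_ids = as.character(probe_ids),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "probes (",
      length(unique(x$gene_ids)), "genes ) x", ncol(x$values),
      "samples [", sum(x$condition == "knockdown"), "knockdown,",
      sum(x$condition == "control"), "control ]\n")
  invisible(x)
}

#' Read an expression matrix and its design file
#'
#' The matrix file is tab-separated with header: first column `probe_id`,
#' second `gene_id`, remaining columns one per sample. The design file is
#' two tab-separated columns `sample_id`, `condition`.
#'
#' @param path Matrix TSV path.
#' @param design_path Design TSV path.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, design_path) {
  if (!file.exists(design_path))
    stop("design file not found: ", design_path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L || !all(c("probe_id", "gene_id") %in% names(df)[1:2]))
    stop("expression table must start with probe_id and gene_id columns")
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("design file must have sample_id and condition columns")
  samples <- names(df)[-(1:2)]
  cond <- design$condition[match(samples, design$sample_id)]
  if (any(is.na(cond)))
    stop("design file misses sample(s): ",
         paste(samples[is.na(cond)], collapse = ", "))
  expression_matrix(as.matrix(df[, -(1:2), drop = FALSE]),
                    df$probe_id, df$gene_id, samples, cond)
}

#' Quantile-normalize samples to a common intensity distribution
#'
#' Forces every sample (column) to share one empirical distribution: the
#' vector of cross-column rank means. Ties within a column receive the mean
#' of the quantile values they span. The operation is idempotent and
#' equivariant under sample permutation.
#'
#' @param em An `expr_matrix`.
#' @return An `expr_matrix` with normalized intensities.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2L) stop("need at least 2 samples to normalize")
  if (any(!is.finite(em$values))) stop("non-finite intensities")
  norm <- limma::normalizeQuantiles(em$values, ties = TRUE)
  em$values <- pmax(norm, 0)
  em
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test of equal means without assuming equal variances; degrees
#' of freedom follow the Welch-Satterthwaite approximation. When both
#' groups have zero variance and equal means, `p = 1` by convention (and
#' `p = 0` with an infinite statistic when the constant values differ).
#'
#' @param a,b Numeric vectors of length >= 2.
#' @return A list with `t_stat`, `df`, `p_value`; `t_stat` is positive when
#'   `mean(a) > mean(b)`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t needs at least 2 observations per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, df = length(a) + length(b) - 2, p_value = 1))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Call differentially expressed genes between knockdown and control
#'
#' Applies the per-gene Welch test to a (normalized) expression matrix at a
#' raw p-value cutoff. Intensities are log2-transformed after a pseudo-count
#' (standard for array intensities and required for symmetric fold
#' changes); duplicate probes of a gene are collapsed by their per-sample
#' median before testing. An optional Benjamini-Hochberg adjustment is an
#' extension beyond the raw cutoff and is off by default.
#'
#' @param em An `expr_matrix`, typically after [quantile_normalize()].
#' @param alpha Significance cutoff on the (adjusted, if `bh`) p-value.
#' @param log_transform Log2-transform intensities before testing
#'   (default `TRUE`).
#' @param pseudo_count Added before the log transform (default 1).
#' @param collapse `"median"` (collapse probes per gene, default) or
#'   `"none"` (test per probe; `gene_id` then repeats).
#' @param bh Apply Benjamini-Hochberg adjustment before the cutoff.
#' @return A `data.frame` with one row per gene (or probe): `gene_id`,
#'   `mean_kd`, `mean_ctrl`, `log2_fc` (knockdown minus control on the
#'   analysis scale), `t_stat`, `df`, `p_value`, and `direction` in
#'   `down_in_kd` / `up_in_kd` / `ns`.
#' @export
call_de <- function(em, alpha = 0.05, log_transform = TRUE,
                    pseudo_count = 1, collapse = c("median", "none"),
                    bh = FALSE) {
  stopifnot(inherits(em, "expr_matrix"))
  collapse <- match.arg(collapse)
  kd <- em$condition == "knockdown"
  ct <- em$condition == "control"
  if (sum(kd) < 2L || sum(ct) < 2L)
    stop("each condition needs at least 2 samples")
  x <- em$values
  if (log_transform) x <- log2(x + pseudo_count)
  if (collapse == "median") {
    genes <- unique(em$gene_ids)
    x <- t(vapply(genes, function(g) {
      rows <- x[em$gene_ids == g, , drop = FALSE]
      apply(rows, 2, stats::median)
    }, numeric(ncol(x))))
    ids <- genes
  } else {
    ids <- em$gene_ids
  }
  res <- lapply(seq_len(nrow(x)), function(i) {
    w <- welch_t(x[i, kd], x[i, ct])
    data.frame(gene_id = ids[i], mean_kd = mean(x[i, kd]),
               mean_ctrl = mean(x[i, ct]),
               log2_fc = mean(x[i, kd]) - mean(x[i, ct]),
               t_stat = w$t_stat, df = w$df, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_eff <- if (bh) stats::p.adjust(out$p_value, method = "BH") else
    out$p_value
  out$direction <- ifelse(p_eff > alpha, "ns",
                          ifelse(out$log2_fc < 0, "down_in_kd", "up_in_kd"))
  out
}

#' Hierarchical clustering order under correlation distance
#'
#' Orders genes or samples by average-linkage agglomerative clustering on
#' the distance `1 - Pearson r` between profiles ("standard correlation" as
#' similarity). The leaf order is deterministic given the input order; ties
#' follow the agglomeration order of [stats::hclust()], which merges the
#' smallest item indices first among equals.
#'
#' @param em An `expr_matrix`.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`.
#' @return A list with `leaf_order` (permutation of item indices),
#'   `merge_heights` (non-decreasing for average/complete/single linkage on
#'   these distances), and `labels`.
#' @export
cluster_order <- function(em, axis = c("genes", "samples"),
                          linkage = c("average", "single", "complete")) {
  stopifnot(inherits(em, "expr_matrix"))
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  prof <- if (axis == "genes") em$values else t(em$values)
  labels <- if (axis == "genes") em$probe_ids else em$sample_ids
  if (nrow(prof) < 2L) stop("need at least 2 items to cluster")
  v <- apply(prof, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance item(s): ",
         paste(labels[v == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(prof)))
  hc <- stats::hclust(d, method = linkage)
  list(leaf_order = hc$order, merge_heights = hc$height, labels = labels)
}

#' Relative expression by the comparative-Ct method
#'
#' Computes the fold change of condition A relative to condition B from
#' qPCR cycle-threshold values, normalising each condition's target Ct
#' against a reference gene (e.g. snRNA U6): `2^-ddCt` with
#' `ddCt = (ct_target_A - ct_ref_A) - (ct_target_B - ct_ref_B)`. A ddCt of
#' 3 is an 8-fold reduction.
#'
#' @param ct_target_a,ct_ref_a Target and reference Ct in condition A.
#' @param ct_target_b,ct_ref_b Target and reference Ct in condition B.
#' @return Fold change of A relative to B (1 = no change).
#' @export
qpcr_relative_expression <- function(ct_target_a, ct_ref_a,
                                     ct_target_b, ct_ref_b) {
  if (!all(is.finite(c(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b))))
    stop("all Ct values must be finite")
  ddct <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-ddct)
}
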