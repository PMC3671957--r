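make_em <- function(values, genes = NULL, R = ncol(values) / 2) {
  n <- nrow(values)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(n))
  expression_matrix(values, sprintf("probe%03d", seq_len(n)), genes,
                    sprintf("s%d", seq_len(ncol(values))),
                    rep(c("knockdown", "control"), each = R))
}

test_that("quantile normalization maps columns onto the rank-mean distribution", {
  em <- make_em(cbind(c(1, 2, 3), c(4, 5, 6)), R = 1)
  qn <- quantile_normalize(em)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))
})

test_that("quantile normalization is idempotent, a fixed point on equal columns, and sample-permutation equivariant", {
  set.seed(21)
  v <- matrix(rexp(300, 1 / 50), nrow = 50)
  em <- make_em(v, R = 3)
  qn1 <- quantile_normalize(em)
  qn2 <- quantile_normalize(qn1)
  expect_equal(qn2$values, qn1$values, tolerance = 1e-12)
  expect_equal(diff(range(colSums(qn1$values))), 0, tolerance = 1e-9)

  same <- make_em(matrix(rep(sort(rexp(50)), 4), ncol = 4), R = 2)
  expect_equal(quantile_normalize(same)$values, same$values,
               tolerance = 1e-12)

  perm <- c(4, 1, 6, 2, 5, 3)
  em_p <- em
  em_p$values <- em$values[, perm]
  qn_p <- quantile_normalize(em_p)
  expect_equal(unname(qn_p$values), unname(qn1$values[, perm]),
               tolerance = 1e-12)
})

test_that("welch_t matches the textbook formulas and the pooled t in the balanced equal-variance case", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welch_t(a, b)
  # hand evaluation of the Welch formulas
  se2 <- var(a) / 3 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(w$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p_value, p_hand, tolerance = 1e-12)

  x <- c(3, 5, 8, 2); y <- c(7, 9, 12, 6)  # equal variances and sizes
  w2 <- welch_t(x, y)
  expect_equal(w2$df, length(x) + length(y) - 2, tolerance = 1e-9)
  expect_equal(w2$p_value, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("welch_t handles identical and degenerate inputs by convention", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t_stat, 0)
  expect_equal(w$p_value, 1)
  expect_equal(welch_t(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t(c(3, 3), c(1, 1))$p_value, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("null Welch p-values are near-uniform at 3v3 and uniform where the approximation is exact", {
  set.seed(202)
  # at 3 per group the Welch approximation is slightly conservative, so
  # exact uniformity fails; the sup-norm deviation must still be small
  # and the lower tail must never be anticonservative
  p3 <- replicate(2000, welch_t(rnorm(3), rnorm(3))$p_value)
  expect_lt(suppressWarnings(ks.test(p3, "punif")$statistic), 0.05)
  expect_lte(mean(p3 <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))

  # with 10 per group the approximation is accurate and KS passes
  p10 <- replicate(2000, welch_t(rnorm(10), rnorm(10))$p_value)
  expect_gt(suppressWarnings(ks.test(p10, "punif")$p.value), 0.01)
})

test_that("call_de recovers planted downregulation and bounds false positives", {
  set.seed(33)
  n <- 100; R <- 3
  planted <- 1:10
  logv <- matrix(rnorm(n * 2 * R, 8, 0.25), nrow = n)
  logv[planted, 1:R] <- logv[planted, 1:R] - 2  # knockdown down by 2
  em <- make_em(2^logv)
  de <- call_de(em, alpha = 0.05)
  expect_setequal(de$gene_id[de$direction == "down_in_kd" &
                               de$gene_id %in% sprintf("g%03d", planted)],
                  sprintf("g%03d", planted))
  fp <- sum(de$direction != "ns" & !de$gene_id %in% sprintf("g%03d", planted))
  expect_lte(fp, qbinom(0.995, n - 10, 0.05))

  # a vanishing cutoff silences every call
  de0 <- call_de(em, alpha = 1e-12)
  expect_true(all(de0$direction[!de0$gene_id %in%
                                  sprintf("g%03d", planted)] == "ns"))
})

test_that("type-I error is calibrated where the Welch approximation holds and conservative at 3v3", {
  # 10 replicates/arm: size within 3 binomial SE of the nominal level
  cfg <- synthetic_config(seed = 5, n_probes = 4000, de_fraction = 0,
                          replicates_per_condition = 10L)
  g <- gen_expression(cfg)
  fpr10 <- mean(call_de(g$matrix)$direction != "ns")
  expect_lt(abs(fpr10 - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  # 3 replicates/arm: the Welch test is conservative, never anticonservative
  cfg3 <- synthetic_config(seed = 5, n_probes = 4000, de_fraction = 0)
  fpr3 <- mean(call_de(gen_expression(cfg3)$matrix)$direction != "ns")
  expect_lte(fpr3, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("direction labels are invariant to an additive intensity shift", {
  set.seed(44)
  logv <- matrix(rnorm(120 * 6, 8, 0.5), nrow = 120)
  logv[1:12, 1:3] <- logv[1:12, 1:3] - 2
  em <- make_em(2^logv)
  em_shift <- em
  em_shift$values <- em$values + 50
  de1 <- call_de(em, log_transform = FALSE)
  de2 <- call_de(em_shift, log_transform = FALSE)
  expect_identical(de1$direction, de2$direction)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-9)
})

test_that("probe collapse takes the per-sample median across a gene's probes", {
  v <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(10, 10, 10, 10))
  em <- expression_matrix(v, c("p1", "p2", "p3"), c("gA", "gA", "gB"),
                          sprintf("s%d", 1:4),
                          rep(c("knockdown", "control"), each = 2))
  de <- call_de(em, log_transform = FALSE)
  gA <- de[de$gene_id == "gA", ]
  expect_equal(gA$mean_kd, mean(c(3, 4)))    # medians (3,4) then (5,6)
  expect_equal(gA$mean_ctrl, mean(c(5, 6)))
})

test_that("correlation-distance clustering separates planted blocks and ignores positive scaling", {
  set.seed(55)
  base1 <- rnorm(20); base2 <- rnorm(20)
  prof <- rbind(
    base1 + rnorm(20, 0, 0.2), base1 + rnorm(20, 0, 0.2),
    base1 + rnorm(20, 0, 0.2),
    base2 + rnorm(20, 0, 0.2), base2 + rnorm(20, 0, 0.2),
    base2 + rnorm(20, 0, 0.2))
  em <- expression_matrix(abs(prof) + 1, sprintf("p%d", 1:6),
                          sprintf("g%d", 1:6), sprintf("s%d", 1:20),
                          rep(c("knockdown", "control"), each = 10))
  ord <- cluster_order(em, axis = "genes")
  pos <- match(1:6, ord$leaf_order)
  expect_true(max(pos[1:3]) < min(pos[4:6]) ||
                min(pos[1:3]) > max(pos[4:6]))
  expect_true(all(diff(ord$merge_heights) >= -1e-9))

  em_scaled <- em
  em_scaled$values[2, ] <- em$values[2, ] * 7
  ord2 <- cluster_order(em_scaled, axis = "genes")
  expect_identical(ord2$leaf_order, ord$leaf_order)
})

test_that("clustering degenerate cases: identical profiles merge at height 0, anti-correlated at 2, zero variance errors", {
  v <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  em <- expression_matrix(v, c("p1", "p2", "p3"), c("g1", "g2", "g3"),
                          sprintf("s%d", 1:4),
                          rep(c("knockdown", "control"), each = 2))
  ord <- cluster_order(em, axis = "genes")
  expect_equal(ord$merge_heights[1], 0, tolerance = 1e-12)  # r = 1 pair
  expect_equal(max(ord$merge_heights), 2, tolerance = 1e-9) # r = -1

  v2 <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5))
  em2 <- expression_matrix(v2, c("p1", "flatline"), c("g1", "g2"),
                           sprintf("s%d", 1:4),
                           rep(c("knockdown", "control"), each = 2))
  expect_error(cluster_order(em2, axis = "genes"), "flatline")
})

test_that("comparative-Ct fold changes follow 2^-ddCt", {
  # ddCt of 3: the knockdown shows an 8-fold reduction
  expect_equal(qpcr_relative_expression(25, 15, 22, 15), 0.125)
  expect_equal(qpcr_relative_expression(20, 15, 20, 15), 1)
  expect_equal(qpcr_relative_expression(19, 15, 20, 15), 2)
  expect_error(qpcr_relative_expression(NA, 1, 2, 3), "finite")
})

test_that("expression IO round-trips through the TSV + design format", {
  cfg <- synthetic_config(seed = 9, n_probes = 40)
  dir <- tempfile()
  write_bundle(cfg, dir)
  em <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "design.tsv"))
  orig <- gen_expression(cfg)$matrix
  expect_equal(em$values, orig$values, tolerance = 1e-6)
  expect_identical(em$condition, orig$condition)
  expect_error(read_expression(file.path(dir, "expression.tsv"),
                               file.path(dir, "nope.tsv")), "nope.tsv")
})
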