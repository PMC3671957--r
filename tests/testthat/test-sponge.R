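toy <- toy_energy_params()

perfect_window <- function(mir_bases) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", mir_bases), "")[[1]]),
        collapse = "")
}

test_that("rna_sequence validates the alphabet and maps T to U", {
  s <- rna_sequence("x", "acgt", role = "transcript")
  expect_equal(s$bases, "ACGU")
  expect_error(rna_sequence("x", "ACGN", role = "transcript"), "non-ACGU")
  expect_warning(rna_sequence("m", "ACGUACG", role = "mir"), "18-26")
})

test_that("FASTA IO round-trips sequences", {
  seqs <- list(rna_sequence("tx1", random_rna(120), "transcript"),
               rna_sequence("tx2", random_rna(80), "transcript"))
  path <- tempfile(fileext = ".fa")
  write_rna_fasta(seqs, path)
  back <- read_rna_fasta(path, role = "transcript")
  expect_equal(vapply(back, `[[`, "", "bases"),
               vapply(seqs, `[[`, "", "bases"))
  expect_equal(vapply(back, `[[`, "", "name"), c("tx1", "tx2"))
})

test_that("seed scan finds exactly the planted antiparallel seed complements", {
  mir <- suppressWarnings(rna_sequence("m", "UAGCUUAUCAGACUGAUGUUGA", "mir"))
  site <- perfect_window(substr(mir$bases, 2, 7))
  tx <- rna_sequence("t", paste0(strrep("A", 50), site, strrep("A", 50)),
                     "transcript")
  cand <- seed_sites(tx, mir)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$seed_start, 50)

  none <- rna_sequence("t", strrep("A", 120), "transcript")
  mir_gc <- suppressWarnings(rna_sequence("m2", "AGCGCGCUUUUUUUUUUUUUUU",
                                          "mir"))
  expect_equal(nrow(seed_sites(none, mir_gc)), 0)
})

test_that("seed scan agrees with the exhaustive string-match oracle on random sequences with planted sites", {
  set.seed(71)
  for (rep in 1:10) {
    mir <- suppressWarnings(rna_sequence("m", random_rna(22), "mir"))
    seed <- substr(mir$bases, 2, 7)
    site <- perfect_window(seed)
    bg <- strsplit(random_rna(2000), "")[[1]]
    planted_at <- sort(sample(seq(10, 1900, by = 60), 10))
    for (p in planted_at) bg[p:(p + 5)] <- strsplit(site, "")[[1]]
    tx <- rna_sequence("t", paste(bg, collapse = ""), "transcript")
    cand <- seed_sites(tx, mir)
    expect_setequal(cand$seed_start + 1, oracle_seed_scan(tx$bases, seed))
    expect_true(all(planted_at %in% (cand$seed_start + 1)))
  }
})

test_that("a perfect complement scores -(L-1) under unit stacks and windows over the maximum are rejected", {
  for (L in c(5, 9, 22)) {
    mir <- suppressWarnings(rna_sequence("m", random_rna(L), "mir"))
    win <- rna_sequence("w", perfect_window(mir$bases), "transcript")
    hit <- duplex_mfe(win, mir, toy)
    expect_equal(hit$delta_g, -(L - 1))
    expect_equal(nrow(hit$pairs), L)
    expect_equal(hit$energy_released, L - 1)
    expect_equal(duplex_notation(hit, L),
                 paste0(strrep("(", L), "&", strrep(")", L)))
  }
  big <- rna_sequence("w", random_rna(60), "transcript")
  mir <- suppressWarnings(rna_sequence("m", random_rna(22), "mir"))
  expect_error(duplex_mfe(big, mir, toy), "exceeds the maximum")
})

test_that("a central mismatch is scored exactly as the enumeration oracle dictates", {
  mir <- suppressWarnings(rna_sequence("m", "ACGUACGUA", "mir"))
  win_chars <- strsplit(perfect_window(mir$bases), "")[[1]]
  win_chars[5] <- setdiff(c("A", "C", "G", "U"),
                          c(win_chars[5], "A"))[1]  # break the middle pair
  win <- rna_sequence("w", paste(win_chars, collapse = ""), "transcript")
  params <- toy_energy_params(internal_open = 2, internal_extend = 1,
                              max_loop = 4)
  hit <- duplex_mfe(win, mir, params)
  expect_equal(hit$delta_g,
               oracle_duplex_mfe(win$bases, mir$bases, params))
})

test_that("the empty pairing bounds delta_g at zero when initiation is free", {
  set.seed(72)
  for (rep in 1:20) {
    win <- rna_sequence("w", random_rna(sample(3:10, 1)), "transcript")
    mir <- suppressWarnings(rna_sequence("m", random_rna(22), "mir"))
    expect_lte(duplex_mfe(win, mir, toy)$delta_g, 0)
  }
})

test_that("delta_g is invariant under reverse-complement relabeling of both strands", {
  set.seed(73)
  for (params in list(toy, default_energy_params())) {
    for (rep in 1:15) {
      a <- random_rna(sample(4:8, 1))
      b <- random_rna(sample(4:8, 1))
      g1 <- duplex_mfe(rna_sequence("w", a, "transcript"),
                       suppressWarnings(rna_sequence("m", b, "mir")),
                       params)$delta_g
      g2 <- duplex_mfe(rna_sequence("w", perfect_window(b), "transcript"),
                       suppressWarnings(rna_sequence("m", perfect_window(a),
                                                     "mir")),
                       params)$delta_g
      expect_equal(g1, g2, tolerance = 1e-9)
    }
  }
})

test_that("weakening every stack cannot make the duplex more stable", {
  set.seed(74)
  strong <- toy_energy_params(stack_energy = -2, max_loop = 3)
  weak <- toy_energy_params(stack_energy = -1.5, max_loop = 3)
  for (rep in 1:15) {
    a <- random_rna(8)
    b <- random_rna(8)
    w <- rna_sequence("w", a, "transcript")
    m <- suppressWarnings(rna_sequence("m", b, "mir"))
    expect_gte(duplex_mfe(w, m, weak)$delta_g,
               duplex_mfe(w, m, strong)$delta_g - 1e-9)
  }
})

test_that("best_site prefers the energetically superior planted site and returns NULL without seeds", {
  mir <- suppressWarnings(rna_sequence("m", "ACGUACGUA", "mir"))
  perfect <- perfect_window(mir$bases)
  mut <- strsplit(perfect, "")[[1]]
  mut[1] <- setdiff(c("A", "C", "G", "U"), c(mut[1], "A"))[1]
  mismatched <- paste(mut, collapse = "")
  tx <- rna_sequence("t", paste0(strrep("A", 30), mismatched,
                                 strrep("A", 30), perfect,
                                 strrep("A", 30)), "transcript")
  hit <- best_site(tx, mir, toy)
  expect_equal(hit$delta_g, -8)
  # the winning window contains the perfect site (second planted block)
  expect_gte(hit$transcript_window[1], 60)

  no_match <- rna_sequence("t", strrep("A", 100), "transcript")
  gc_mir <- suppressWarnings(rna_sequence("m2", "AGCGCGCUUUUUUUUUUUUUUU",
                                          "mir"))
  expect_null(best_site(no_match, gc_mir, toy))
})

test_that("sponge_score sums energy released over the panel, with zero for siteless miRs", {
  mirs <- suppressWarnings(list(
    rna_sequence("m1", "ACGUACGUA", "mir"),
    rna_sequence("m2", "CAGUCAGUC", "mir"),
    rna_sequence("m3", "AGCGCGCGC", "mir")))
  tx <- rna_sequence("t", paste0(
    strrep("A", 25), perfect_window(mirs[[1]]$bases),
    strrep("A", 25), perfect_window(mirs[[2]]$bases),
    strrep("A", 25)), "transcript")
  # m3's seed complement (GCGCGC on the transcript) never occurs
  expect_equal(length(oracle_seed_scan(tx$bases,
                                       substr(mirs[[3]]$bases, 2, 7))), 0)
  expect_equal(sponge_score(tx, mirs, toy), 16)
  tab <- sponge_score(tx, mirs, toy, per_mir = TRUE)
  expect_equal(tab$energy_released, c(8, 8, 0))

  # concatenation cannot lose the best sites
  tx2 <- rna_sequence("t2", paste0(tx$bases, strrep("A", 20), tx$bases),
                      "transcript")
  expect_gte(sponge_score(tx2, mirs, toy), sponge_score(tx, mirs, toy))
})

test_that("composition shuffle preserves the base multiset and is seed-reproducible", {
  set.seed(75)
  for (rep in 1:20) {
    s <- rna_sequence("s", random_rna(sample(c(1, 10, 100), 1)),
                      "transcript")
    sh <- shuffle_composition(s, seed = rep)
    expect_equal(base_counts(sh$bases), base_counts(s$bases))
  }
  one <- rna_sequence("s", "G", "transcript")
  expect_equal(shuffle_composition(one, 1)$bases, "G")

  s <- rna_sequence("s", random_rna(100), "transcript")
  expect_identical(shuffle_composition(s, 42)$bases,
                   shuffle_composition(s, 42)$bases)
  expect_false(shuffle_composition(s, 1)$bases ==
                 shuffle_composition(s, 2)$bases)
})

test_that("dinucleotide shuffle preserves dinucleotide counts and terminal bases", {
  dinuc_counts <- function(b) {
    ch <- strsplit(b, "")[[1]]
    table(factor(paste0(ch[-length(ch)], ch[-1]),
                 levels = as.vector(outer(c("A", "C", "G", "U"),
                                          c("A", "C", "G", "U"),
                                          paste0))))
  }
  set.seed(76)
  for (rep in 1:10) {
    s <- rna_sequence("s", random_rna(200), "transcript")
    sh <- shuffle_dinucleotide(s, seed = rep)
    expect_equal(dinuc_counts(sh$bases), dinuc_counts(s$bases))
    expect_equal(substr(sh$bases, 1, 1), substr(s$bases, 1, 1))
    expect_equal(substr(sh$bases, 200, 200), substr(s$bases, 200, 200))
  }
})

test_that("the shuffle null flags planted sponge instances and follows the add-one formula", {
  cfg <- synthetic_config(seed = 14, transcript_length = 1200,
                          site_mutation_rate = 0)
  sp <- gen_sponge_instance(cfg)
  res <- run_sponge_null(sp$transcript, utr3 = sp$utr3, mirs = sp$mirs,
                         params = toy, n_shuffles = 10, seed = 2)
  # strongly planted: every null score falls below the true score
  expect_equal(res$full$empirical_p, 1 / 11)
  expect_equal(res$utr3$empirical_p, 1 / 11)
  expect_equal(res$full$empirical_p,
               (1 + sum(res$full$null_scores >= res$full$true_score)) /
                 (1 + res$full$n_shuffles))

  expect_error(run_sponge_null(sp$transcript, utr3 = c(500, 50000),
                               mirs = sp$mirs, params = toy,
                               n_shuffles = 10, seed = 2), "utr3")
  expect_error(run_sponge_null(sp$transcript, mirs = sp$mirs,
                               params = toy, n_shuffles = 5, seed = 2),
               "at least 10")
})

test_that("the sponge null is bit-identical under a fixed seed and leaves the caller's RNG alone", {
  cfg <- synthetic_config(seed = 15, transcript_length = 600,
                          planted_sites_per_mir = 0)
  sp <- gen_sponge_instance(cfg)
  mirs <- sp$mirs[1:3]
  set.seed(99); before <- runif(1)
  set.seed(99)
  r1 <- run_sponge_null(sp$transcript, mirs = mirs, params = toy,
                        n_shuffles = 12, seed = 31)
  after <- runif(1)
  expect_equal(after, before)  # RNG stream undisturbed
  r2 <- run_sponge_null(sp$transcript, mirs = mirs, params = toy,
                        n_shuffles = 12, seed = 31)
  expect_identical(r1, r2)
})

test_that("shipped default parameters load with physical signs and wobble disabled", {
  p <- default_energy_params()
  expect_true(all(p$stack_table <= 0))
  expect_equal(unname(p$stack_table["GC/CG"]), -3.42)
  expect_equal(p$init_penalty, 4.09)
  expect_false(p$allow_gu)
  expect_error(energy_params(c(`GC/CG` = 0.5, `AA/UU` = -1),
                             init_penalty = -1), "penalties")
})
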