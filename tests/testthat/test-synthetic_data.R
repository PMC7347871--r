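test_that("generators are deterministic under a fixed seed", {
  p1 <- simulate_mitogenome_pair(divergence = 0.2, seed = 60)
  p2 <- simulate_mitogenome_pair(divergence = 0.2, seed = 60)
  expect_identical(p1$genome_f$sequence, p2$genome_f$sequence)
  expect_identical(p1$genome_m$sequence, p2$genome_m$sequence)
  h1 <- simulate_haplotypes(6, 200, 0.02, seed = 61)
  h2 <- simulate_haplotypes(6, 200, 0.02, seed = 61)
  expect_identical(h1$seq, h2$seq)
  q1 <- simulate_qpcr_dataset(n_samples = 3, seed = 62)
  q2 <- simulate_qpcr_dataset(n_samples = 3, seed = 62)
  expect_identical(q1$samples$cq, q2$samples$cq)
})

test_that("mitogenome pair carries the planted structure and divergence", {
  pair <- simulate_mitogenome_pair(divergence = 0.1, seed = 63)
  f <- pair$genome_f; m <- pair$genome_m
  # M-specific structure: extended atp8, repeat region, relocated rrnS
  atp8_m <- m$features[m$features$name == "atp8", ]
  expect_equal(atp8_m$end - atp8_m$start, 885)
  expect_true("repeat_region" %in% m$features$category)
  expect_false("repeat_region" %in% f$features$category)
  pos_m <- match(c("rrnL", "rrnS"), m$features$name)
  expect_equal(diff(pos_m), 2) # rrnS follows rrnL (repeat in between)
  expect_gt(m$length, f$length)
  # realized p-distance binomial around the target
  expect_lt(abs(mean(pair$truth$realized_p) - 0.1), 0.02)
  # truth alignments are gap-free and translate cleanly for proteins
  expect_false(any(grepl("-", unlist(lapply(pair$alignments, `[[`, "seq")))))
  cox1 <- pair$alignments$cox1
  expect_no_error(lapply(cox1$seq, translate_cds))
  expect_error(simulate_mitogenome_pair(divergence = 0.8), "0.75")
})

test_that("zero divergence gives identical gene sequences", {
  pair <- simulate_mitogenome_pair(divergence = 0, seed = 64,
                                   extend_atp8 = FALSE, add_repeat = FALSE,
                                   relocate_rrns = FALSE)
  expect_identical(pair$genome_f$sequence, pair$genome_m$sequence)
  expect_true(all(pair$truth$realized_p == 0))
})

test_that("skew profile shows up in the generated composition", {
  prof <- list(nc1 = list(at_skew = 0.3, gc_content = 0.3))
  pair <- simulate_mitogenome_pair(divergence = 0, seed = 65,
                                   skew_profile = prof)
  g <- pair$genome_f
  nc1 <- as.list(g$features[g$features$name == "nc1", ])
  s <- extract_feature_sequence(g, nc1)
  n <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  at_skew <- (n[["A"]] - n[["T"]]) / (n[["A"]] + n[["T"]])
  expect_lt(abs(at_skew - 0.3), 0.05)
})

test_that("coalescent haplotypes hit the Watterson expectation", {
  hs <- simulate_haplotypes(18, 1317, 1e-9, seed = 66)
  expect_equal(diversity_stats(hs)$S, 0L) # theta -> 0 limit
  set.seed(67)
  S <- replicate(300, attr(simulate_haplotypes(18, 1317, 0.02), "truth")$S)
  expected <- 0.02 * 1317 * sum(1 / (1:17))
  expect_lt(abs(mean(S) - expected) / expected, 0.05)
  # realized S matches what diversity_stats counts (infinite sites)
  hs2 <- simulate_haplotypes(10, 800, 0.02, seed = 68)
  expect_equal(diversity_stats(hs2)$S, attr(hs2, "truth")$S)
})

test_that("codon mode respects omega and avoids stops", {
  hs <- simulate_haplotypes(6, 300, 0.05, omega = 0.5, seed = 69)
  for (s in hs$seq) expect_no_error(translate_cds(s))
  set.seed(70)
  r <- replicate(15, {
    hs <- simulate_haplotypes(8, 999, 0.05, omega = 0.1)
    nei_gojobori_kaks(hs, bootstrap_reps = 0)$Ka_over_Ks
  })
  expect_lt(mean(r, na.rm = TRUE), 0.5)
})

test_that("qPCR generator produces the stated table shapes and truth", {
  sim <- simulate_qpcr_dataset(n_samples = 5, seed = 71)
  expect_equal(nrow(sim$dilutions), 3 * 3 * 3 * 7) # targets x exp x reps x folds
  expect_named(sim$samples, c("sample_id", "tissue", "target", "replicate", "cq"))
  expect_equal(nrow(sim$samples), 5 * 2 * 3 * 3)
  tr <- sim$truth$samples
  male <- tr[tr$tissue == "male_mantle", ]
  expect_equal(male$m_per_ndna, 15 + 0.8 * male$f_per_ndna)
  fem <- tr[tr$tissue == "female_mantle", ]
  expect_true(all(fem$f_per_ndna / fem$m_per_ndna >= 1e3 - 1e-9 &
                    fem$f_per_ndna / fem$m_per_ndna <= 1e4 + 1e-9))
  expect_error(simulate_qpcr_dataset(true_intercept = -50), "negative")
})

test_that("female-mantle contamination recovers the planted F/M range", {
  sim <- simulate_qpcr_dataset(n_samples = 6, sigma_cq = 0.05, seed = 72)
  curves <- fit_standard_curves(sim$dilutions)
  q <- quantify_samples(sim$samples, curves, cq_cutoff = 45)
  fm <- ratio_table(q[q$tissue == "female_mantle", ], curves,
                    "F_cox1", "M_nad1")
  expect_true(all(fm$ratio > 5e2 & fm$ratio < 2e4))
})

test_that("binomial NGS split inverts through ngs_ratio", {
  cnt <- simulate_ngs_counts(1, 100, 100, 10000, seed = 73)
  expect_lt(abs(cnt$reads_m - 5000), 200)
  cnt2 <- simulate_ngs_counts(31.05, 24347, 18113, 1e6, seed = 74)
  est <- ngs_ratio(cnt2$reads_m, cnt2$reads_f, 24347, 18113,
                   bootstrap_reps = 0)$ratio
  expect_lt(abs(est - 31.05) / 31.05, 0.02)
  expect_error(simulate_ngs_counts(1, 100, 100, 0), "positive")
})
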