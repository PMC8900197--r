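test_that("filter_bins masks by rule and rejects unanalyzable samples", {
  g <- small_genome
  s <- simulate_sample(karyotype("XX"),
                       source_profile("SCM", dropout_rate = 0), g, seed = 3)
  f <- quiet(filter_bins(s, g))
  # dropout-free high-depth sample: only Y bins (zero counts in XX) masked
  expect_true(all(f$mask[g$chrom != "Y"]))
  expect_true(all(!f$mask[g$chrom == "Y"]))

  # a bin with panel median below the floor is masked, exactly that bin
  panel <- small_panel
  panel2 <- panel
  target <- which(is_autosome(g$chrom))[5]
  panel2$median_diploid[target] <- 0
  f2 <- quiet(filter_bins(s, g, panel2))
  expect_false(f2$mask[target])
  expect_identical(f2$mask[-target], f$mask[-target] & panel$mask[-target])

  # 60% dropout -> not analyzable
  s_bad <- s
  set.seed(1)
  s_bad$counts[sample.int(s$n_bins, round(0.6 * s$n_bins))] <- 0L
  expect_error(quiet(filter_bins(s_bad, g)), "not analyzable")
})

test_that("gc_correct removes an injected GC trend", {
  g <- small_genome
  auto <- is_autosome(g$chrom)
  # deterministic depth with a pure linear GC bias
  depth <- round(100 * (1 + 2 * (g$gc - 0.4)))
  s <- structure(list(sample_id = "x", source = "SCM",
                      counts = as.integer(pmax(depth, 1)),
                      n_bins = nrow(g), total_reads = sum(depth)),
                 class = "bin_counts")
  f <- quiet(filter_bins(s, g))
  corr <- gc_correct(f, g)
  r_before <- cor(depth[auto], g$gc[auto])
  r_after <- cor(corr[auto], g$gc[auto])
  expect_gt(abs(r_before), 0.9)
  expect_lt(abs(r_after), 0.05)
  # mean autosomal depth preserved
  expect_equal(mean(corr[auto]), mean(depth[auto]), tolerance = 1e-6)
  # determinism: identical counts give identical corrections
  expect_identical(corr, gc_correct(f, g))
})

test_that("gc_correct with constant GC returns input up to a constant", {
  g <- small_genome
  g$gc <- 0.41
  s <- simulate_sample(karyotype("XX"), source_profile("SCM"),
                       small_genome, seed = 5)
  f <- quiet(filter_bins(s, g))
  corr <- gc_correct(f, g)
  valid <- attr(corr, "mask")
  expect_equal(corr[valid] / s$counts[valid],
               rep(corr[valid][1] / s$counts[valid][1], sum(valid)))
})

test_that("build_panel medians are robust and CV masking behaves", {
  g <- small_genome
  base <- rep(100, nrow(g))
  ident <- replicate(5, base, simplify = FALSE)
  pan <- build_panel(ident, g, sexes = rep("XX", 5))
  auto <- is_autosome(g$chrom)
  expect_true(all(pan$median_diploid[auto] == 1)) # autosomal median 1 after scaling
  expect_true(all(pan$mask[auto]))

  # one doubled bin in one of five samples leaves the median untouched
  pert <- ident
  pert[[3]][10] <- 200
  pan2 <- build_panel(pert, g, sexes = rep("XX", 5))
  expect_equal(pan2$median_diploid[10], pan$median_diploid[10])

  expect_error(build_panel(ident[1:2], g), "at least 3")

  # degenerate config: CV cutoff 0 masks everything with any variation,
  # and normalization then fails for lack of valid bins
  set.seed(8)
  noisy <- lapply(1:5, function(i) base + runif(nrow(g), 0, 5))
  pan3 <- build_panel(noisy, g, sexes = rep("XX", 5), cv_cutoff = 0)
  expect_true(all(!pan3$mask))
  corr <- base
  attr(corr, "mask") <- rep(TRUE, nrow(g))
  expect_error(reference_normalize(corr, pan3, g), "no valid bins")
})

test_that("reference_normalize anchors the autosomal median exactly at 1", {
  g <- small_genome
  panel <- small_panel
  s <- simulate_sample(karyotype("XY"), source_profile("SCM"), g, seed = 13)
  prof <- quiet(normalize_sample(s, g, panel))
  auto_valid <- prof$valid & is_autosome(g$chrom)
  expect_equal(median(prof$ratio[auto_valid]), 1, tolerance = 1e-12)

  # sample identical to the diploid panel median -> ratio 1 everywhere valid
  corr <- panel$median_diploid * 50
  attr(corr, "mask") <- panel$median_diploid > 0
  prof2 <- reference_normalize(corr, panel, g)
  expect_true(all(abs(prof2$ratio[prof2$valid] - 1) < 1e-9))
})

test_that("normalization is invariant to a constant scaling of counts", {
  g <- small_genome
  panel <- small_panel
  s <- simulate_sample(karyotype("XX"), source_profile("SCM"), g, seed = 17)
  s10 <- s
  s10$counts <- s$counts * 10L
  p1 <- quiet(normalize_sample(s, g, panel))
  p2 <- quiet(normalize_sample(s10, g, panel))
  expect_identical(p1$valid, p2$valid)
  expect_equal(p1$ratio[p1$valid], p2$ratio[p2$valid], tolerance = 1e-9)
})

test_that("simulate -> normalize recovers full-event dosage", {
  # loose sanity check at 10% genome scale (24 bins on chr2); the
  # full-scale 2% recovery guarantee is exercised in test-acceptance
  g <- small_genome
  panel <- small_panel
  tr <- karyotype("XY", whole_chromosome_event("2", 3, 1, g))
  s <- simulate_sample(tr, source_profile("SCM"), g, seed = 19)
  prof <- quiet(normalize_sample(s, g, panel))
  on2 <- g$chrom == "2" & prof$valid
  others <- is_autosome(g$chrom) & g$chrom != "2" & prof$valid
  base <- median(prof$ratio[others])
  expect_equal(mean(prof$ratio[on2]) / base, 1.5, tolerance = 0.08)
})

test_that("GC invariance holds across seeded replicates at full scale", {
  env <- full_env()
  g <- env$genome
  auto <- is_autosome(g$chrom)
  fails <- 0L
  for (seed in 1:10) {
    s <- simulate_sample(karyotype("XX"),
                         source_profile("SCM", gc_bias_strength = 1.5),
                         g, seed = 100 + seed)
    prof <- quiet(normalize_sample(s, g, env$panel))
    sel <- prof$valid & auto
    if (abs(cor(prof$ratio[sel], g$gc[sel])) >= 0.05) fails <- fails + 1L
  }
  expect_lte(fails, 1L) # |r| < 0.05 on at least 95% of replicates
})
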