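test_that("mosaic_fraction inverts the linear dosage model", {
  expect_equal(mosaic_fraction(1.5, "gain"), 1)   # full trisomy: +50% reads
  expect_equal(mosaic_fraction(0.5, "loss"), 1)   # full monosomy: -50%
  expect_equal(mosaic_fraction(1.0, "gain"), 0)
  expect_equal(mosaic_fraction(1.25, "gain"), 0.5)
  expect_equal(mosaic_fraction(1.3, "gain"), 0.6)
  expect_equal(mosaic_fraction(0.7, "loss"), 0.6)
  # direction inconsistent with the shift
  expect_equal(mosaic_fraction(1.3, "loss"), 0)
  expect_equal(mosaic_fraction(0.7, "gain"), 0)
  # saturation
  expect_equal(mosaic_fraction(2.0, "gain"), 1)
})

seg_row <- function(chrom, start, end, mean) {
  data.frame(chrom = chrom, start = start, end = end,
             n_bins = end - start, mean = mean, p = 0.001)
}

test_that("call_chromosome applies the 50% reporting floor and full cutoff", {
  expect_error(call_chromosome(seg_row("1", 0, 0, 1)[0, ]), "empty")

  # whole-chromosome full trisomy
  cc <- call_chromosome(seg_row("1", 0, 100, 1.5))
  expect_identical(cc$state, "gain")
  expect_identical(cc$copy_number, 3)
  # whole-chromosome r = 1.1 -> m = 0.2, below the reporting floor
  cc <- call_chromosome(seg_row("2", 0, 100, 1.1))
  expect_identical(cc$state, "euploid")
  # r = 1.3 -> reportable 60% mosaic gain
  cc <- call_chromosome(seg_row("3", 0, 100, 1.3))
  expect_identical(cc$state, "mosaic_gain")
  expect_equal(cc$m, 0.6)
  # r = 0.55 whole chromosome -> m = 0.9 >= full_cutoff -> full loss
  cc <- call_chromosome(seg_row("4", 0, 100, 0.55))
  expect_identical(cc$state, "loss")
  expect_identical(cc$copy_number, 1)

  # a deviating segment spanning less than whole_chrom_fraction
  segs <- rbind(seg_row("5", 0, 30, 1.52), seg_row("5", 30, 100, 1.0))
  cc <- call_chromosome(segs)
  expect_identical(cc$state, "segmental")
  # the same segment but below min_segment_bins is not reported
  segs <- rbind(seg_row("5", 0, 5, 1.52), seg_row("5", 5, 100, 1.0))
  cc <- call_chromosome(segs, min_segment_bins = 10)
  expect_identical(cc$state, "euploid")
})

fake_profile <- function(genome, x_ratio, y_ratio = NA) {
  ratio <- rep(1, nrow(genome))
  valid <- rep(TRUE, nrow(genome))
  ratio[genome$chrom == "X"] <- x_ratio
  if (is.na(y_ratio)) valid[genome$chrom == "Y"] <- FALSE
  else ratio[genome$chrom == "Y"] <- y_ratio
  structure(list(ratio = ratio, valid = valid, baseline = 1,
                 sample_id = "fake", source = "SCM", genome = genome),
            class = "copy_ratio_profile")
}

test_that("call_sex windows classify dosage correctly", {
  g <- small_genome
  expect_identical(as.character(call_sex(fake_profile(g, 1.0, NA))), "XX")
  expect_identical(as.character(call_sex(fake_profile(g, 0.5, 0.5))), "XY")
  # X dosage between the windows
  expect_identical(as.character(call_sex(fake_profile(g, 0.72, 0.5))),
                   "indeterminate")
})

test_that("sex is recovered from simulated samples", {
  g <- small_genome
  correct <- 0L
  for (i in 1:6) {
    sex <- if (i %% 2 == 0) "XX" else "XY"
    s <- simulate_sample(karyotype(sex), source_profile("SCM"), g,
                         seed = 600 + i)
    prof <- quiet(normalize_sample(s, g, small_panel))
    if (identical(as.character(call_sex(prof)), sex)) correct <- correct + 1L
  }
  expect_identical(correct, 6L)
})

test_that("classify_sample groups calls and formats karyotypes", {
  mk_call <- function(chrom, state, cn = 2, m = NA, dir = "gain") {
    structure(list(chrom = chrom, state = state, copy_number = cn, m = m,
                   direction = dir,
                   segment = seg_row(chrom, 0, 50, cn / 2)),
              class = "chromosome_call")
  }
  eu <- lapply(as.character(1:22), mk_call, state = "euploid")
  pc <- classify_sample(eu, sex = "XY", sample_id = "a")
  expect_identical(pc$classification, "euploid")
  expect_identical(pc$karyotype, "46,XY")

  tri <- eu
  tri[[21]] <- mk_call("21", "gain", cn = 3)
  pc <- classify_sample(tri, sex = "XY")
  expect_identical(pc$classification, "aneuploid")
  expect_identical(pc$karyotype, "47,XY,+21")

  mono <- eu
  mono[[16]] <- mk_call("16", "loss", cn = 1, dir = "loss")
  pc <- classify_sample(mono, sex = "XX")
  expect_identical(pc$karyotype, "45,XX,-16")

  mos <- eu
  mos[[16]] <- mk_call("16", "mosaic_loss", cn = 1.4, m = 0.6, dir = "loss")
  pc <- classify_sample(mos, sex = "XX")
  expect_identical(pc$classification, "aneuploid")
  expect_match(pc$karyotype, "-16")
  expect_match(pc$karyotype, "0.6", fixed = TRUE)

  pc <- classify_sample(eu, sex = "XY", technical_failure = TRUE)
  expect_identical(pc$classification, "no_result")
})

test_that("analyze_sample flags unanalyzable input as no_result", {
  g <- small_genome
  s <- simulate_sample(karyotype("XX"), source_profile("SCM"), g, seed = 71)
  set.seed(2)
  s$counts[sample.int(s$n_bins, round(0.7 * s$n_bins))] <- 0L
  pc <- quiet(analyze_sample(s, g, small_panel))
  expect_identical(pc$classification, "no_result")
})

test_that("estimated mosaic fraction increases with the simulated fraction", {
  g <- small_genome
  est <- vapply(c(0.3, 0.5, 0.7, 0.9), function(m) {
    vals <- vapply(1:6, function(i) {
      tr <- karyotype("XY", whole_chromosome_event("4", 3, m, g))
      s <- simulate_sample(tr, source_profile("SCM"), g,
                           seed = round(1e4 * m) + i)
      prof <- quiet(normalize_sample(s, g, small_panel))
      r4 <- mean(prof$ratio[g$chrom == "4" & prof$valid])
      mosaic_fraction(r4, "gain")
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_equal(est, c(0.3, 0.5, 0.7, 0.9), tolerance = 0.15)
})
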