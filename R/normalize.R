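#' Filter bins of a counts vector before normalization
#'
#' Masks bins that are (a) flagged unusable in the genome, (b) outside the
#' allowed GC range, (c) below the reference panel's minimum median depth
#' (when a panel is supplied), or (d) zero-count (dropout). If more than
#' half of the autosomal bins end up masked the sample is rejected as not
#' analyzable, mirroring the technical-failure category of liquid-biopsy
#' screening (samples without reliable sequencing data yield no result).
#'
#' @param counts A `bin_counts` object.
#' @param genome Matching `genome_bins`.
#' @param panel Optional `reference_panel` (see [build_panel()]).
#' @param gc_range Length-2 numeric, bins with GC outside are masked.
#' @param min_panel_median Panel median depth below which a bin is masked.
#' @param max_masked_fraction Autosomal masked fraction above which the
#'   sample is rejected (default 0.5).
#' @return The `bin_counts` with a logical `mask` element added (TRUE =
#'   keep).
#' @export
filter_bins <- function(counts, genome, panel = NULL,
                        gc_range = c(0.2, 0.8), min_panel_median = 0.1,
                        max_masked_fraction = 0.5) {
  .check_genome(genome)
  stopifnot(inherits(counts, "bin_counts"),
            counts$n_bins == nrow(genome))
  mask <- genome$usable &
    genome$gc >= gc_range[1] & genome$gc <= gc_range[2] &
    counts$counts > 0L
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "reference_panel"),
              length(panel$median_diploid) == nrow(genome))
    mask <- mask & panel$mask &
      !is.na(panel$median_diploid) &
      panel$median_diploid >= min_panel_median
  }
  auto <- is_autosome(genome$chrom)
  frac_masked <- mean(!mask[auto])
  message(sprintf("filter_bins: masked %d of %d bins (%.1f%% of autosomal)",
                  sum(!mask), length(mask), 100 * frac_masked))
  if (frac_masked > max_masked_fraction)
    stop("sample not analyzable: ",
         sprintf("%.1f%% of autosomal bins masked", 100 * frac_masked))
  counts$mask <- mask
  counts
}

#' GC-correct masked bin counts
#'
#' Fits a smooth trend of log depth versus GC over the valid autosomal
#' bins (loess, robust symmetric family with two iterations) and divides
#' it out of every bin, preserving the mean autosomal depth. Bins whose
#' GC falls outside the fitted range are corrected with the nearest fitted
#' value.
#'
#' @param counts A masked `bin_counts` (from [filter_bins()]; an unmasked
#'   object gets an all-TRUE mask).
#' @param genome Matching `genome_bins`.
#' @param span Loess span (default 0.3).
#' @return Numeric vector of corrected depths (NA at masked bins), with
#'   the mask as attribute `"mask"`.
#' @export
gc_correct <- function(counts, genome, span = 0.3) {
  .check_genome(genome)
  stopifnot(inherits(counts, "bin_counts"))
  mask <- counts$mask %||% rep(TRUE, counts$n_bins)
  depth <- as.numeric(counts$counts)
  if (all(depth[mask] == 0)) stop("all valid bins have zero counts")
  valid_auto <- mask & is_autosome(genome$chrom) & depth > 0
  if (sum(valid_auto) < 100)
    stop("need at least 100 valid autosomal bins for GC correction")

  if (sd(genome$gc[valid_auto]) < 1e-6) {
    # constant GC: no trend to remove
    corrected <- depth
    corrected[!mask] <- NA_real_
    attr(corrected, "mask") <- mask
    return(corrected)
  }
  # two-pass fit: remove per-chromosome median log-shifts (whole-
  # chromosome dosage changes) before estimating the GC trend, so an
  # aneuploid chromosome cannot drag the trend toward itself
  y <- log(depth[valid_auto])
  gc_fit <- genome$gc[valid_auto]
  chrom_fit <- genome$chrom[valid_auto]
  fit1 <- loess(y ~ gc_fit, span = span, degree = 2,
                family = "symmetric",
                control = loess.control(iterations = 3))
  resid_med <- tapply(y - fitted(fit1), chrom_fit, median)
  # only offsets of dosage magnitude are removed: a reportable event
  # shifts a chromosome by >= log(1.25) ~ 0.22, GC-driven chromosome
  # offsets are much smaller
  resid_med[abs(resid_med) <= 0.15] <- 0
  y_adj <- y - resid_med[chrom_fit]
  fit <- loess(y_adj ~ gc_fit, span = span, degree = 2,
               family = "symmetric",
               control = loess.control(iterations = 3))
  grid <- seq(min(gc_fit), max(gc_fit), length.out = 200)
  trend <- predict(fit, newdata = data.frame(gc_fit = grid))
  # nearest-value extrapolation outside the autosomal GC range
  factor_log <- approx(grid, trend, xout = genome$gc, rule = 2)$y
  factor_log <- factor_log - mean(factor_log[valid_auto])

  corrected <- depth / exp(factor_log)
  # preserve mean autosomal depth
  corrected <- corrected *
    mean(depth[valid_auto]) / mean(corrected[valid_auto])
  corrected[!mask] <- NA_real_
  attr(corrected, "mask") <- mask
  corrected
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a reference normalization panel from euploid samples
#'
#' Each GC-corrected sample is scaled to autosomal median 1, then per-bin
#' medians are taken. Autosomal medians use all panel samples; the X
#' median uses the 46,XX samples (two X copies) and the Y diploid-scale
#' reference is twice the 46,XY samples' median (one Y copy), so the
#' stored `median_diploid` is everywhere the depth expected from two
#' copies. Bins whose coefficient of variation across panel samples
#' exceeds `cv_cutoff`, or whose median is non-positive, are masked.
#'
#' @param panel_depths List of GC-corrected depth vectors (from
#'   [gc_correct()]), one per euploid panel sample.
#' @param genome Matching `genome_bins`.
#' @param sexes Character vector (`"XX"`/`"XY"`) per panel sample.
#' @param cv_cutoff Coefficient-of-variation mask cutoff (default 0.3).
#' @return A `reference_panel`: list with `median_diploid`, `mask`,
#'   `cv`, `n_samples`, `sexes`.
#' @export
build_panel <- function(panel_depths, genome, sexes = NULL,
                        cv_cutoff = 0.3) {
  .check_genome(genome)
  if (length(panel_depths) < 3) stop("need at least 3 panel samples")
  if (is.null(sexes)) sexes <- rep(c("XX", "XY"),
                                   length.out = length(panel_depths))
  stopifnot(length(sexes) == length(panel_depths),
            all(sexes %in% c("XX", "XY")))

  auto <- is_autosome(genome$chrom)
  norm <- lapply(panel_depths, function(d) {
    stopifnot(length(d) == nrow(genome))
    d / median(d[auto], na.rm = TRUE)
  })
  mat <- do.call(cbind, norm)

  row_med <- function(cols) {
    if (length(cols) == 0L) return(rep(NA_real_, nrow(mat)))
    apply(mat[, cols, drop = FALSE], 1L, median, na.rm = TRUE)
  }
  med_all <- row_med(seq_along(norm))
  med_xx <- row_med(which(sexes == "XX"))
  med_xy <- row_med(which(sexes == "XY"))

  median_diploid <- med_all
  x_bins <- genome$chrom == "X"
  y_bins <- genome$chrom == "Y"
  median_diploid[x_bins] <- med_xx[x_bins]
  median_diploid[y_bins] <- 2 * med_xy[y_bins]
  median_diploid[is.na(median_diploid)] <- 0

  row_cv <- function(rows, cols) {
    apply(mat[rows, cols, drop = FALSE], 1L, function(r) {
      m <- mean(r, na.rm = TRUE)
      if (!is.finite(m) || m <= 0) return(Inf)
      sd(r, na.rm = TRUE) / m
    })
  }
  cv <- row_cv(seq_len(nrow(mat)), seq_along(norm))
  # sex-chromosome dosage differs between XX and XY panel samples, so
  # their variability is judged within the matching sex only
  if (any(x_bins) && sum(sexes == "XX") >= 2)
    cv[x_bins] <- row_cv(x_bins, which(sexes == "XX"))
  if (any(y_bins) && sum(sexes == "XY") >= 2)
    cv[y_bins] <- row_cv(y_bins, which(sexes == "XY"))
  mask <- is.finite(cv) & cv <= cv_cutoff & median_diploid > 0
  structure(list(median_diploid = median_diploid, mask = mask, cv = cv,
                 n_samples = length(panel_depths), sexes = sexes),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d samples, %d/%d bins usable\n",
              x$n_samples, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Read and write a reference panel
#'
#' The per-bin medians and CVs go to a TSV; the mask, sample count and
#' panel sexes go to a JSON sidecar (`<path>.json`).
#'
#' @param panel A `reference_panel`.
#' @param path TSV file path (sidecar written alongside).
#' @return `write_panel` returns `path` invisibly; `read_panel` returns
#'   the `reference_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  write.table(data.frame(median_diploid = panel$median_diploid,
                         cv = panel$cv),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mask = panel$mask,
                            n_samples = panel$n_samples,
                            sexes = panel$sexes),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing panel sidecar: ", sidecar)
  tab <- read.delim(path, sep = "\t")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(median_diploid = tab$median_diploid,
                 mask = as.logical(meta$mask), cv = tab$cv,
                 n_samples = meta$n_samples, sexes = meta$sexes),
            class = "reference_panel")
}

#' Normalize a sample against the reference panel
#'
#' Per-bin copy ratio `r_b = depth_b / panel_median_b` (diploid-scale
#' panel), anchored so the median over valid autosomal bins is exactly 1.
#' The autosomal median is a robust baseline: a single aneuploid
#' chromosome barely moves it, whereas it would shift the mean. Under
#' this anchoring a full trisomy sits at `r = 1.5` (a 50% increase over
#' the disomic baseline) and a full monosomy at `r = 0.5`; on a 46,XX
#' diploid scale an XY sample shows X and Y near 0.5.
#'
#' @param corrected GC-corrected depths from [gc_correct()].
#' @param panel A `reference_panel` sharing the same `genome_bins`.
#' @param genome Matching `genome_bins`.
#' @param sample_id Sample identifier carried into the profile.
#' @param source Source tag carried into the profile.
#' @return A `copy_ratio_profile`: list with `ratio` (NA at invalid bins),
#'   `valid`, `baseline` (autosomal median depth ratio before anchoring),
#'   `sample_id`, `source`, `genome`.
#' @export
reference_normalize <- function(corrected, panel, genome,
                                sample_id = "sample", source = "unknown") {
  .check_genome(genome)
  stopifnot(inherits(panel, "reference_panel"),
            length(corrected) == nrow(genome),
            length(panel$median_diploid) == nrow(genome))
  mask <- attr(corrected, "mask") %||% !is.na(corrected)
  valid <- mask & panel$mask & panel$median_diploid > 0
  if (!any(valid)) stop("no valid bins after intersecting sample and panel masks")

  ratio <- as.numeric(corrected) / panel$median_diploid
  ratio[!valid] <- NA_real_
  auto_valid <- valid & is_autosome(genome$chrom)
  if (!any(auto_valid)) stop("no valid autosomal bins to anchor the baseline")
  baseline <- median(ratio[auto_valid])
  if (!is.finite(baseline) || baseline <= 0)
    stop("degenerate autosomal baseline")
  ratio <- ratio / baseline

  structure(list(ratio = ratio, valid = valid, baseline = baseline,
                 sample_id = sample_id, source = source, genome = genome),
            class = "copy_ratio_profile")
}

#' @export
print.copy_ratio_profile <- function(x, ...) {
  cat(sprintf("copy_ratio_profile '%s' [%s]: %d/%d valid bins\n",
              x$sample_id, x$source, sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Per-chromosome mean copy ratio
#'
#' @param profile A `copy_ratio_profile`.
#' @return Named numeric vector of mean valid-bin ratios per chromosome.
#' @export
chromosome_mean_ratio <- function(profile) {
  stopifnot(inherits(profile, "copy_ratio_profile"))
  g <- profile$genome
  vapply(chromosome_names(), function(ch) {
    sel <- g$chrom == ch & profile$valid
    if (!any(sel)) return(NA_real_)
    mean(profile$ratio[sel])
  }, numeric(1))
}

#' Run filtering, GC correction and reference normalization in one step
#'
#' @param counts A `bin_counts`.
#' @param genome Matching `genome_bins`.
#' @param panel A `reference_panel`.
#' @param config A [screen_config()] list (normalization settings).
#' @return A `copy_ratio_profile`.
#' @export
normalize_sample <- function(counts, genome, panel,
                             config = screen_config()) {
  filtered <- filter_bins(counts, genome, panel,
                          gc_range = config$gc_range,
                          min_panel_median = config$min_panel_median,
                          max_masked_fraction = config$max_masked_fraction)
  corrected <- gc_correct(filtered, genome, span = config$gc_span)
  reference_normalize(corrected, panel, genome,
                      sample_id = counts$sample_id,
                      source = counts$source)
}

#' Build a reference panel from raw panel counts
#'
#' Convenience wrapper: filters and GC-corrects each euploid panel sample,
#' then calls [build_panel()].
#'
#' @param panel_counts List of `bin_counts` for euploid samples.
#' @param genome Matching `genome_bins`.
#' @param sexes Character vector of panel sample sexes.
#' @param config A [screen_config()].
#' @return A `reference_panel`.
#' @export
build_panel_from_counts <- function(panel_counts, genome, sexes = NULL,
                                    config = screen_config()) {
  depths <- lapply(panel_counts, function(s) {
    f <- filter_bins(s, genome, panel = NULL,
                     gc_range = config$gc_range,
                     max_masked_fraction = config$max_masked_fraction)
    gc_correct(f, genome, span = config$gc_span)
  })
  build_panel(depths, genome, sexes = sexes,
              cv_cutoff = config$panel_cv_cutoff)
}
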