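#' Mosaic fraction implied by a copy-ratio shift
#'
#' Under the linear dosage model a mosaic single-copy event with cell
#' fraction `m` shifts the copy ratio to `1 + m/2` (gain) or `1 - m/2`
#' (loss), so `m = clamp(2 * |r - 1|, 0, 1)`. If the direction is
#' inconsistent with the sign of `r - 1` the fraction is 0.
#'
#' @param r Mean copy ratio of the segment or chromosome (>= 0).
#' @param direction `"gain"` or `"loss"`.
#' @return Mosaic fraction in \[0, 1\].
#' @examples
#' mosaic_fraction(1.5, "gain")   # 1: full trisomy
#' mosaic_fraction(1.25, "gain")  # 0.5
#' @export
mosaic_fraction <- function(r, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(r), r >= 0)
  if ((direction == "gain" && r < 1) || (direction == "loss" && r > 1))
    return(0)
  min(max(2 * abs(r - 1), 0), 1)
}

#' Call one chromosome from its segments
#'
#' Applies the reporting rules of mosaic-aware aneuploidy screening: the
#' dominant deviating segment (largest |mean - 1| among segments of at
#' least `min_segment_bins` bins) drives the call. If it spans at least
#' `whole_chrom_fraction` of the chromosome's bins the call is
#' whole-chromosome: mosaic fraction `m >= full_cutoff` yields a full
#' gain/loss with integer copy number, `0.5 <= m < full_cutoff` a mosaic
#' call with its fraction, and `m < 0.5` is below the reporting floor
#' (mosaicism above 50% is reported) so the chromosome is called euploid.
#' A smaller deviating segment with `m >= 0.5` yields a `segmental` call.
#'
#' @param segments Segment rows for one chromosome (from
#'   [segment_genome()]).
#' @param mosaic_floor Minimum reportable mosaic fraction (default 0.5).
#' @param full_cutoff Fraction above which an event is printed as a full
#'   integer-copy aneuploidy (default 0.8).
#' @param whole_chrom_fraction Span fraction above which a segment counts
#'   as whole-chromosome (default 0.8).
#' @param min_segment_bins Minimum bins for a reportable segmental event
#'   (default 10).
#' @return A `chromosome_call`: list with `chrom`, `state` (euploid,
#'   gain, loss, mosaic_gain, mosaic_loss, segmental), `copy_number`
#'   (2 * r, real), `m` (reported fraction or NA), `segment` (driving
#'   segment row).
#' @export
call_chromosome <- function(segments, mosaic_floor = 0.5,
                            full_cutoff = 0.8,
                            whole_chrom_fraction = 0.8,
                            min_segment_bins = 10L) {
  if (is.null(segments) || nrow(segments) == 0L)
    stop("empty segment list")
  chrom <- segments$chrom[1L]
  stopifnot(all(segments$chrom == chrom))
  n_total <- sum(segments$n_bins)

  eligible <- segments[segments$n_bins >= min_segment_bins, , drop = FALSE]
  if (nrow(eligible) == 0L) eligible <- segments
  dom <- eligible[which.max(abs(eligible$mean - 1)), , drop = FALSE]
  r <- dom$mean
  direction <- if (r >= 1) "gain" else "loss"
  m <- mosaic_fraction(r, direction)
  span <- dom$n_bins / n_total

  state <- "euploid"
  report_m <- NA_real_
  if (m >= mosaic_floor && dom$n_bins >= min_segment_bins) {
    if (span >= whole_chrom_fraction) {
      if (m >= full_cutoff) {
        state <- direction
      } else {
        state <- paste0("mosaic_", direction)
        report_m <- m
      }
    } else {
      state <- "segmental"
      report_m <- m
    }
  }
  copy_number <- 2 * r
  if (state %in% c("gain", "loss"))
    copy_number <- max(0, round(2 * r))
  structure(list(chrom = chrom, state = state, copy_number = copy_number,
                 m = report_m, direction = direction, segment = dom),
            class = "chromosome_call")
}

#' Call the sample's sex from X and Y dosage
#'
#' Ratios are on the 46,XX diploid scale (see [reference_normalize()]):
#' an XX sample shows X near 1 and Y near 0; an XY sample shows X and Y
#' both near 0.5. Mean ratios falling outside both windows give an
#' indeterminate call.
#'
#' @param profile A `copy_ratio_profile`.
#' @param x_xx_window,x_xy_window Acceptance windows for the X mean ratio
#'   (defaults `[0.8, 1.2]` and `[0.35, 0.65]`).
#' @param y_xx_max Maximum Y mean ratio for an XX call (default 0.2).
#' @param y_xy_window Window for the Y mean ratio in an XY call
#'   (default `[0.3, 0.7]`).
#' @return `"XX"`, `"XY"` or `"indeterminate"`, with attributes
#'   `x_ratio`, `y_ratio`.
#' @export
call_sex <- function(profile, x_xx_window = c(0.8, 1.2),
                     x_xy_window = c(0.35, 0.65), y_xx_max = 0.2,
                     y_xy_window = c(0.3, 0.7)) {
  stopifnot(inherits(profile, "copy_ratio_profile"))
  g <- profile$genome
  x_sel <- g$chrom == "X" & profile$valid
  if (!any(x_sel)) {
    out <- "indeterminate"
    attr(out, "x_ratio") <- NA_real_
    attr(out, "y_ratio") <- NA_real_
    return(out)
  }
  x_ratio <- mean(profile$ratio[x_sel])
  # Y bins are invalid for XX samples (zero counts); treat missing Y as
  # zero dosage rather than unknown
  y_sel <- g$chrom == "Y" & profile$valid
  y_ratio <- if (any(y_sel)) mean(profile$ratio[y_sel]) else 0

  out <- if (x_ratio >= x_xx_window[1] && x_ratio <= x_xx_window[2] &&
             y_ratio <= y_xx_max) "XX"
  else if (x_ratio >= x_xy_window[1] && x_ratio <= x_xy_window[2] &&
           y_ratio >= y_xy_window[1] && y_ratio <= y_xy_window[2]) "XY"
  else "indeterminate"
  attr(out, "x_ratio") <- x_ratio
  attr(out, "y_ratio") <- y_ratio
  out
}

#' Classify a sample from its chromosome calls
#'
#' Any non-euploid chromosome call makes the sample aneuploid/mosaic (the
#' two-category grouping used for concordance scoring); a technical
#' failure gives `no_result`. The karyotype string follows ISCN-like
#' conventions, e.g. `"46,XY"`, `"47,XY,+21"`, `"45,XX,-16"`,
#' `"46,XX,+16[0.6]"` for a 60% mosaic gain, and `"46,XY,del(5)[0.8]"`
#' for a segmental loss.
#'
#' @param chrom_calls List of `chromosome_call` objects (one per called
#'   chromosome).
#' @param sex Sex call from [call_sex()].
#' @param sample_id Sample identifier.
#' @param technical_failure Logical; `TRUE` forces `no_result`.
#' @return A `ploidy_call`: list with `sample_id`, `classification`
#'   (`"euploid"`, `"aneuploid"`, `"no_result"`), `karyotype`, `sex`,
#'   `chromosomes` (per-chromosome summary data frame).
#' @export
classify_sample <- function(chrom_calls, sex = "indeterminate",
                            sample_id = "sample",
                            technical_failure = FALSE) {
  tab <- do.call(rbind, lapply(chrom_calls, function(cc) {
    data.frame(chrom = cc$chrom, state = cc$state,
               copy_number = cc$copy_number,
               m = ifelse(is.na(cc$m), NA_real_, cc$m),
               mean_ratio = cc$segment$mean,
               stringsAsFactors = FALSE)
  }))
  if (technical_failure) {
    return(structure(list(sample_id = sample_id,
                          classification = "no_result",
                          karyotype = NA_character_,
                          sex = "indeterminate", chromosomes = tab),
                     class = "ploidy_call"))
  }
  abnormal <- vapply(chrom_calls, function(cc) cc$state != "euploid",
                     logical(1))
  classification <- if (any(abnormal)) "aneuploid" else "euploid"

  count <- 46L
  parts <- character(0)
  for (cc in chrom_calls) {
    if (cc$state %in% c("gain", "loss")) {
      count <- count + (as.integer(cc$copy_number) - 2L)
      parts <- c(parts, paste0(if (cc$state == "gain") "+" else "-",
                               cc$chrom))
    } else if (cc$state %in% c("mosaic_gain", "mosaic_loss")) {
      parts <- c(parts, sprintf("%s%s[%.2g]",
                                if (cc$state == "mosaic_gain") "+" else "-",
                                cc$chrom, cc$m))
    } else if (cc$state == "segmental") {
      parts <- c(parts, sprintf("%s(%s)[%.2g]",
                                if (cc$direction == "gain") "dup" else "del",
                                cc$chrom, cc$m))
    }
  }
  sex_tag <- if (sex %in% c("XX", "XY")) sex else "??"
  karyo <- paste(c(sprintf("%d,%s", count, sex_tag), parts), collapse = ",")
  structure(list(sample_id = sample_id, classification = classification,
                 karyotype = karyo, sex = as.character(sex),
                 chromosomes = tab),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy_call '%s': %s (%s), sex %s\n", x$sample_id,
              x$classification, x$karyotype %||% "-", x$sex))
  invisible(x)
}

#' Analyze one sample end to end
#'
#' Runs bin filtering, GC correction, reference normalization, circular
#' binary segmentation, sex calling and per-chromosome classification.
#' Samples failing QC (too many masked bins / not analyzable) come back
#' as `no_result` rather than raising an error.
#'
#' @param counts A `bin_counts` object.
#' @param genome Matching `genome_bins`.
#' @param panel A `reference_panel`.
#' @param config A [screen_config()].
#' @param seed Integer seed for segmentation permutations.
#' @return A `ploidy_call` with attributes `profile` and `segments`
#'   (NULL on technical failure).
#' @export
analyze_sample <- function(counts, genome, panel,
                           config = screen_config(), seed = 1L) {
  profile <- tryCatch(
    normalize_sample(counts, genome, panel, config),
    error = function(e) e
  )
  if (inherits(profile, "error")) {
    message("sample ", counts$sample_id, ": ", conditionMessage(profile))
    return(classify_sample(list(), sample_id = counts$sample_id,
                           technical_failure = TRUE))
  }
  sex <- call_sex(profile,
                  x_xx_window = config$x_xx_window,
                  x_xy_window = config$x_xy_window,
                  y_xx_max = config$y_xx_max,
                  y_xy_window = config$y_xy_window)

  # rescale sex chromosomes to per-copy-pair units so a normal XY sample
  # reads ratio 1 on X and Y
  if (identical(as.character(sex), "XY")) {
    sex_bins <- profile$genome$chrom %in% c("X", "Y")
    profile$ratio[sex_bins] <- profile$ratio[sex_bins] * 2
  }

  segs <- segment_genome(profile, alpha = config$alpha,
                         n_perm = config$n_perm,
                         min_width = config$min_width,
                         merge_threshold = config$merge_threshold,
                         seed = seed)
  call_one <- function(ch) {
    sub <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    call_chromosome(sub, mosaic_floor = config$mosaic_floor,
                    full_cutoff = config$full_cutoff,
                    whole_chrom_fraction = config$whole_chrom_fraction,
                    min_segment_bins = config$min_segment_bins)
  }
  called_chroms <- chromosome_names()[1:22]
  if (identical(as.character(sex), "XY") || identical(as.character(sex), "XX")) {
    sex_chroms <- if (identical(as.character(sex), "XX")) "X" else c("X", "Y")
    called_chroms <- c(called_chroms, sex_chroms)
  }
  chrom_calls <- Filter(Negate(is.null), lapply(called_chroms, call_one))
  out <- classify_sample(chrom_calls, sex = sex,
                         sample_id = counts$sample_id)
  attr(out, "profile") <- profile
  attr(out, "segments") <- segs
  out
}

#' Analyze a cohort of samples
#'
#' @param counts_list List of `bin_counts`.
#' @param genome,panel,config As in [analyze_sample()].
#' @param seed Integer seed (one sub-seed per sample).
#' @return List of `ploidy_call` objects.
#' @export
analyze_cohort <- function(counts_list, genome, panel,
                           config = screen_config(), seed = 1L) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, length(counts_list))
  lapply(seq_along(counts_list), function(i) {
    analyze_sample(counts_list[[i]], genome, panel, config,
                   seed = seeds[i])
  })
}
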