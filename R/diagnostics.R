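#' Confusion matrix of calls against a gold standard
#'
#' The positive class is aneuploid/mosaic, matching the two-category
#' grouping (euploid vs aneuploid/mosaic) used to score liquid-biopsy
#' karyotyping against an ICM or whole-blastocyst reference. Samples
#' whose call is `no_result` are excluded from the matrix with a logged
#' count.
#'
#' @param calls Data frame with columns `sample_id` and `class`, or a
#'   list of `ploidy_call` objects. Classes are matched case-insensitively;
#'   anything starting with "aneuploid" or "mosaic" counts as positive.
#' @param truths Data frame with columns `sample_id` and `class` holding
#'   the reference classifications.
#' @return A `confusion_matrix`: list with `TP`, `FP`, `TN`, `FN`, `n`,
#'   `n_excluded`.
#' @export
confusion_matrix <- function(calls, truths) {
  calls <- .as_class_table(calls)
  truths <- .as_class_table(truths)
  if (!setequal(calls$sample_id, truths$sample_id) ||
      anyDuplicated(calls$sample_id) || anyDuplicated(truths$sample_id))
    stop("calls and truths must cover the same unique sample ids")
  truths <- truths[match(calls$sample_id, truths$sample_id), ]

  keep <- calls$class != "no_result" & truths$class != "no_result"
  if (any(!keep))
    message("confusion_matrix: excluded ", sum(!keep),
            " no_result sample(s)")
  call_pos <- .is_positive(calls$class[keep])
  truth_pos <- .is_positive(truths$class[keep])
  cm <- list(TP = sum(call_pos & truth_pos),
             FP = sum(call_pos & !truth_pos),
             TN = sum(!call_pos & !truth_pos),
             FN = sum(!call_pos & truth_pos))
  cm$n <- cm$TP + cm$FP + cm$TN + cm$FN
  cm$n_excluded <- sum(!keep)
  structure(cm, class = "confusion_matrix")
}

.as_class_table <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "ploidy_call"))) {
    x <- data.frame(
      sample_id = vapply(x, `[[`, character(1), "sample_id"),
      class = vapply(x, `[[`, character(1), "classification"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("sample_id", "class") %in% names(x)))
  x$class <- tolower(as.character(x$class))
  x
}

.is_positive <- function(class) {
  grepl("^(aneuploid|mosaic)", class)
}

#' Build a confusion matrix directly from counts
#'
#' @param TP,FP,TN,FN Non-negative integer cell counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 n = TP + FP + TN + FN, n_excluded = 0L),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix (positive = aneuploid/mosaic): TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$n))
  invisible(x)
}

#' Diagnostic metrics of a confusion matrix
#'
#' Computes, with aneuploid/mosaic as the positive class:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), negative predictive
#' value TN/(TN+FN), positive predictive value TP/(TP+FP), and the
#' two-category concordance (TP+TN)/n. A metric whose denominator is
#' zero is `NA` (undefined), never 0.
#'
#' @param cm A `confusion_matrix`.
#' @return A `diagnostic_summary`: list of the five metrics (fractions),
#'   their numerators/denominators, and display percentages rounded
#'   half-up to one decimal.
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) {
    if (den == 0) list(value = NA_real_, num = num, den = den,
                       pct = NA_real_)
    else list(value = num / den, num = num, den = den,
              pct = round_half_up(100 * num / den, 1))
  }
  structure(list(
    sensitivity = frac(cm$TP, cm$TP + cm$FN),
    specificity = frac(cm$TN, cm$TN + cm$FP),
    npv = frac(cm$TN, cm$TN + cm$FN),
    ppv = frac(cm$TP, cm$TP + cm$FP),
    concordance = frac(cm$TP + cm$TN, cm$n),
    cm = cm
  ), class = "diagnostic_summary")
}

#' Round half away from zero
#'
#' Display rounding matching the convention of printed clinical tables
#' (41/80 -> 51.3%), unlike [round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  for (nm in c("sensitivity", "specificity", "npv", "ppv", "concordance")) {
    f <- x[[nm]]
    if (is.na(f$value))
      cat(sprintf("%-12s undefined (0 denominator)\n", nm))
    else
      cat(sprintf("%-12s %.1f%% (%d/%d)\n", nm, f$pct, f$num, f$den))
  }
  invisible(x)
}

#' Pool two confusion matrices cellwise
#'
#' Subgroup matrices (e.g. scored against the inner-cell-mass reference
#' and against the whole-blastocyst reference) pool by cellwise addition
#' into the total-cohort matrix.
#'
#' @param cm_a,cm_b `confusion_matrix` objects.
#' @return Pooled `confusion_matrix`.
#' @export
pool_matrices <- function(cm_a, cm_b) {
  stopifnot(inherits(cm_a, "confusion_matrix"),
            inherits(cm_b, "confusion_matrix"))
  confusion_counts(cm_a$TP + cm_b$TP, cm_a$FP + cm_b$FP,
                   cm_a$TN + cm_b$TN, cm_a$FN + cm_b$FN)
}

#' Ploidy or sex concordance between calls and reference
#'
#' Fraction of evaluable samples whose call matches the reference.
#' Indeterminate, `no_result` and `NA` entries (on either side) are
#' excluded from the denominator with a logged count.
#'
#' @param calls,truths Character vectors (aligned) or data frames with
#'   `sample_id` and `class` columns (matched by id).
#' @param mode `"ploidy"` (euploid vs aneuploid/mosaic grouping) or
#'   `"sex"` (exact label match).
#' @return List with `fraction`, `matches`, `evaluable`, `n_excluded`,
#'   `pct` (round-half-up, 1 decimal).
#' @export
concordance <- function(calls, truths, mode = c("ploidy", "sex")) {
  mode <- match.arg(mode)
  if (is.data.frame(calls) || is.data.frame(truths)) {
    calls <- .as_class_table(calls)
    truths <- .as_class_table(truths)
    if (!setequal(calls$sample_id, truths$sample_id))
      stop("calls and truths must cover the same sample ids")
    truths <- truths[match(calls$sample_id, truths$sample_id), ]
    calls <- calls$class
    truths <- truths$class
  }
  stopifnot(length(calls) == length(truths))
  calls <- tolower(as.character(calls))
  truths <- tolower(as.character(truths))
  bad <- c("no_result", "indeterminate", "na", "")
  keep <- !(calls %in% bad) & !(truths %in% bad) &
    !is.na(calls) & !is.na(truths)
  if (any(!keep))
    message("concordance: excluded ", sum(!keep), " sample(s)")
  if (!any(keep)) stop("no evaluable samples")
  calls <- calls[keep]
  truths <- truths[keep]
  matches <- if (mode == "ploidy")
    sum(.is_positive(calls) == .is_positive(truths))
  else sum(calls == truths)
  evaluable <- sum(keep)
  list(fraction = matches / evaluable, matches = matches,
       evaluable = evaluable, n_excluded = sum(!keep),
       pct = round_half_up(100 * matches / evaluable, 1))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Textbook Pearson statistic on the table `rbind(c(a, b), c(c, d))`,
#' with optional Yates continuity correction, and the p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d).
#' @param correct Apply the Yates continuity correction (default TRUE,
#'   the usual convention for 2x2 tables).
#' @return List with `statistic`, `p`, `correct`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  n <- sum(cells)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("chi-square undefined: zero row or column margin")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       correct = correct)
}

#' Table-style diagnostic report for two assays against a reference
#'
#' Scores each assay's calls against the shared gold-standard truth,
#' overall and within reference subgroups, mirroring the layout of
#' published SCM/BF validation tables: one row per metric, one column
#' per assay and subgroup, plus chi-square comparisons between assays.
#'
#' @param sheets Named list of call data frames (`sample_id`, `class`),
#'   one per assay (e.g. `list(SCM = ..., BF = ...)`).
#' @param truth Data frame with `sample_id`, `class` and optionally a
#'   `reference` column defining subgroups (e.g. ICM / WB).
#' @return A `diagnostic_report`: list with per-assay, per-subgroup
#'   `diagnostic_summary` objects and pairwise chi-square p-values.
#' @export
diagnostic_report <- function(sheets, truth) {
  stopifnot(is.list(sheets), length(sheets) >= 1, !is.null(names(sheets)))
  subgroups <- list(total = truth)
  if ("reference" %in% names(truth)) {
    for (ref in unique(truth$reference))
      subgroups[[ref]] <- truth[truth$reference == ref, , drop = FALSE]
  }
  out <- list()
  for (sub in names(subgroups)) {
    tr <- subgroups[[sub]]
    out[[sub]] <- lapply(sheets, function(sheet) {
      sheet <- sheet[sheet$sample_id %in% tr$sample_id, , drop = FALSE]
      diagnostic_metrics(confusion_matrix(sheet, tr))
    })
  }
  comparisons <- list()
  if (length(sheets) == 2) {
    nms <- names(sheets)
    for (sub in names(subgroups)) {
      da <- out[[sub]][[nms[1]]]
      db <- out[[sub]][[nms[2]]]
      comparisons[[sub]] <- lapply(
        setNames(nm = c("sensitivity", "specificity", "npv", "ppv")),
        function(metric) {
          fa <- da[[metric]]; fb <- db[[metric]]
          if (is.na(fa$value) || is.na(fb$value)) return(NA_real_)
          chi_square_2x2(fa$num, fa$den - fa$num,
                         fb$num, fb$den - fb$num)$p
        })
    }
  }
  structure(list(metrics = out, comparisons = comparisons),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  for (sub in names(x$metrics)) {
    cat("==", sub, "==\n")
    for (assay in names(x$metrics[[sub]])) {
      cat("--", assay, "--\n")
      print(x$metrics[[sub]][[assay]])
    }
  }
  invisible(x)
}
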