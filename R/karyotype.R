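#' Construct a ground-truth sample karyotype
#'
#' A karyotype is the simulation ground truth: a sex and a list of
#' copy-number events. An empty event list is a euploid truth. Mosaic
#' fraction `m = 1` means a full (non-mosaic) event; `0 < m < 1` means the
#' stated fraction of cells carries the event, shifting the expected copy
#' ratio to `1 + m * (cn - 2) / 2` on a diploid background.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param events Data frame with columns `chrom`, `start_bin`, `end_bin`
#'   (bin indices within the chromosome, 0-based half-open; use
#'   [whole_chromosome_event()] for whole-chromosome aneuploidies),
#'   `cn` (integer copy number in 0,1,3,4) and `m` (mosaic fraction in
#'   (0, 1]). `NULL` or zero rows = euploid.
#' @return A `sample_karyotype` object.
#' @export
karyotype <- function(sex = c("XX", "XY"), events = NULL) {
  sex <- match.arg(sex)
  if (is.null(events))
    events <- data.frame(chrom = character(), start_bin = integer(),
                         end_bin = integer(), cn = integer(), m = numeric(),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start_bin", "end_bin", "cn", "m") %in%
                  names(events)))
  events$chrom <- as.character(events$chrom)
  if (nrow(events)) {
    if (!all(events$cn %in% c(0L, 1L, 3L, 4L)))
      stop("event copy numbers must be in {0, 1, 3, 4}")
    if (any(events$m <= 0 | events$m > 1))
      stop("mosaic fractions must lie in (0, 1]")
    if (any(events$start_bin < 0 | events$end_bin <= events$start_bin))
      stop("events must have end_bin > start_bin >= 0")
    by_chrom <- split(events, events$chrom)
    for (ev in by_chrom) {
      if (nrow(ev) > 1L) {
        ev <- ev[order(ev$start_bin), , drop = FALSE]
        if (any(ev$start_bin[-1L] < ev$end_bin[-nrow(ev)]))
          stop("events on chromosome ", ev$chrom[1L], " overlap")
      }
    }
  }
  structure(list(sex = sex, events = events), class = "sample_karyotype")
}

#' Whole-chromosome aneuploidy event
#'
#' @param chrom Chromosome label.
#' @param cn Copy number (0, 1, 3 or 4).
#' @param m Mosaic fraction in (0, 1]; 1 = full aneuploidy.
#' @param genome A `genome_bins` object (to determine the chromosome's bin
#'   count).
#' @return One-row event data frame suitable for [karyotype()].
#' @export
whole_chromosome_event <- function(chrom, cn, m = 1, genome) {
  .check_genome(genome)
  n <- sum(genome$chrom == chrom)
  if (n == 0L) stop("chromosome ", chrom, " not present in genome")
  data.frame(chrom = as.character(chrom), start_bin = 0L, end_bin = n,
             cn = as.integer(cn), m = m, stringsAsFactors = FALSE)
}

#' @export
print.sample_karyotype <- function(x, ...) {
  cat("sample_karyotype:", x$sex, "\n")
  if (nrow(x$events) == 0L) cat("  euploid (no events)\n")
  else print(x$events)
  invisible(x)
}

#' Expected per-bin copy number implied by a truth karyotype
#'
#' Baseline is 2 on autosomes; on X and Y it follows the sex (XX: X=2,
#' Y=0; XY: X=1, Y=1). A mosaic event with copy number `cn` and fraction
#' `m` gives effective copy number `base + m * (cn - base)`.
#'
#' @param truth A `sample_karyotype`.
#' @param genome A `genome_bins`.
#' @return Numeric vector of effective copy numbers, one per bin.
#' @export
expected_copy_number <- function(truth, genome) {
  .check_genome(genome)
  cn <- ifelse(is_autosome(genome$chrom), 2,
               ifelse(genome$chrom == "X",
                      if (truth$sex == "XX") 2 else 1,
                      if (truth$sex == "XX") 0 else 1))
  ev <- truth$events
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      on_chrom <- which(genome$chrom == ev$chrom[k])
      if (length(on_chrom) == 0L)
        stop("event chromosome ", ev$chrom[k], " not in genome")
      if (ev$end_bin[k] > length(on_chrom))
        stop("event on chromosome ", ev$chrom[k], " exceeds genome bins")
      hit <- on_chrom[seq(ev$start_bin[k] + 1L, ev$end_bin[k])]
      cn[hit] <- cn[hit] + ev$m[k] * (ev$cn[k] - cn[hit])
    }
  }
  cn
}
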