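#' @useDynLib nicscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rgamma rmultinom loess
#'   loess.control predict approx sd pchisq setNames
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

# Human-like chromosome lengths in Mb, compiled into the package so the
# binned coordinate system needs no external genome download.
.chrom_lengths_mb <- c(
  "1" = 249, "2" = 242, "3" = 198, "4" = 190, "5" = 182, "6" = 171,
  "7" = 159, "8" = 145, "9" = 138, "10" = 134, "11" = 135, "12" = 133,
  "13" = 114, "14" = 107, "15" = 102, "16" = 90, "17" = 83, "18" = 80,
  "19" = 59, "20" = 64, "21" = 47, "22" = 51, "X" = 156, "Y" = 57
)

#' Chromosome labels used by the binned genome
#'
#' @return Character vector `c("1", ..., "22", "X", "Y")`.
#' @export
chromosome_names <- function() names(.chrom_lengths_mb)

#' Autosome test
#'
#' @param chrom character vector of chromosome labels.
#' @return Logical vector, `TRUE` for chromosomes 1-22.
#' @export
is_autosome <- function(chrom) !(chrom %in% c("X", "Y"))

#' Build a binned genome coordinate system
#'
#' Tiles 24 human-like chromosomes (fixed built-in length table, 3086 Mb
#' total) into fixed-width bins and attaches a per-bin GC fraction drawn
#' from a seeded smooth process: a per-chromosome AR(1) walk around mean
#' 0.41 (autocorrelation 0.9, innovation sd 0.03), clipped to
#' \[0.2, 0.8\].
#' Any smooth heterogeneous GC field suffices to exercise GC correction;
#' no real-genome sequence is consulted.
#'
#' @param bin_width Bin width in bp (default 1e6, i.e. 1 Mb bins).
#' @param scale Fraction in (0, 1] shrinking every chromosome
#'   proportionally; useful for fast small-genome tests.
#' @param gc_seed Integer seed for the GC process (fixed default so two
#'   calls with equal arguments return identical genomes).
#' @return A `genome_bins` data frame with columns `chrom`, `start`,
#'   `end` (bp, 0-based half-open), `gc`, `usable`.
#' @examples
#' g <- build_genome(bin_width = 1e6, scale = 0.05)
#' table(g$chrom)[["21"]]
#' @export
build_genome <- function(bin_width = 1e6, scale = 1, gc_seed = 20220221L) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L)
  if (bin_width < 1e4) stop("bin_width must be at least 10,000 bp")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]")

  len_bp <- round(.chrom_lengths_mb * 1e6 * scale)
  n_bins <- ceiling(len_bp / bin_width)
  if (any(n_bins < 1L))
    stop("scale too small: chromosome ", names(which(n_bins < 1L))[1L],
         " has no bins")

  chrom <- rep(names(len_bp), n_bins)
  idx <- unlist(lapply(n_bins, seq_len), use.names = FALSE) - 1L
  start <- idx * bin_width
  end <- pmin(start + bin_width, rep(len_bp, n_bins))

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(gc_seed)
  gc <- unlist(lapply(n_bins, .gc_walk), use.names = FALSE)

  out <- data.frame(
    chrom = chrom, start = start, end = end, gc = gc,
    usable = TRUE, stringsAsFactors = FALSE
  )
  class(out) <- c("genome_bins", "data.frame")
  out
}

# AR(1) walk for one chromosome's GC track. The correlation length is a
# few bins (isochore-like), so every chromosome samples the full GC
# range: per-chromosome mean GC varies far less than bin-level GC, which
# keeps GC correction from confounding with chromosome dosage.
.gc_walk <- function(n, mu = 0.41, phi = 0.9, sd_innov = 0.03) {
  g <- numeric(n)
  g[1L] <- mu + rnorm(1L, 0, sd_innov / sqrt(1 - phi^2))
  if (n > 1L) {
    e <- rnorm(n - 1L, 0, sd_innov)
    for (i in 2:n) g[i] <- mu + phi * (g[i - 1L] - mu) + e[i - 1L]
  }
  pmin(pmax(g, 0.2), 0.8)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

.check_genome <- function(genome) {
  stopifnot(is.data.frame(genome),
            all(c("chrom", "start", "end", "gc", "usable") %in% names(genome)))
  invisible(genome)
}
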