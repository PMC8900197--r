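#' Sequencing / amplification profile for a DNA source
#'
#' Bundles the count-noise parameters used to simulate one sample type.
#' The presets reflect the qualitative behaviour of embryo liquid-biopsy
#' sources: spent culture medium (SCM) yields substantially more cell-free
#' DNA than blastocoel fluid (BF), so BF is emulated as noisier
#' (higher amplification overdispersion, more bin dropout); biopsy
#' references (ICM, WB) are cleaner than either. The `control` preset
#' mimics a blank-medium control that should fail QC.
#'
#' @param source One of `"SCM"`, `"BF"`, `"ICM"`, `"WB"`, `"control"`, or
#'   `"custom"` (use the explicit arguments).
#' @param total_reads Total reads per sample (default 2e6, i.e. ~2 million
#'   shallow-WGS reads).
#' @param dispersion Overdispersion of per-bin counts (gamma-multinomial
#'   mixing variance; per-bin count CV is about
#'   `sqrt(dispersion + 1/mean_count)`). Must be >= 0.
#' @param gc_bias_strength Strength of the multiplicative GC coverage bias
#'   `exp(strength * (gc - 0.41))`; 0 disables GC bias.
#' @param dropout_rate Fraction of bins zeroed out before read sampling.
#' @param contamination Fraction `c` in \[0, 1\] of reads originating from a
#'   46,XX contaminant (e.g. maternal cumulus-cell DNA).
#' @return A `source_profile` object (list).
#' @examples
#' source_profile("SCM")
#' source_profile("BF", dropout_rate = 0.2)
#' @export
source_profile <- function(source = c("SCM", "BF", "ICM", "WB", "control",
                                      "custom"),
                           total_reads = NULL, dispersion = NULL,
                           gc_bias_strength = NULL, dropout_rate = NULL,
                           contamination = NULL) {
  source <- match.arg(source)
  preset <- switch(source,
    SCM     = list(total_reads = 2e6, dispersion = 0.005,
                   gc_bias_strength = 1.0, dropout_rate = 0.01,
                   contamination = 0),
    BF      = list(total_reads = 2e6, dispersion = 0.04,
                   gc_bias_strength = 1.5, dropout_rate = 0.08,
                   contamination = 0),
    ICM     = list(total_reads = 2e6, dispersion = 0.003,
                   gc_bias_strength = 0.6, dropout_rate = 0.002,
                   contamination = 0),
    WB      = list(total_reads = 2e6, dispersion = 0.003,
                   gc_bias_strength = 0.6, dropout_rate = 0.002,
                   contamination = 0),
    control = list(total_reads = 5e4, dispersion = 0.5,
                   gc_bias_strength = 1.0, dropout_rate = 0.6,
                   contamination = 0),
    custom  = list(total_reads = 2e6, dispersion = 0.005,
                   gc_bias_strength = 1.0, dropout_rate = 0.01,
                   contamination = 0)
  )
  if (!is.null(total_reads)) preset$total_reads <- total_reads
  if (!is.null(dispersion)) preset$dispersion <- dispersion
  if (!is.null(gc_bias_strength)) preset$gc_bias_strength <- gc_bias_strength
  if (!is.null(dropout_rate)) preset$dropout_rate <- dropout_rate
  if (!is.null(contamination)) preset$contamination <- contamination

  with(preset, {
    stopifnot(total_reads >= 1)
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop("dropout_rate must be in [0, 1)")
    if (contamination < 0 || contamination > 1)
      stop("contamination must be in [0, 1]")
  })
  structure(c(list(source = source), preset), class = "source_profile")
}

#' @export
print.source_profile <- function(x, ...) {
  cat(sprintf(
    "source_profile [%s]: %g reads, dispersion %g, gc bias %g, dropout %g, contamination %g\n",
    x$source, x$total_reads, x$dispersion, x$gc_bias_strength,
    x$dropout_rate, x$contamination))
  invisible(x)
}

# Multiplicative GC coverage bias used by the simulator.
.gc_bias_factor <- function(gc, strength, center = 0.41) {
  exp(strength * (gc - center))
}
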