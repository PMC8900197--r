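#' Pipeline configuration
#'
#' Central bundle of all tunable parameters, serializable to/from JSON.
#' Unknown keys in `...` or in a loaded file are an error (no silent
#' defaults).
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `screen_config` list with elements:
#' \describe{
#'   \item{bin_width, genome_scale}{genome binning (bp; scale in (0,1]).}
#'   \item{gc_range, gc_span, min_panel_median, max_masked_fraction,
#'     panel_cv_cutoff}{normalization settings.}
#'   \item{alpha, n_perm, min_width, merge_threshold}{CBS parameters.}
#'   \item{mosaic_floor, full_cutoff, whole_chrom_fraction,
#'     min_segment_bins}{calling thresholds (mosaic reporting floor 0.5).}
#'   \item{x_xx_window, x_xy_window, y_xx_max, y_xy_window}{sex-call
#'     dosage windows.}
#'   \item{seed}{default pipeline seed.}
#' }
#' @export
screen_config <- function(...) {
  defaults <- list(
    bin_width = 1e6, genome_scale = 1,
    gc_range = c(0.2, 0.8), gc_span = 0.3, min_panel_median = 0.1,
    max_masked_fraction = 0.5, panel_cv_cutoff = 0.3,
    alpha = 0.01, n_perm = 1000L, min_width = 3L, merge_threshold = 0.1,
    mosaic_floor = 0.5, full_cutoff = 0.8, whole_chrom_fraction = 0.8,
    min_segment_bins = 10L,
    x_xx_window = c(0.8, 1.2), x_xy_window = c(0.35, 0.65),
    y_xx_max = 0.2, y_xy_window = c(0.3, 0.7),
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("config overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$n_perm >= 100,
            cfg$min_width >= 2, cfg$mosaic_floor >= 0,
            cfg$mosaic_floor <= 1, cfg$full_cutoff >= cfg$mosaic_floor,
            cfg$whole_chrom_fraction > 0, cfg$whole_chrom_fraction <= 1,
            cfg$genome_scale > 0, cfg$genome_scale <= 1)
  structure(cfg, class = "screen_config")
}

#' Read / write a pipeline configuration
#'
#' @param path JSON file path.
#' @param config A `screen_config`.
#' @return `read_config` returns a `screen_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(screen_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Short stable hash of a configuration
#'
#' FNV-1a over the canonical JSON serialization; stamped into pipeline
#' outputs so any result can be traced to the exact configuration.
#'
#' @param config A `screen_config`.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; avoids 32-bit
    # integer overflow in bitwXor
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h <- (h * 16777619) %% 4294967296
  }
  # h may exceed .Machine$integer.max; print as two 16-bit halves
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
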