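#' Run the full screening pipeline on a simulated cohort
#'
#' Convenience end-to-end driver: builds the binned genome, simulates a
#' euploid reference panel and an embryo cohort, normalizes and calls
#' every sample, scores the calls against the simulation ground truth,
#' and (optionally) writes cohort TSVs, a call sheet CSV and an
#' evaluation JSON stamped with the configuration hash.
#'
#' @param n Cohort size.
#' @param aneuploid_rate,mosaic_rate Cohort composition (defaults mirror
#'   the 148-embryo validation cohort: 47/148 aneuploid).
#' @param sources Character vector of source profiles to simulate
#'   (default `"SCM"`).
#' @param n_ref Reference panel size (default 20).
#' @param config A [screen_config()].
#' @param seed Integer seed fixing simulation, segmentation and panel.
#' @param out_dir Optional output directory; `NULL` writes nothing.
#' @return List with `genome`, `truths`, `calls` (per source),
#'   `evaluation` (per source: `diagnostic_summary` vs truth), `config`.
#' @export
run_pipeline <- function(n = 148, aneuploid_rate = 47 / 148,
                         mosaic_rate = 0.3, sources = "SCM", n_ref = 20,
                         config = screen_config(), seed = 1L,
                         out_dir = NULL) {
  genome <- build_genome(bin_width = config$bin_width,
                         scale = config$genome_scale)
  profiles <- lapply(sources, source_profile)
  names(profiles) <- sources

  panel_raw <- simulate_reference_panel(n_ref, source_profile("SCM"),
                                        genome, seed = seed * 1000L + 7L)
  panel <- build_panel_from_counts(panel_raw$samples, genome,
                                   sexes = panel_raw$sexes, config = config)

  cohort <- simulate_cohort(n = n, aneuploid_rate = aneuploid_rate,
                            mosaic_rate = mosaic_rate,
                            profiles = profiles, genome = genome,
                            seed = seed)
  truth_tab <- data.frame(
    sample_id = vapply(seq_len(n), function(i) sprintf("embryo%03d", i),
                       character(1)),
    class = vapply(cohort$truths, truth_class, character(1)),
    stringsAsFactors = FALSE)

  calls <- list()
  evaluation <- list()
  for (src in sources) {
    calls[[src]] <- analyze_cohort(cohort$counts[[src]], genome, panel,
                                   config, seed = seed + 17L)
    cm <- confusion_matrix(calls[[src]], truth_tab)
    evaluation[[src]] <- diagnostic_metrics(cm)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, genome, file.path(out_dir, "cohort"),
                 config = config, seed = seed)
    for (src in sources)
      write_calls(calls[[src]],
                  file.path(out_dir, paste0("calls_", src, ".csv")))
    ev <- lapply(evaluation, function(d) {
      lapply(d[c("sensitivity", "specificity", "npv", "ppv",
                 "concordance")],
             function(f) list(value = f$value, num = f$num, den = f$den))
    })
    jsonlite::write_json(
      list(config_hash = config_hash(config), seed = seed,
           evaluation = ev),
      file.path(out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genome = genome, truths = cohort$truths, calls = calls,
       evaluation = evaluation, config = config)
}
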