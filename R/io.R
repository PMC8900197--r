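#' Read and write per-bin count tables
#'
#' BED-like TSV dialect with header `chrom start end count`, 0-based
#' half-open coordinates. `one_based = TRUE` converts 1-based inclusive
#' starts on input. Malformed rows raise errors naming the row.
#'
#' @param path File path.
#' @param sample_id,source Metadata stored in the returned `bin_counts`.
#' @param one_based Input coordinates are 1-based inclusive.
#' @return `read_bin_table` returns a list with `counts` (a `bin_counts`)
#'   and `bins` (chrom/start/end data frame); `write_bin_table` returns
#'   `path` invisibly.
#' @export
read_bin_table <- function(path, sample_id = basename(path),
                           source = "unknown", one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 4 || !all(c("chrom", "start", "end", "count") %in%
                               names(tab)))
    stop(path, ": expected 4 columns chrom/start/end/count, got ",
         paste(names(tab), collapse = ","))
  if (nrow(tab) == 0) stop(path, ": empty bin table")
  bad <- which(!is.finite(tab$count) | tab$count < 0 |
                 tab$count != floor(tab$count))
  if (length(bad)) # +1: report file lines, counting the header
    stop(path, ": invalid count at line ", bad[1] + 1L)
  if (one_based) tab$start <- tab$start - 1L
  disorder <- which(diff(tab$start) <= 0 &
                      tab$chrom[-1] == tab$chrom[-nrow(tab)])
  if (length(disorder))
    stop(path, ": bins not sorted at line ", disorder[1] + 2L)
  counts <- structure(list(sample_id = sample_id, source = source,
                           counts = as.integer(tab$count),
                           n_bins = nrow(tab),
                           total_reads = sum(tab$count)),
                      class = "bin_counts")
  list(counts = counts,
       bins = tab[, c("chrom", "start", "end")])
}

#' @rdname read_bin_table
#' @param counts A `bin_counts`.
#' @param genome Matching `genome_bins`.
#' @export
write_bin_table <- function(counts, genome, path) {
  .check_genome(genome)
  stopifnot(inherits(counts, "bin_counts"),
            counts$n_bins == nrow(genome))
  tab <- data.frame(chrom = genome$chrom, start = genome$start,
                    end = genome$end, count = counts$counts)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write segments in SEG format
#'
#' Standard SEG columns (`sample`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark`, `seg.mean`) with `seg.mean` as log2 ratio plus a
#' `seg.ratio` column carrying the linear ratio.
#'
#' @param segments Segment data frame from [segment_genome()].
#' @param genome Matching `genome_bins`.
#' @param sample_id Sample name written into the first column.
#' @param path File path.
#' @return `read_seg` returns the segment data frame; `write_seg`
#'   returns `path` invisibly.
#' @export
write_seg <- function(segments, genome, sample_id, path) {
  .check_genome(genome)
  tab <- data.frame(
    sample = sample_id,
    chrom = segments$chrom,
    loc.start = genome$start[segments$genome_start + 1L],
    loc.end = genome$end[segments$genome_end],
    num.mark = segments$n_bins,
    seg.mean = log2(pmax(segments$mean, 1e-6)),
    seg.ratio = segments$mean
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "loc.start", "loc.end", "num.mark",
            "seg.mean")
  if (!all(need %in% names(tab)))
    stop(path, ": missing SEG columns ",
         paste(setdiff(need, names(tab)), collapse = ","))
  if (nrow(tab) == 0) stop(path, ": empty SEG file")
  tab
}

#' Read and write per-sample call sheets
#'
#' CSV with header `sample_id, class, karyotype, sex`.
#'
#' @param calls List of `ploidy_call` objects or a data frame.
#' @param path File path.
#' @return `read_calls` returns a data frame; `write_calls` returns
#'   `path` invisibly.
#' @export
write_calls <- function(calls, path) {
  if (!is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(pc) {
      data.frame(sample_id = pc$sample_id, class = pc$classification,
                 karyotype = pc$karyotype %||% NA_character_,
                 sex = pc$sex, stringsAsFactors = FALSE)
    }))
  }
  write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(tab)))
    stop(path, ": call sheet needs sample_id and class columns")
  tab
}

#' Write a simulated cohort to disk
#'
#' Emits one BED-like TSV of bin counts per sample per source, a truth
#' table CSV (`sample_id`, `sex`, `class`, `karyotype_string`) and a
#' manifest JSON recording the configuration hash, seed and file list.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param genome Matching `genome_bins`.
#' @param dir Output directory (created if missing).
#' @param config The `screen_config` used (hashed into the manifest).
#' @param seed The seed the cohort was simulated with.
#' @return The manifest (invisibly).
#' @export
write_cohort <- function(cohort, genome, dir, config = screen_config(),
                         seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (src in names(cohort$counts)) {
    src_dir <- file.path(dir, src)
    dir.create(src_dir, showWarnings = FALSE)
    for (s in cohort$counts[[src]]) {
      f <- file.path(src_dir, paste0(s$sample_id, ".tsv"))
      write_bin_table(s, genome, f)
      files <- c(files, f)
    }
  }
  truth <- do.call(rbind, lapply(seq_along(cohort$truths), function(i) {
    tr <- cohort$truths[[i]]
    data.frame(sample_id = sprintf("embryo%03d", i), sex = tr$sex,
               class = truth_class(tr),
               karyotype_string = truth_karyotype_string(tr),
               stringsAsFactors = FALSE)
  }))
  truth_path <- file.path(dir, "truth.csv")
  write.csv(truth, truth_path, row.names = FALSE)
  manifest <- list(n = length(cohort$truths),
                   sources = names(cohort$counts),
                   config_hash = config_hash(config), seed = seed,
                   truth = basename(truth_path),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Path to a bundled fixture file
#'
#' The package ships plain-text summary fixtures from a published
#' 148-embryo SCM/BF niPGT-A validation cohort:
#' \describe{
#'   \item{`cohort148_confusion.csv`}{confusion counts per assay
#'     (SCM/BF) and reference subgroup (ICM/WB/total).}
#'   \item{`cohort148_samples.csv`}{a per-sample call/truth sheet
#'     realizing those counts.}
#'   \item{`cohort212_sex_ploidy.csv`}{per-sample ploidy and sex
#'     call/reference sheet for the IVF/ICSI comparison (212 embryos).}
#'   \item{`wbscm64_confusion.csv`}{confusion counts of the 64-pair
#'     WB-SCM set.}
#' }
#' The per-sample sheets are synthetic reconstructions: they realize the
#' published marginal counts exactly, but individual row pairings are
#' arbitrary.
#'
#' @param name Fixture file name.
#' @return Absolute file path.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "nicscreen")
  if (p == "") stop("no bundled fixture named ", name)
  p
}
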