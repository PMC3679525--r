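#' Run every synthetic generator for one study
#'
#' Convenience wrapper tying the generators together: genome, planted
#' truth, multi-caller peak calls plus binding read counts, the expression
#' timecourse, and (optionally, it is the slowest part) the two-design
#' PBM probe sets.
#'
#' @param config a [sim_config()].
#' @param pbm also simulate the protein-binding microarrays?
#' @return list with `config`, `annotation`, `truth`, `peaks`, `counts`,
#'   `input_control`, `expression`, and `probes` (NULL unless `pbm`).
#' @export
simulate_study <- function(config = sim_config(), pbm = FALSE) {
  annotation <- simulate_genome(config)
  truth <- simulate_truth(config, annotation)
  binding <- simulate_binding(config, annotation, truth)
  expression <- simulate_expression(config, annotation, truth)
  list(config = config,
       annotation = annotation,
       truth = truth,
       peaks = binding$peaks,
       counts = binding$counts,
       input_control = binding$input_control,
       expression = expression,
       probes = if (pbm) simulate_pbm(config) else NULL)
}

#' A noise-free variant of a configuration
#'
#' Sets caller jitter and false/missed call rates to zero, removes the
#' replicate effect and log-normal noise on binding RPKM, and shrinks
#' expression noise to a numerically tiny (but still strictly decreasing
#' across waves) level, so that every downstream stage should recover the
#' planted truth exactly.
#'
#' @param config a [sim_config()] to strip of noise.
#' @return a `sim_config`.
#' @export
sim_config_noise_free <- function(config = sim_config()) {
  config$caller_spec$jitter_bp <- 0
  config$caller_spec$fp_rate <- 0
  config$caller_spec$fn_rate <- 0
  config$binding_noise_sd <- 0
  config$expr_noise_sd <- 0.02
  ws <- config$wave_spec
  config$wave_spec$sd <- 0.02 * 0.75^(seq_len(nrow(ws)) - 1)
  og <- config$other_regulated
  if (nrow(og) > 0) config$other_regulated$sd <- 0.02
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

#' Write a simulated study to disk
#'
#' Materialises the study in the formats the readers consume: BED6 peak
#' files (one per caller x replicate x timepoint), a GFF3 gene annotation,
#' TSV tables for read counts, input controls and expression, TSV probe
#' files per array design, and a JSON truth file.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_gff3(study$annotation, file.path(dir, "annotation.gff3"),
                        chrom_sizes = study$config$chrom_sizes)
  pk <- study$peaks %>%
    group_by(.data$caller, .data$replicate, .data$timepoint)
  for (grp in dplyr::group_split(pk)) {
    f <- sprintf("peaks_%s_r%d_t%s.bed", grp$caller[1], grp$replicate[1],
                 gsub("\\.", "p", as.character(grp$timepoint[1])))
    write_peaks_bed(grp, file.path(dir, f))
  }
  readr::write_tsv(study$counts, file.path(dir, "binding_counts.tsv"))
  readr::write_tsv(study$input_control, file.path(dir, "input_control.tsv"))
  readr::write_tsv(study$expression, file.path(dir, "expression.tsv"))
  if (!is.null(study$probes)) {
    for (d in unique(study$probes$design)) {
      readr::write_tsv(
        study$probes %>% filter(.data$design == d) %>%
          select("probe_id", "sequence", "intensity"),
        file.path(dir, sprintf("probes_%s.tsv", d)))
    }
  }
  truth <- study$truth
  jsonlite::write_json(
    list(genes = truth$genes,
         regions = truth$regions,
         occupancy_fold = as.list(truth$occupancy_fold),
         pfm = unclass(truth$pfm)),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
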