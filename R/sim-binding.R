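#' Simulate multi-caller ChIP peak calls and binding read counts
#'
#' Emits, for every caller x replicate x timepoint, the true binding
#' intervals perturbed by caller-specific coordinate jitter, with a
#' fraction of calls dropped (`fn_rate`) and a proportional number of
#' spurious intervals added (`fp_rate`). Occupancy follows a smooth curve
#' rising from baseline at 0 hr to its maximum at 4 hr; callers only emit
#' a region at timepoints where its occupancy is detectably above baseline
#' (fold > 1.2), so no peaks are called at 0 hr. Per-region read counts
#' are emitted for every timepoint and replicate, with a multiplicative
#' log-normal replicate effect (ChIP efficiency) and log2-normal replicate
#' noise of sd `binding_noise_sd`; input-control RPKM at 0 and 4 hr is
#' provided per region for the bound/unbound cutoff.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @return list with tibbles `peaks` (chrom, start, end, strand, caller,
#'   replicate, timepoint, score), `counts` (region_id, timepoint,
#'   replicate, count, library_size) and `input_control` (region_id,
#'   input_0h, input_4h).
#' @export
simulate_binding <- function(config, annotation, truth) {
  set.seed((sim_seed(config, "binding") + 7L) %% .Machine$integer.max)
  regions <- truth$regions
  fold <- truth$occupancy_fold
  tps <- config$timepoints
  reps <- seq_len(config$n_replicates)
  noisy <- config$binding_noise_sd > 0

  # replicate-level ChIP efficiency (what median normalization removes)
  rep_factor <- if (noisy) 2^rnorm(length(reps), 0, 0.15) else rep(1, length(reps))

  peaks <- list()
  for (ci in seq_len(nrow(config$caller_spec))) {
    cs <- config$caller_spec[ci, ]
    for (tp in tps[fold[as.character(tps)] > 1.2]) {
      for (rp in reps) {
        keep <- runif(nrow(regions)) >= cs$fn_rate
        kept <- regions[keep, ]
        if (nrow(kept) > 0) {
          js <- round(rnorm(nrow(kept), 0, cs$jitter_bp))
          je <- round(rnorm(nrow(kept), 0, cs$jitter_bp))
          start <- pmax(0L, as.integer(kept$start + js))
          end <- as.integer(pmax(start + 50L, kept$end + je))
          n_fp <- rpois(1, cs$fp_rate * nrow(kept))
          fp <- NULL
          if (n_fp > 0) {
            fp_chrom <- sample(names(config$chrom_sizes), n_fp, replace = TRUE)
            fp_w <- round(runif(n_fp, 200, 600))
            fp_s <- floor(runif(n_fp, 0, config$chrom_sizes[fp_chrom] - fp_w))
            fp <- tibble(chrom = fp_chrom, start = as.integer(fp_s),
                         end = as.integer(fp_s + fp_w))
          }
          peaks[[length(peaks) + 1]] <- bind_rows(
            tibble(chrom = kept$chrom, start = start, end = end),
            fp
          ) %>% mutate(strand = ".", caller = cs$caller, replicate = rp,
                       timepoint = tp,
                       score = fold[[as.character(tp)]] + rnorm(n(), 0, 0.1))
        }
      }
    }
  }
  peaks <- if (length(peaks)) list_rbind(peaks) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), caller = character(), replicate = integer(),
           timepoint = numeric(), score = numeric())

  grid <- expand_grid(region_id = regions$region_id, timepoint = tps,
                      replicate = reps) %>%
    left_join(select(regions, "region_id", "start", "end", "base_rpkm"),
              by = "region_id") %>%
    mutate(
      library_size = 2e6L,
      rpkm_true = .data$base_rpkm * fold[as.character(.data$timepoint)] *
        rep_factor[.data$replicate] *
        2^rnorm(n(), 0, config$binding_noise_sd),
      count = round(.data$rpkm_true * (.data$end - .data$start) / 1000 *
                      .data$library_size / 1e6)
    )
  counts <- select(grid, "region_id", "timepoint", "replicate", "count",
                   "library_size")

  in_noise <- if (noisy) 2^rnorm(nrow(regions) * 2, 0, 0.1) else 1
  input_control <- tibble(
    region_id = regions$region_id,
    input_0h = regions$base_rpkm * 1.1 * head(in_noise, nrow(regions)),
    input_4h = regions$base_rpkm * 1.3 * utils::tail(in_noise, nrow(regions))
  )

  list(peaks = peaks, counts = counts, input_control = input_control)
}

#' Simulate the expression timecourse
#'
#' Wave genes follow a step trajectory on the log2 scale: 0 before their
#' wave's onset, the wave amplitude at and after onset, with log2-normal
#' replicate noise whose sd decreases from wave to wave. Repressed groups
#' behave the same with negative amplitudes. Non-responsive and stable
#' genes are flat with noise `expr_noise_sd`; not-detected genes have all
#' RPKM below 1.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @return long tibble (gene_id, timepoint, replicate, rpkm).
#' @export
simulate_expression <- function(config, annotation, truth) {
  set.seed(sim_seed(config, "expression"))
  params <- bind_rows(
    config$wave_spec %>%
      mutate(category = sprintf("wave%d", .data$wave)) %>%
      select("category", "onset", "amplitude_log2", "sd"),
    config$other_regulated %>%
      rename(category = "group") %>%
      select("category", "onset", "amplitude_log2", "sd"),
    tibble(category = c("nonresponsive", "stable", "not_detected"),
           onset = Inf, amplitude_log2 = 0, sd = config$expr_noise_sd)
  )
  genes <- truth$genes %>%
    left_join(params, by = "category") %>%
    mutate(base = ifelse(.data$category == "not_detected",
                         runif(n(), 0.05, 0.7),  # flat, below detection
                         2^runif(n(), 1.5, 5)))

  tbl <- expand_grid(gene_id = genes$gene_id,
                     timepoint = config$timepoints,
                     replicate = seq_len(config$n_replicates)) %>%
    left_join(select(genes, "gene_id", "category", "onset",
                     "amplitude_log2", "sd", "base"),
              by = "gene_id") %>%
    mutate(
      log2fc = ifelse(.data$timepoint >= .data$onset, .data$amplitude_log2, 0),
      rpkm = .data$base * 2^(.data$log2fc + rnorm(n(), 0, .data$sd))
    )
  nd <- tbl$category == "not_detected"
  tbl$rpkm[nd] <- pmin(tbl$rpkm[nd], 0.95)  # censored at the detection floor
  select(tbl, "gene_id", "timepoint", "replicate", "rpkm")
}
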