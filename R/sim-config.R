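#' Configuration for the synthetic ethylene-timecourse study
#'
#' Bundles and validates every free parameter of the synthetic-data
#' generators. The defaults emulate the structure of an etiolated-seedling
#' ethylene timecourse: seven sampling times from 0 to 24 hr, TF occupancy
#' rising to its maximum at 4 hr, a four-wave transcriptional induction
#' program whose replicate noise decreases wave by wave, additional
#' repressed gene groups, non-responsive and not-detected genes, multiple
#' peak callers with coordinate jitter and false/missed calls, and a
#' two-design universal protein-binding microarray carrying a planted motif.
#'
#' @param seed integer seed; all generators are deterministic given the
#'   config (each consumes an offset of this seed).
#' @param n_genes total number of genes to simulate.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param timepoints ordered hours of the timecourse; must start at 0.
#' @param n_replicates biological replicates per timepoint.
#' @param n_target_genes number of TF candidate target genes (genes given a
#'   true binding region).
#' @param wave_spec tibble with one row per planted induction wave:
#'   `onset` (hours), `amplitude_log2` (log2 fold change reached at and
#'   after onset), `sd` (log2 replicate noise, strictly decreasing across
#'   waves), `n_genes`, `frac_target` (fraction of the wave's genes that
#'   are TF targets).
#' @param other_regulated tibble of non-TF-driven regulated gene groups
#'   (same columns minus `frac_target`, plus `frac_target` defaulting
#'   small); these populate the non-wave paths of the split tree.
#' @param frac_nonresponsive fraction of genes expressed but flat.
#' @param frac_not_detected fraction of genes with all RPKM at or below 1.
#' @param expr_noise_sd log2 replicate noise for non-wave genes.
#' @param caller_spec tibble with one row per emulated peak caller:
#'   `caller`, `jitter_bp`, `fp_rate`, `fn_rate`.
#' @param binding_noise_sd log2 replicate noise on binding-region RPKM.
#' @param max_binding_fold peak occupancy fold change (reached at 4 hr).
#' @param pbm_spec list with `pfm` (planted motif, a [pfm] object),
#'   `probe_length`, `noise_sd` (Gaussian noise on the score scale),
#'   `designs` (two design labels).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                       timepoints = c(0, 0.25, 0.5, 1, 4, 12, 24),
                       n_replicates = 3L,
                       n_target_genes = 400L,
                       wave_spec = default_wave_spec(),
                       other_regulated = default_other_regulated(),
                       frac_nonresponsive = 0.2,
                       frac_not_detected = 0.1,
                       expr_noise_sd = 0.25,
                       caller_spec = default_caller_spec(),
                       binding_noise_sd = 0.15,
                       max_binding_fold = 6,
                       pbm_spec = default_pbm_spec()) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chrom_sizes = chrom_sizes, timepoints = timepoints,
              n_replicates = as.integer(n_replicates),
              n_target_genes = as.integer(n_target_genes),
              wave_spec = as_tibble(wave_spec),
              other_regulated = as_tibble(other_regulated),
              frac_nonresponsive = frac_nonresponsive,
              frac_not_detected = frac_not_detected,
              expr_noise_sd = expr_noise_sd,
              caller_spec = as_tibble(caller_spec),
              binding_noise_sd = binding_noise_sd,
              max_binding_fold = max_binding_fold,
              pbm_spec = pbm_spec)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_wave_spec <- function() {
  tibble(wave = 1:4,
         onset = c(0.25, 1, 4, 12),
         amplitude_log2 = c(3.5, 3, 2.5, 2),
         sd = c(0.8, 0.6, 0.45, 0.3),
         n_genes = c(120L, 120L, 120L, 120L),
         frac_target = 0.5)
}

#' @rdname sim_config
#' @export
default_other_regulated <- function() {
  # repressed gene groups; they carry the minority of down-regulated targets
  # so that ~85% of regulated targets are induced.
  tibble(group = c("downA", "downB"),
         onset = c(0.5, 4),
         amplitude_log2 = c(-2.5, -2),
         sd = c(0.6, 0.5),
         n_genes = c(400L, 400L),
         frac_target = c(0.0525, 0.0525))
}

#' @rdname sim_config
#' @export
default_caller_spec <- function() {
  tibble(caller = c("spp", "macs"),
         jitter_bp = c(30, 50),
         fp_rate = c(0.05, 0.08),
         fn_rate = c(0.05, 0.08))
}

#' @rdname sim_config
#' @export
default_pbm_spec <- function() {
  list(pfm = default_planted_pfm(), probe_length = 36L, noise_sd = 0.25,
       designs = c("ME", "HK"))
}

#' @rdname sim_config
#' @export
default_planted_pfm <- function() {
  # EIN3/TEIL-like 8 bp consensus with a dominant base per column
  # (information content > 1 bit/column).
  consensus <- c("A", "T", "G", "T", "A", "T", "C", "T")
  m <- matrix(0.05, nrow = 4, ncol = 8, dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(consensus)) m[consensus[i], i] <- 0.85
  pfm(m)
}

validate_sim_config <- function(cfg) {
  if (length(cfg$chrom_sizes) == 0 || is.null(names(cfg$chrom_sizes))) {
    stop_bad_arg("chrom_sizes must be a nonempty named vector")
  }
  tp <- cfg$timepoints
  if (tp[1] != 0 || any(diff(tp) <= 0)) {
    stop_bad_arg("timepoints must be strictly increasing and include 0")
  }
  fr <- c(cfg$frac_nonresponsive, cfg$frac_not_detected)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop_bad_arg("fractions must lie in [0,1] and sum to at most 1")
  }
  ws <- cfg$wave_spec
  if (nrow(ws) > 1 && any(diff(ws$sd) >= 0)) {
    stop_bad_arg("wave sds must be strictly decreasing across successive waves")
  }
  if (!all(ws$onset %in% tp)) stop_bad_arg("wave onsets must be timepoints")
  n_reg <- sum(ws$n_genes) + sum(cfg$other_regulated$n_genes)
  n_flat <- round(cfg$n_genes * (cfg$frac_nonresponsive + cfg$frac_not_detected))
  if (n_reg + n_flat > cfg$n_genes) {
    stop_bad_arg("wave/other gene counts plus fractions exceed n_genes")
  }
  n_reg_targets <- sum(round(ws$n_genes * ws$frac_target)) +
    sum(round(cfg$other_regulated$n_genes * cfg$other_regulated$frac_target))
  if (cfg$n_target_genes < n_reg_targets) {
    stop_bad_arg("n_target_genes (%d) smaller than planted regulated targets (%d)",
                 cfg$n_target_genes, n_reg_targets)
  }
  ps <- cfg$pbm_spec
  if (ps$probe_length < 8) stop_bad_arg("pbm probe_length must be >= 8")
  if (ncol(unclass(ps$pfm)) > ps$probe_length) {
    stop_bad_arg("planted PFM wider than probe_length")
  }
  if (nrow(cfg$caller_spec) < 2) stop_bad_arg("caller_spec needs >= 2 callers")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_genes, "genes,", length(x$timepoints), "timepoints,",
      x$n_replicates, "replicates,", x$n_target_genes, "target genes\n")
  cat("  waves:", nrow(x$wave_spec), " other regulated groups:",
      nrow(x$other_regulated), " callers:", nrow(x$caller_spec), "\n")
  invisible(x)
}

# derived seeds for each generator so stages are independently reproducible
sim_seed <- function(cfg, stage) {
  offsets <- c(genome = 11L, binding = 23L, expression = 37L, pbm = 53L)
  (cfg$seed * 101L + offsets[[stage]]) %% .Machine$integer.max
}
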