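#' Simulate a compact gene annotation
#'
#' Places single-exon genes on the configured chromosomes, non-overlapping
#' and separated by at least 6 kb so that a binding region placed near a
#' gene's TSS has a unique gene within the 5 kb association window.
#' Coordinates are 0-based half-open; the TSS is the body start on the
#' plus strand and the body end on the minus strand.
#'
#' @param config a [sim_config()].
#' @return tibble with columns gene_id, chrom, strand, start, end, tss.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "genome"))
  sizes <- config$chrom_sizes
  n <- config$n_genes
  prop <- sizes / sum(sizes)
  n_per <- floor(prop * n)
  rest <- n - sum(n_per)
  if (rest > 0) n_per[seq_len(rest)] <- n_per[seq_len(rest)] + 1L

  min_gap <- 6000L
  max_len <- 3000L
  out <- imap(n_per, function(k, chrom) {
    if (k == 0) return(NULL)
    slot <- floor(sizes[[chrom]] / k)
    if (slot < max_len + min_gap + 100) {
      stop_bad_arg("placement failure: chromosome %s (%.0f bp) too small for %d genes",
                   chrom, sizes[[chrom]], k)
    }
    len <- round(runif(k, 1000, max_len))
    slack <- slot - len - min_gap
    start <- (seq_len(k) - 1L) * slot + min_gap %/% 2L + floor(runif(k, 0, slack))
    strand <- sample(c("+", "-"), k, replace = TRUE)
    tibble(chrom = chrom, strand = strand,
           start = as.integer(start), end = as.integer(start + len))
  }) %>% list_rbind()

  out %>%
    mutate(gene_id = sprintf("G%05d", row_number()),
           tss = ifelse(.data$strand == "+", .data$start, .data$end)) %>%
    select("gene_id", "chrom", "strand", "start", "end", "tss")
}

#' Planted ground truth for a synthetic study
#'
#' Assigns every gene to a category (induction wave, repressed group,
#' non-responsive, not-detected, stable), marks the TF candidate target
#' genes, and places one true binding region near the TSS of each target.
#' The truth is fully reproducible from the configuration.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_genome()].
#' @return a `sim_truth` list with tibbles `genes` (gene_id, category,
#'   wave, direction, is_target), `regions` (true binding intervals with
#'   target gene and baseline RPKM), the per-timepoint occupancy fold
#'   curve, and the planted PFM.
#' @export
simulate_truth <- function(config, annotation) {
  set.seed(sim_seed(config, "binding"))
  ws <- config$wave_spec
  og <- config$other_regulated
  n <- config$n_genes
  ids <- sample(annotation$gene_id)

  take <- function(k) {
    got <- ids[seq_len(k)]
    ids <<- ids[-seq_len(k)]
    got
  }
  genes <- list()
  for (i in seq_len(nrow(ws))) {
    genes[[length(genes) + 1]] <- tibble(
      gene_id = take(ws$n_genes[i]), category = sprintf("wave%d", ws$wave[i]),
      wave = ws$wave[i], direction = sign(ws$amplitude_log2[i]))
  }
  for (i in seq_len(nrow(og))) {
    genes[[length(genes) + 1]] <- tibble(
      gene_id = take(og$n_genes[i]), category = og$group[i],
      wave = NA_integer_, direction = sign(og$amplitude_log2[i]))
  }
  n_nd <- round(config$frac_not_detected * n)
  n_nr <- round(config$frac_nonresponsive * n)
  genes[[length(genes) + 1]] <- tibble(gene_id = take(n_nd), category = "not_detected",
                                       wave = NA_integer_, direction = 0)
  genes[[length(genes) + 1]] <- tibble(gene_id = take(n_nr), category = "nonresponsive",
                                       wave = NA_integer_, direction = 0)
  genes[[length(genes) + 1]] <- tibble(gene_id = ids, category = "stable",
                                       wave = NA_integer_, direction = 0)
  genes <- list_rbind(genes)

  # targets: a planted fraction of each regulated group, the rest split
  # between expressed-flat (future EIN3-NR) and not-detected (EIN3-ND) genes
  pick_targets <- function(cat_tbl, k) head(cat_tbl$gene_id, k)
  reg_targets <- character()
  for (i in seq_len(nrow(ws))) {
    grp <- filter(genes, .data$category == sprintf("wave%d", ws$wave[i]))
    reg_targets <- c(reg_targets, pick_targets(grp, round(ws$n_genes[i] * ws$frac_target[i])))
  }
  for (i in seq_len(nrow(og))) {
    grp <- filter(genes, .data$category == og$group[i])
    reg_targets <- c(reg_targets, pick_targets(grp, round(og$n_genes[i] * og$frac_target[i])))
  }
  n_left <- config$n_target_genes - length(reg_targets)
  n_nr_t <- round(0.7 * n_left)
  n_nd_t <- n_left - n_nr_t
  nr_pool <- filter(genes, .data$category == "nonresponsive")$gene_id
  nd_pool <- filter(genes, .data$category == "not_detected")$gene_id
  if (length(nr_pool) < n_nr_t || length(nd_pool) < n_nd_t) {
    stop_bad_arg("not enough non-responsive/not-detected genes for target quota")
  }
  targets <- c(reg_targets, head(nr_pool, n_nr_t), head(nd_pool, n_nd_t))
  genes <- mutate(genes, is_target = .data$gene_id %in% targets)

  # one true binding region near each target TSS
  tg <- annotation %>% filter(.data$gene_id %in% targets)
  width <- round(runif(nrow(tg), 200, 600))
  center <- tg$tss + round(runif(nrow(tg), -800, 800))
  start <- pmax(0L, as.integer(center - width %/% 2))
  regions <- tibble(
    region_id = region_id(tg$chrom, start, start + width),
    chrom = tg$chrom, start = start, end = as.integer(start + width),
    gene_id = tg$gene_id,
    base_rpkm = 2^runif(nrow(tg), 2, 4)
  ) %>% arrange(.data$chrom, .data$start)

  structure(list(
    genes = genes %>% arrange(.data$gene_id),
    regions = regions,
    occupancy_fold = binding_fold_curve(config$timepoints, config$max_binding_fold),
    pfm = config$pbm_spec$pfm
  ), class = "sim_truth")
}

# smooth log-logistic rise peaking at 4 hr, then a mild exponential decline;
# any curve whose argmax over the sampled timepoints is 4 hr would do.
binding_fold_curve <- function(timepoints, max_fold) {
  r <- function(t) (t / 1)^1.5 / (1 + (t / 1)^1.5)
  g <- r(pmin(timepoints, 4)) / r(4) *
    ifelse(timepoints > 4, exp(-0.02 * (timepoints - 4)), 1)
  setNames(1 + (max_fold - 1) * g, as.character(timepoints))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$genes), "genes,", nrow(x$regions),
      "true binding regions\n")
  print(dplyr::count(x$genes, .data$category, .data$is_target))
  invisible(x)
}
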