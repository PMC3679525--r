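#' Merge intervals separated by less than a maximum gap
#'
#' Collapses intervals on the same chromosome whenever the gap between
#' them is strictly less than `max_gap` bp (overlapping and bookended
#' intervals always merge; a gap of exactly `max_gap` does not).
#'
#' @param intervals tibble with chrom, start, end (0-based half-open).
#' @param max_gap maximum gap in bp; default 200.
#' @return tibble (chrom, start, end), sorted, with pairwise gaps of at
#'   least `max_gap`; coverage of the input is preserved.
#' @export
merge_intervals <- function(intervals, max_gap = 200) {
  if (max_gap < 0) stop_bad_arg("max_gap must be >= 0")
  validate_intervals(intervals, "merge_intervals input")
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- intervals_to_granges(intervals[c("chrom", "start", "end")])
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap, ignore.strand = TRUE)
  granges_to_intervals(merged) %>%
    arrange(.data$chrom, .data$start) %>%
    select("chrom", "start", "end")
}

#' Consensus peak calls by majority vote
#'
#' Within every replicate x timepoint, calls from each peak caller are
#' first merged (gap rule as in [merge_intervals()]); genomic stretches
#' covered by calls from more than one caller (at least `min_callers`,
#' any >= 1 bp intersection) are retained, then merged again. This is the
#' "overlapping peaks by more than one software package" rule: with two
#' callers both must call, with three at least two.
#'
#' @param calls tibble of peak calls (chrom, start, end, caller,
#'   replicate, timepoint).
#' @param callers declared caller identifiers; calls from undeclared
#'   callers are an error. Default: the callers present.
#' @param min_callers minimum number of distinct callers covering a
#'   retained stretch (default 2).
#' @param max_gap merge gap in bp.
#' @return tibble (replicate, timepoint, chrom, start, end) of consensus
#'   intervals per condition.
#' @export
majority_vote <- function(calls, callers = NULL, min_callers = 2, max_gap = 200) {
  validate_intervals(calls, "peak calls")
  need <- c("caller", "replicate", "timepoint")
  if (!all(need %in% names(calls))) {
    stop_bad_arg("calls must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(callers)) callers <- unique(calls$caller)
  if (length(callers) < 2) stop_bad_arg("need >= 2 declared callers")
  unknown <- setdiff(unique(calls$caller), callers)
  if (length(unknown) > 0) {
    stop_bad_arg("unknown caller id(s): %s", paste(unknown, collapse = ", "))
  }

  calls %>%
    group_by(.data$replicate, .data$timepoint) %>%
    dplyr::group_modify(function(grp, key) {
      per_caller <- grp %>%
        group_by(.data$caller) %>%
        dplyr::group_map(~ merge_intervals(.x, max_gap = max_gap))
      gr <- intervals_to_granges(list_rbind(per_caller))
      cov <- GenomicRanges::coverage(gr)
      sl <- IRanges::slice(cov, lower = min_callers, rangesOnly = TRUE)
      hit <- tibble(
        chrom = rep(names(sl), lengths(sl)),
        start = unlist(lapply(sl, BiocGenerics::start), use.names = FALSE) - 1L,
        end = unlist(lapply(sl, BiocGenerics::end), use.names = FALSE)
      )
      if (nrow(hit) == 0) {
        return(tibble(chrom = character(), start = integer(), end = integer()))
      }
      merge_intervals(hit, max_gap = max_gap)
    }) %>%
    ungroup() %>%
    select("replicate", "timepoint", "chrom", "start", "end")
}

#' Unify consensus sets across replicates and timepoints
#'
#' Pools the per-condition consensus intervals and merges them into the
#' final binding-region set; a region present in any replicate x
#' timepoint survives. Records, per unified region, how many conditions
#' contributed an overlapping consensus interval.
#'
#' @param consensus output of [majority_vote()].
#' @param max_gap merge gap in bp.
#' @return tibble (region_id, chrom, start, end, n_conditions).
#' @export
unify_regions <- function(consensus, max_gap = 200) {
  validate_intervals(consensus, "consensus set")
  merged <- merge_intervals(consensus, max_gap = max_gap)
  if (nrow(merged) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_conditions = integer()))
  }
  mg <- intervals_to_granges(merged)
  cg <- intervals_to_granges(consensus)
  ov <- GenomicRanges::findOverlaps(mg, cg, ignore.strand = TRUE)
  cond <- paste(consensus$replicate, consensus$timepoint,
                sep = "|")[S4Vectors::subjectHits(ov)]
  n_cond <- tibble(i = S4Vectors::queryHits(ov), cond = cond) %>%
    distinct() %>%
    dplyr::count(.data$i, name = "n_conditions")
  merged %>%
    mutate(region_id = region_id(.data$chrom, .data$start, .data$end),
           n_conditions = 0L) %>%
    mutate(n_conditions = replace(.data$n_conditions, n_cond$i,
                                  n_cond$n_conditions)) %>%
    select("region_id", "chrom", "start", "end", "n_conditions")
}

#' Reads per kilobase per million (RPKM)
#'
#' @param read_count reads in the feature.
#' @param region_length feature length in bp (> 0).
#' @param library_size total mapped reads in the sample (> 0).
#' @return RPKM = read_count / (region_length/1000) / (library_size/1e6).
#' @export
compute_rpkm <- function(read_count, region_length, library_size) {
  if (any(region_length <= 0)) stop_bad_arg("region_length must be > 0")
  if (any(library_size <= 0)) stop_bad_arg("library_size must be > 0")
  if (any(read_count < 0)) stop_bad_arg("read_count must be >= 0")
  read_count / (region_length / 1000) / (library_size / 1e6)
}

#' RPKM per binding region, timepoint and replicate
#'
#' Joins a read-count table onto the unified region set and computes
#' RPKM from each region's length and the sample library size.
#'
#' @param regions tibble with region_id, start, end.
#' @param counts tibble (region_id, timepoint, replicate, count,
#'   library_size).
#' @return `counts` with an `rpkm` column.
#' @export
quantify_regions <- function(regions, counts) {
  missing <- setdiff(unique(counts$region_id), regions$region_id)
  if (length(missing) > 0) {
    stop_bad_arg("counts reference unknown region(s), e.g. %s", missing[1])
  }
  counts %>%
    left_join(regions %>%
                mutate(length = .data$end - .data$start) %>%
                select("region_id", "length"),
              by = "region_id") %>%
    mutate(rpkm = compute_rpkm(.data$count, .data$length, .data$library_size)) %>%
    select(-"length")
}

#' Transfer a read-count table onto another region set
#'
#' Re-keys per-region counts onto a different (e.g. freshly unified)
#' region set by genomic overlap: each target region receives the summed
#' counts of the source regions it overlaps, per timepoint and replicate.
#' Target regions overlapping no source region get zero counts at the
#' sample's library size.
#'
#' @param regions target region tibble (region_id, chrom, start, end).
#' @param source_regions source region tibble (region_id, chrom, start,
#'   end) matching the ids used in `counts`.
#' @param counts tibble (region_id, timepoint, replicate, count,
#'   library_size) keyed by `source_regions` ids.
#' @return counts keyed by `regions` ids.
#' @export
transfer_counts <- function(regions, source_regions, counts) {
  validate_intervals(regions, "target regions")
  validate_intervals(source_regions, "source regions")
  ov <- GenomicRanges::findOverlaps(intervals_to_granges(regions),
                                    intervals_to_granges(source_regions),
                                    ignore.strand = TRUE)
  map_tbl <- tibble(
    region_id = regions$region_id[S4Vectors::queryHits(ov)],
    source_id = source_regions$region_id[S4Vectors::subjectHits(ov)]
  )
  libs <- counts %>%
    distinct(.data$timepoint, .data$replicate, .data$library_size)
  mapped <- counts %>%
    rename(source_id = "region_id") %>%
    inner_join(map_tbl, by = "source_id", relationship = "many-to-many") %>%
    group_by(.data$region_id, .data$timepoint, .data$replicate) %>%
    summarise(count = sum(.data$count),
              library_size = first(.data$library_size), .groups = "drop")
  expand_grid(region_id = regions$region_id,
              libs) %>%
    left_join(mapped, by = c("region_id", "timepoint", "replicate",
                             "library_size")) %>%
    mutate(count = replace_na(.data$count, 0)) %>%
    select("region_id", "timepoint", "replicate", "count", "library_size")
}

#' Median normalization across replicates
#'
#' Rescales each replicate multiplicatively so that its median value
#' equals the grand median of the per-replicate medians. Within-replicate
#' order is preserved; the scheme is multiplicative, so it is not
#' invariant to additive shifts.
#'
#' @param x long tibble holding the values.
#' @param value column holding the values (default `rpkm`).
#' @param by grouping column defining a replicate (default `replicate`).
#' @return `x` with the value column rescaled.
#' @export
median_normalize <- function(x, value = "rpkm", by = "replicate") {
  meds <- x %>%
    group_by(across(all_of(by))) %>%
    summarise(.med = median(.data[[value]]), .groups = "drop")
  if (any(meds$.med <= 0)) {
    stop_bad_arg("replicate with non-positive median %s: normalization undefined",
                 value)
  }
  grand <- median(meds$.med)
  x %>%
    left_join(meds, by = by) %>%
    mutate(!!value := .data[[value]] * grand / .data$.med) %>%
    select(-".med")
}

#' Log2 ratio against the 0 hr control
#'
#' @param rpkm_t,rpkm_0 RPKM at the timepoint and at 0 hr.
#' @param pseudocount added to both (must be > 0) so zero-signal regions
#'   stay finite; default 0.5.
#' @return log2((rpkm_t + pseudocount) / (rpkm_0 + pseudocount)).
#' @export
log2_vs_control <- function(rpkm_t, rpkm_0, pseudocount = 0.5) {
  if (pseudocount <= 0) stop_bad_arg("pseudocount must be > 0")
  log2((rpkm_t + pseudocount) / (rpkm_0 + pseudocount))
}

#' Replicate-averaged log2 profile versus 0 hr
#'
#' Averages RPKM over replicates per feature and timepoint, then takes
#' the log2 ratio of each timepoint against the feature's 0 hr mean.
#'
#' @param x long tibble (id column, timepoint, replicate, value column).
#' @param id feature id column (default `region_id`).
#' @param value value column (default `rpkm`).
#' @param pseudocount see [log2_vs_control()].
#' @return tibble (id, timepoint, log2fc).
#' @export
log2_profile <- function(x, id = "region_id", value = "rpkm", pseudocount = 0.5) {
  means <- x %>%
    group_by(across(all_of(c(id, "timepoint")))) %>%
    summarise(.m = mean(.data[[value]]), .groups = "drop")
  base <- means %>%
    filter(.data$timepoint == min(.data$timepoint)) %>%
    select(all_of(id), .m0 = ".m")
  means %>%
    left_join(base, by = id) %>%
    mutate(log2fc = log2_vs_control(.data$.m, .data$.m0, pseudocount)) %>%
    select(all_of(id), "timepoint", "log2fc")
}

#' Fold change by the delta-delta-Ct method
#'
#' qPCR-style relative enrichment with normalization to a reference
#' amplicon: fold = 2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control)).
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   threshold cycles; all must be finite.
#' @return fold change.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_control,
               ct_ref_control)
  if (any(!is.finite(cts))) stop_bad_arg("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
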