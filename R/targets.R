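#' Assign binding regions to genes
#'
#' Applies the distance rules: a region is associated to a gene if its
#' center lies within `window` bp of the gene; with exactly one candidate
#' that gene is taken (`single`); with several, the nearest expressed gene
#' (max RPKM > 1 anywhere in the timecourse) wins (`nearest_expressed`);
#' if no candidate is expressed, the nearest gene wins
#' (`nearest_unexpressed`); with no candidate the region stays unassigned
#' (`none`). Distance runs from the region center to the nearest bp of
#' the gene body (0 inside the body) or, with `distance_to = "tss"`, to
#' the TSS. Ties break to the lower gene start, then gene_id.
#'
#' @param regions tibble with region_id, chrom, start, end.
#' @param annotation gene tibble (gene_id, chrom, strand, start, end, tss).
#' @param expression optional tibble (gene_id, max_rpkm) or the long
#'   expression table (gene_id, rpkm); genes absent from it count as
#'   unexpressed. With NULL every gene counts as expressed.
#' @param window association window in bp (default 5000).
#' @param distance_to "body" (default) or "tss".
#' @param expressed_threshold RPKM above which a gene is expressed.
#' @return tibble (region_id, gene_id, distance, rule); gene_id is NA and
#'   distance NA where rule is "none".
#' @export
assign_targets <- function(regions, annotation, expression = NULL,
                           window = 5000, distance_to = c("body", "tss"),
                           expressed_threshold = 1) {
  distance_to <- arg_match(distance_to)
  validate_intervals(regions, "regions")
  bad <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(bad) > 0) {
    stop_bad_arg("region chromosome(s) absent from annotation: %s",
                 paste(bad, collapse = ", "))
  }
  expr <- gene_max_rpkm(expression, annotation, expressed_threshold)

  cand <- regions %>%
    mutate(center = .data$start + (.data$end - .data$start) %/% 2L) %>%
    select("region_id", "chrom", "center") %>%
    inner_join(annotation %>%
                 select("gene_id", "chrom", gstart = "start", gend = "end",
                        "tss"),
               by = "chrom", relationship = "many-to-many") %>%
    mutate(distance = if (distance_to == "body") {
      pmax(0L, .data$gstart - .data$center, .data$center - (.data$gend - 1L))
    } else {
      abs(.data$center - .data$tss)
    }) %>%
    filter(.data$distance <= window) %>%
    left_join(expr, by = "gene_id") %>%
    mutate(expressed = replace_na(.data$expressed, FALSE))

  assigned <- cand %>%
    group_by(.data$region_id) %>%
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 1) {
        return(tibble(gene_id = g$gene_id, distance = g$distance,
                      rule = "single"))
      }
      pool <- if (any(g$expressed)) g[g$expressed, ] else g
      pool <- pool %>%
        arrange(.data$distance, .data$gstart, .data$gene_id)
      tibble(gene_id = pool$gene_id[1], distance = pool$distance[1],
             rule = if (any(g$expressed)) "nearest_expressed"
                    else "nearest_unexpressed")
    }) %>%
    ungroup()

  regions %>%
    select("region_id") %>%
    left_join(assigned, by = "region_id") %>%
    mutate(rule = replace_na(.data$rule, "none"))
}

# normalize the expression argument to (gene_id, expressed)
gene_max_rpkm <- function(expression, annotation, threshold) {
  if (is.null(expression)) {
    return(tibble(gene_id = annotation$gene_id, expressed = TRUE))
  }
  if ("max_rpkm" %in% names(expression)) {
    return(tibble(gene_id = expression$gene_id,
                  expressed = expression$max_rpkm > threshold))
  }
  if (all(c("gene_id", "rpkm") %in% names(expression))) {
    return(expression %>%
             group_by(.data$gene_id) %>%
             summarise(expressed = any(.data$rpkm > threshold),
                       .groups = "drop"))
  }
  stop_bad_arg("expression must have (gene_id, max_rpkm) or (gene_id, rpkm)")
}

#' Strand-aware promoter windows
#'
#' The `length` bp immediately upstream of each TSS: (tss - length, tss)
#' on the plus strand, (tss, tss + length) on the minus strand, clipped
#' at the chromosome bounds when sizes are supplied.
#'
#' @param annotation gene tibble (gene_id, chrom, strand, tss).
#' @param length window length in bp (> 0), default 1000.
#' @param chrom_sizes optional named vector used to clip the right edge.
#' @return tibble (gene_id, chrom, start, end, strand).
#' @export
promoter_windows <- function(annotation, length = 1000, chrom_sizes = NULL) {
  if (length <= 0) stop_bad_arg("promoter length must be > 0")
  out <- annotation %>%
    mutate(
      start = ifelse(.data$strand == "+", pmax(0, .data$tss - length), .data$tss),
      end = ifelse(.data$strand == "+", .data$tss, .data$tss + length)
    )
  if (!is.null(chrom_sizes)) {
    out <- out %>%
      mutate(end = pmin(.data$end, chrom_sizes[.data$chrom]))
  }
  out %>%
    filter(.data$end > .data$start) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    select("gene_id", "chrom", "start", "end", "strand")
}

#' Extract promoter sequences from a genome
#'
#' @param promoters output of [promoter_windows()].
#' @param genome named character vector (or DNAStringSet) of chromosome
#'   sequences.
#' @return named character vector of promoter sequences (reverse
#'   complemented on the minus strand).
#' @export
promoter_sequences <- function(promoters, genome) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome),
                                                     names(genome))
  seqs <- substring(genome[promoters$chrom], promoters$start + 1L,
                    promoters$end)
  neg <- promoters$strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  setNames(seqs, promoters$gene_id)
}
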