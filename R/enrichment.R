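#' Exact upper-tail hypergeometric enrichment
#'
#' P(X >= k) when drawing n items from a universe of N containing K
#' successes. Vectorised over its arguments.
#'
#' @param k observed successes in the draw (0 <= k <= min(n, K)).
#' @param n draw size.
#' @param K successes in the universe.
#' @param N universe size.
#' @return exact upper-tail probability.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n < 0 | K < 0
  if (any(bad)) {
    stop_bad_arg("inconsistent hypergeometric counts (k=%s, n=%s, K=%s, N=%s)",
                 k[bad][1], n[bad][1], K[bad][1], N[bad][1])
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_bad_arg("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Motif over-representation in regulated promoters
#'
#' Scans every promoter with each motif; a gene "has" a motif when its
#' promoter contains at least one hit at the scan threshold. Enrichment
#' of motif-bearing genes among the regulated set relative to the
#' universe is scored with the exact hypergeometric upper tail and
#' flagged when p falls below `p_flag`.
#'
#' @param motifs named list of [pfm()] objects (a single `pfm` is
#'   accepted).
#' @param regulated character vector of regulated gene ids (nonempty,
#'   subset of `universe`).
#' @param universe character vector of all analyzed gene ids.
#' @param promoters named character vector of promoter sequences covering
#'   the universe.
#' @param scan_threshold bits threshold passed to [scan_pwm()] (default:
#'   60% of each motif's maximum score).
#' @param p_flag flagging threshold (default 1e-5, strict <).
#' @param ... further arguments to [scan_pwm()].
#' @return tibble (motif, k, n, K, N, p, flagged).
#' @export
promoter_overrepresentation <- function(motifs, regulated, universe,
                                        promoters, scan_threshold = NULL,
                                        p_flag = 1e-5, ...) {
  if (inherits(motifs, "pfm")) motifs <- list(motif1 = motifs)
  if (length(regulated) == 0) stop_bad_arg("empty regulated set")
  if (!all(regulated %in% universe)) {
    stop_bad_arg("regulated genes must be a subset of the universe")
  }
  miss <- setdiff(universe, names(promoters))
  if (length(miss) > 0) {
    stop_bad_arg("promoter missing for %d universe gene(s), e.g. %s",
                 length(miss), miss[1])
  }
  promoters <- promoters[universe]
  list_rbind(imap(motifs, function(m, name) {
    hits <- scan_pwm(promoters, m, threshold = scan_threshold, ...)
    with_motif <- unique(hits$sequence_id)
    k <- sum(regulated %in% with_motif)
    K <- length(with_motif)
    tibble(motif = name, k = k, n = length(regulated), K = K,
           N = length(universe),
           p = hypergeom_enrichment(k, length(regulated), K,
                                    length(universe)))
  })) %>%
    mutate(flagged = .data$p < p_flag) %>%
    arrange(.data$p)
}

#' Length- and chromosome-preserving shuffle of regions
#'
#' Background generator for region-based motif enrichment: each region is
#' replaced by a uniformly placed region of the same length on the same
#' chromosome.
#'
#' @param regions tibble (chrom, start, end).
#' @param chrom_sizes named chromosome lengths.
#' @param seed integer seed.
#' @return tibble of shuffled regions with the same lengths.
#' @export
shuffle_regions <- function(regions, chrom_sizes, seed = 1L) {
  validate_intervals(regions, "regions")
  set.seed(seed)
  len <- regions$end - regions$start
  maxs <- chrom_sizes[regions$chrom] - len
  if (any(maxs < 0)) stop_bad_arg("region longer than its chromosome")
  start <- floor(runif(nrow(regions), 0, maxs + 1))
  tibble(chrom = regions$chrom, start = as.integer(start),
         end = as.integer(start + len))
}
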