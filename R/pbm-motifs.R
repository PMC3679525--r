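#' Rank-based 8-mer E-scores from a probe set
#'
#' For every reverse-complement-collapsed k-mer, the E-score is the
#' area-under-the-ROC-curve of the intensities of probes containing the
#' k-mer (in either orientation) against all remaining probes, minus 0.5:
#' a rank statistic bounded in [-0.5, 0.5], symmetric under reverse
#' complement and invariant under any strictly monotone transform of the
#' intensities. K-mers absent from every probe are reported with a
#' missing E-score, never 0.
#'
#' @param probes tibble (probe_id, sequence, intensity).
#' @param kmer_length k-mer length (default 8).
#' @param complete also report absent k-mers (with NA); default TRUE.
#' @return tibble (kmer, escore, n_probes) over canonical k-mers
#'   (lexicographic minimum of the pair k-mer / reverse complement).
#' @export
compute_escores <- function(probes, kmer_length = 8, complete = TRUE) {
  stopifnot(all(c("sequence", "intensity") %in% names(probes)))
  L <- nchar(probes$sequence)
  if (any(L < kmer_length)) stop_bad_arg("probes shorter than kmer_length")

  occ <- list()
  for (len in unique(L)) {
    idx <- which(L == len)
    nw <- len - kmer_length + 1
    occ[[length(occ) + 1]] <- tibble(
      probe = rep(idx, each = nw),
      kmer = as.vector(vapply(probes$sequence[idx], function(s) {
        substring(s, seq_len(nw), seq_len(nw) + kmer_length - 1)
      }, character(nw), USE.NAMES = FALSE))
    )
  }
  occ <- list_rbind(occ)
  kmers <- unique(occ$kmer)
  canon_map <- setNames(canonical_kmer(kmers), kmers)
  occ$kmer <- unname(canon_map[occ$kmer])
  occ <- distinct(occ)

  r <- rank(probes$intensity)
  n_all <- nrow(probes)
  out <- occ %>%
    group_by(.data$kmer) %>%
    summarise(n_probes = n(), rank_sum = sum(r[.data$probe]),
              .groups = "drop") %>%
    mutate(
      escore = ifelse(
        .data$n_probes == n_all, NA_real_,
        (.data$rank_sum - .data$n_probes * (.data$n_probes + 1) / 2) /
          (.data$n_probes * (n_all - .data$n_probes)) - 0.5)
    ) %>%
    select("kmer", "escore", "n_probes")

  if (complete) {
    all_canon <- all_canonical_kmers(kmer_length)
    out <- tibble(kmer = all_canon) %>%
      left_join(out, by = "kmer") %>%
      mutate(n_probes = replace_na(.data$n_probes, 0L))
  }
  arrange(out, desc(.data$escore))
}

all_canonical_kmers <- function(k) {
  grid <- do.call(expand_grid, setNames(rep(list(DNA_BASES), k),
                                        sprintf("p%d", seq_len(k))))
  kmers <- do.call(paste0, grid)
  sort(unique(canonical_kmer(kmers)))
}

#' Look up the E-score of a k-mer (either orientation)
#'
#' @param escores output of [compute_escores()].
#' @param kmer character vector of k-mers.
#' @return numeric E-scores (NA when missing).
#' @export
escore_lookup <- function(escores, kmer) {
  key <- canonical_kmer(kmer)
  escores$escore[match(key, escores$kmer)]
}

#' Build a PFM by aligning high-scoring 8-mers
#'
#' The alignment-based PFM constructor: every k-mer with E-score strictly
#' above `e_threshold` is collected; the top-scoring one seeds an
#' ungapped alignment, and each further k-mer is added at the offset and
#' orientation (forward or reverse complement) maximizing matches to the
#' running consensus. Column base counts are weighted by each k-mer's
#' E-score (set `weight = "uniform"` for unweighted counts), and columns
#' covered by fewer than half of the aligned k-mers are trimmed (columns
#' covered by exactly half are kept).
#'
#' @param escores output of [compute_escores()].
#' @param e_threshold inclusion threshold on the E-score (default 0.45,
#'   strict >).
#' @param weight "escore" (default) or "uniform" column weighting.
#' @return a [pfm()]; the alignment (kmer, offset, orientation, weight)
#'   is attached as attribute `"alignment"`.
#' @export
pwm_align <- function(escores, e_threshold = 0.45,
                      weight = c("escore", "uniform")) {
  weight <- arg_match(weight)
  pass <- escores %>%
    filter(!is.na(.data$escore), .data$escore > e_threshold) %>%
    arrange(desc(.data$escore))
  if (nrow(pass) == 0) {
    stop_bad_arg("no k-mer passes the E-score threshold %.3g: empty motif",
                 e_threshold)
  }
  k <- nchar(pass$kmer[1])
  w <- if (weight == "escore") pass$escore else rep(1, nrow(pass))

  # aligned sequences as (kmer, offset) in a shared coordinate system
  aln <- tibble(kmer = pass$kmer[1], offset = 0L, orientation = "+",
                weight = w[1])
  counts <- weighted_counts(aln, k)
  if (nrow(pass) > 1) {
    for (i in 2:nrow(pass)) {
      cand <- c("+" = pass$kmer[i], "-" = revcomp(pass$kmer[i]))
      cons_codes <- apply(counts, 2, which.max)
      span <- as.integer(colnames(counts))
      best <- NULL
      for (orient in names(cand)) {
        codes <- match(strsplit(cand[[orient]], "")[[1]], DNA_BASES)
        for (off in (min(span) - k + 1):max(span)) {
          pos <- off + seq_len(k) - 1L
          keep <- pos %in% span
          if (!any(keep)) next
          matches <- sum(codes[keep] ==
                           cons_codes[match(pos[keep], span)])
          score <- c(matches, -abs(off), orient == "+")
          if (is.null(best) || compare_lex(score, best$score) > 0) {
            best <- list(offset = off, orientation = orient, score = score)
          }
        }
      }
      aln <- bind_rows(aln, tibble(kmer = cand[[best$orientation]],
                                   offset = best$offset,
                                   orientation = best$orientation,
                                   weight = w[i]))
      counts <- weighted_counts(aln, k)
    }
  }

  # trim columns covered by fewer than half of the aligned k-mers
  coverage <- weighted_counts(aln %>% mutate(weight = 1), k)
  keep <- colSums(coverage) * 2 >= nrow(aln)
  counts <- counts[, keep, drop = FALSE]
  out <- pfm(sweep(counts, 2, colSums(counts), "/"))
  attr(out, "alignment") <- aln
  out
}

compare_lex <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

# 4 x span weighted base counts of an alignment; columns named by offset
weighted_counts <- function(aln, k) {
  span <- min(aln$offset):(max(aln$offset) + k - 1L)
  m <- matrix(0, nrow = 4, ncol = length(span),
              dimnames = list(DNA_BASES, span))
  for (i in seq_len(nrow(aln))) {
    codes <- strsplit(aln$kmer[i], "")[[1]]
    pos <- match(aln$offset[i] + seq_len(k) - 1L, span)
    for (j in seq_len(k)) {
      m[codes[j], pos[j]] <- m[codes[j], pos[j]] + aln$weight[i]
    }
  }
  m
}

#' Cross-array evaluation of a PFM
#'
#' Predicts each probe's intensity as the maximum log-odds window score
#' of the PFM over both strands and returns the Pearson correlation of
#' predictions with the measured intensities across all probes.
#'
#' @param x a [pfm()].
#' @param probes tibble (probe_id, sequence, intensity); probes must be
#'   at least as long as the motif.
#' @param ... passed to [max_pwm_score()].
#' @return Pearson r.
#' @export
evaluate_pfm <- function(x, probes, ...) {
  pred <- max_pwm_score(probes$sequence, x, ...)
  if (sd(pred) == 0) stop_bad_arg("predictions have zero variance: r undefined")
  cor(pred, probes$intensity)
}

#' Choose the best PFM by cross-design correlation
#'
#' Each candidate PFM is scored on the array design it was NOT trained
#' on; the candidate with the highest Pearson correlation wins. Ties
#' break to the wider PFM, then to training-design label order.
#'
#' @param candidates list of lists with elements `pfm` (a [pfm()]) and
#'   `design` (training design label).
#' @param probe_sets named list of probe tibbles by design label; every
#'   candidate needs its opposite design present.
#' @param ... passed to [evaluate_pfm()].
#' @return the winning `pfm`, with the evaluation table in attribute
#'   `"evaluation"`.
#' @export
select_best_pfm <- function(candidates, probe_sets, ...) {
  stopifnot(length(candidates) > 0)
  eval_tbl <- list_rbind(imap(candidates, function(cand, i) {
    opp <- setdiff(names(probe_sets), cand$design)
    if (length(opp) == 0) {
      stop_bad_arg("no opposite design available for candidate trained on %s",
                   cand$design)
    }
    tibble(candidate = as.integer(i), design = cand$design,
           eval_design = opp[1], width = ncol(cand$pfm),
           r = evaluate_pfm(cand$pfm, probe_sets[[opp[1]]], ...))
  }))
  ord <- order(-eval_tbl$r, -eval_tbl$width, eval_tbl$design)
  winner <- candidates[[eval_tbl$candidate[ord[1]]]]$pfm
  attr(winner, "evaluation") <- eval_tbl[ord, ]
  winner
}
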