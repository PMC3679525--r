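#' Expression call per gene
#'
#' A gene is expressed if any single replicate at any timepoint exceeds
#' the RPKM threshold (strictly greater than; a gene sitting exactly at
#' the threshold everywhere is not expressed).
#'
#' @param expression long tibble (gene_id, timepoint, replicate, rpkm).
#' @param threshold RPKM threshold, default 1.
#' @return tibble (gene_id, expressed, max_rpkm).
#' @export
call_expressed <- function(expression, threshold = 1) {
  expression %>%
    group_by(.data$gene_id) %>%
    summarise(max_rpkm = max(.data$rpkm),
              expressed = any(.data$rpkm > threshold),
              .groups = "drop")
}

#' Differential expression between consecutive timepoints
#'
#' For every consecutive timepoint pair a two-sample t test is run on the
#' replicate values per gene (pooled-variance Student by default, Welch
#' optionally), and a call is emitted when the test passes `alpha` AND
#' the un-logged replicate means differ by at least `min_pct` percent of
#' the earlier mean. The t test runs on log2(rpkm + pseudocount), the
#' scale on which replicate noise is closest to Gaussian; the percent
#' filter stays on the raw RPKM means. With a zero prior mean the percent
#' change is undefined and the gene is called only if the current mean is
#' positive and the test passes. Direction follows the sign of the mean
#' difference.
#'
#' @param expression long tibble (gene_id, timepoint, replicate, rpkm);
#'   at least 2 replicates per timepoint.
#' @param alpha per-test significance level (default 0.05); no
#'   multiple-testing correction is applied by default, set
#'   `adjust = "BH"` for step-up adjusted calls.
#' @param min_pct minimum percent difference from the prior timepoint.
#' @param var_equal pooled-variance Student t (TRUE, default) or Welch.
#' @param adjust "none" (default) or "BH".
#' @param test_scale "log2" (default) or "raw" replicate values for the t
#'   test.
#' @param pseudocount added before log2 for the test scale.
#' @return tibble (gene_id, timepoint, prev_timepoint, direction,
#'   p_value, pct_change, log2fc) with one row per emitted call.
#' @export
call_de <- function(expression, alpha = 0.05, min_pct = 50, var_equal = TRUE,
                    adjust = c("none", "BH"), test_scale = c("log2", "raw"),
                    pseudocount = 0.5) {
  adjust <- arg_match(adjust)
  test_scale <- arg_match(test_scale)
  tps <- sort(unique(expression$timepoint))
  if (length(tps) < 2) stop_bad_arg("need >= 2 timepoints")

  vals <- expression %>%
    mutate(y = if (test_scale == "log2") log2(.data$rpkm + pseudocount)
               else .data$rpkm) %>%
    group_by(.data$gene_id, .data$timepoint) %>%
    summarise(n = n(), m_raw = mean(.data$rpkm), m = mean(.data$y),
              v = var(.data$y), .groups = "drop")
  if (any(vals$n < 2)) stop_bad_arg("need >= 2 replicates at every timepoint")

  pairs <- tibble(prev_timepoint = tps[-length(tps)], timepoint = tps[-1])
  res <- vals %>%
    inner_join(pairs, by = "timepoint") %>%
    inner_join(vals %>%
                 rename(prev_timepoint = "timepoint", n0 = "n",
                        m_raw0 = "m_raw", m0 = "m", v0 = "v"),
               by = c("gene_id", "prev_timepoint")) %>%
    mutate(
      sp2 = ((.data$n - 1) * .data$v + (.data$n0 - 1) * .data$v0) /
        (.data$n + .data$n0 - 2),
      se = if (var_equal) sqrt(.data$sp2 * (1 / .data$n + 1 / .data$n0))
           else sqrt(.data$v / .data$n + .data$v0 / .data$n0),
      df = if (var_equal) .data$n + .data$n0 - 2
           else (.data$v / .data$n + .data$v0 / .data$n0)^2 /
             ((.data$v / .data$n)^2 / (.data$n - 1) +
                (.data$v0 / .data$n0)^2 / (.data$n0 - 1)),
      tstat = (.data$m - .data$m0) / .data$se,
      p_value = ifelse(.data$se == 0,
                       ifelse(.data$m == .data$m0, 1, 0),
                       2 * pt(-abs(.data$tstat), .data$df)),
      pct_change = ifelse(.data$m_raw0 == 0, Inf,
                          100 * abs(.data$m_raw - .data$m_raw0) / .data$m_raw0),
      direction = ifelse(.data$m_raw >= .data$m_raw0, "up", "down"),
      log2fc = log2((.data$m_raw + pseudocount) / (.data$m_raw0 + pseudocount))
    )
  if (adjust == "BH") res$p_value <- p.adjust(res$p_value, method = "BH")
  res %>%
    filter(.data$p_value <= alpha,
           ifelse(is.infinite(.data$pct_change), .data$m_raw > 0,
                  .data$pct_change >= min_pct)) %>%
    select("gene_id", "timepoint", "prev_timepoint", "direction",
           "p_value", "pct_change", "log2fc") %>%
    arrange(.data$gene_id, .data$timepoint)
}

#' Classify TF candidate targets by their transcriptional response
#'
#' Partition of the gene universe: a target with at least one
#' differential-expression call is regulated (EIN3-R); a target expressed
#' but never called is non-regulated (EIN3-NR); a target never expressed
#' is not detected (EIN3-ND); everything else is a nontarget.
#'
#' @param universe character vector of all gene ids.
#' @param targets character vector of TF candidate target gene ids.
#' @param expressed output of [call_expressed()] (or a character vector
#'   of expressed gene ids).
#' @param de_calls output of [call_de()].
#' @return tibble (gene_id, class) with class in EIN3-R / EIN3-NR /
#'   EIN3-ND / nontarget; the classes partition `universe`.
#' @export
classify_genes <- function(universe, targets, expressed, de_calls) {
  if (is.data.frame(expressed)) {
    expressed <- expressed$gene_id[expressed$expressed]
  }
  de_genes <- unique(de_calls$gene_id)
  tibble(gene_id = universe) %>%
    mutate(class = dplyr::case_when(
      .data$gene_id %in% targets & .data$gene_id %in% de_genes ~ "EIN3-R",
      .data$gene_id %in% targets & .data$gene_id %in% expressed ~ "EIN3-NR",
      .data$gene_id %in% targets ~ "EIN3-ND",
      TRUE ~ "nontarget"
    ))
}

#' Up/down fractions of differentially expressed genes
#'
#' Fractions of DE genes with any up call and any down call (a gene
#' called both ways at different timepoints counts in both), overall and
#' within the regulated-target class when a classification is given.
#'
#' @param de_calls output of [call_de()].
#' @param classes optional output of [classify_genes()]; adds an "EIN3-R"
#'   scope restricted to regulated targets.
#' @return tibble (scope, n_genes, frac_up, frac_down, frac_both).
#' @export
direction_summary <- function(de_calls, classes = NULL) {
  summarise_dir <- function(calls, scope) {
    per_gene <- calls %>%
      group_by(.data$gene_id) %>%
      summarise(up = any(.data$direction == "up"),
                down = any(.data$direction == "down"), .groups = "drop")
    n <- nrow(per_gene)
    tibble(scope = scope, n_genes = n,
           frac_up = if (n == 0) 0 else mean(per_gene$up),
           frac_down = if (n == 0) 0 else mean(per_gene$down),
           frac_both = if (n == 0) 0 else mean(per_gene$up & per_gene$down))
  }
  out <- summarise_dir(de_calls, "all")
  if (!is.null(classes)) {
    reg <- classes$gene_id[classes$class == "EIN3-R"]
    out <- bind_rows(out,
                     summarise_dir(filter(de_calls, .data$gene_id %in% reg),
                                   "EIN3-R"))
  }
  out
}

#' Ordinary least-squares fit of expression change on binding change
#'
#' Regresses the per-gene expression log2 change at a timepoint on the
#' assigned region's binding log2 change, quantifying how far binding
#' level predicts transcriptional response.
#'
#' @param data tibble holding the paired changes.
#' @param binding,expression column names of the binding and expression
#'   log2 changes.
#' @return tibble (slope, intercept, r_squared, p_value, n).
#' @export
binding_expression_regression <- function(data, binding = "delta_binding",
                                          expression = "delta_expression") {
  x <- data[[binding]]
  y <- data[[expression]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_bad_arg("need >= 3 finite pairs, got %d", length(x))
  if (var(x) == 0) stop_bad_arg("zero variance in binding changes")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # exact fits trip a benign warning
  tibble(slope = coef(fit)[["x"]], intercept = coef(fit)[["(Intercept)"]],
         r_squared = s$r.squared,
         p_value = s$coefficients["x", "Pr(>|t|)"], n = length(x))
}

#' Cumulative kinetics of the transcriptional response
#'
#' For every timepoint, the cumulative fraction of ever-differentially-
#' expressed genes whose first call occurred at or before it; the curve
#' is non-decreasing and ends at 1.
#'
#' @param de_calls output of [call_de()].
#' @param timepoints the full ordered timecourse.
#' @return tibble (timepoint, n_first, cum_fraction).
#' @export
response_kinetics <- function(de_calls, timepoints) {
  first <- de_calls %>%
    group_by(.data$gene_id) %>%
    summarise(first_tp = min(.data$timepoint), .groups = "drop")
  n_total <- nrow(first)
  tibble(timepoint = sort(timepoints)) %>%
    mutate(n_first = map_int(.data$timepoint,
                             ~ sum(first$first_tp == .x)),
           cum_fraction = if (n_total == 0) 0 else
             cumsum(.data$n_first) / n_total)
}

#' Rank temporal binding profiles by a moderated timecourse statistic
#'
#' Scores each region by the sum over post-0 hr timepoints of its squared
#' replicate-mean log2 change, scaled by a per-region replicate variance
#' shrunk halfway toward the global mean replicate variance (a moderated
#' Hotelling-type score in the spirit of replicated-timecourse ranking
#' statistics). Flat profiles score near zero; strong coherent temporal
#' change ranks first.
#'
#' @param log2_tbl long tibble (region_id, timepoint, replicate, log2fc)
#'   of log2 ratios versus 0 hr; needs >= 2 replicates.
#' @param k optionally return only the top k regions (with a warning if
#'   k exceeds the number of regions).
#' @return tibble (region_id, score, rank), best first.
#' @export
rank_timecourses <- function(log2_tbl, k = NULL) {
  per_tp <- log2_tbl %>%
    group_by(.data$region_id, .data$timepoint) %>%
    summarise(n = n(), m = mean(.data$log2fc), v = var(.data$log2fc),
              .groups = "drop")
  if (any(per_tp$n < 2)) stop_bad_arg("need >= 2 replicates per timepoint")
  t0 <- min(per_tp$timepoint)
  per_region <- per_tp %>%
    group_by(.data$region_id) %>%
    summarise(s2 = mean(.data$v),
              dev2 = sum(.data$m[.data$timepoint != t0]^2),
              .groups = "drop")
  s2_bar <- mean(per_region$s2)
  out <- per_region %>%
    mutate(score = .data$dev2 / (0.5 * (.data$s2 + s2_bar) + 1e-12)) %>%
    arrange(desc(.data$score)) %>%
    mutate(rank = row_number()) %>%
    select("region_id", "score", "rank")
  if (!is.null(k)) {
    if (k > nrow(out)) {
      warn(sprintf("k = %d exceeds the %d available regions; returning all",
                   k, nrow(out)))
      k <- nrow(out)
    }
    out <- head(out, k)
  }
  out
}
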