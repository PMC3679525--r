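perfect_pfm <- function(word) {
  m <- matrix(0, 4, nchar(word), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nchar(word))) m[substr(word, i, i), i] <- 1
  pfm(m)
}

test_that("log-odds scanning matches closed-form scores", {
  p <- perfect_pfm("ACGT")
  hits <- scan_pwm(c(s1 = "ACGT"), p, pseudocount = 1e-9, threshold = 7.9)
  expect_equal(hits$score[hits$strand == "+"], 8, tolerance = 1e-5)

  # mismatch under a zero-frequency column stays finite
  lo <- pwm_log_odds(p, pseudocount = 0.01)
  want <- 3 * log2((1 + 0.01 * 0.25) / (1.01 * 0.25)) +
    log2(0.01 * 0.25 / (1.01 * 0.25))
  hits2 <- scan_pwm(c(s1 = "ACGA"), p, pseudocount = 0.01, threshold = -Inf)
  expect_equal(hits2$score[hits2$strand == "+" & hits2$offset == 0], want,
               tolerance = 1e-9)

  # shorter than the motif: no hits
  expect_identical(nrow(scan_pwm(c(s = "AC"), p)), 0L)
})

test_that("scanning the reverse complement swaps strands, not scores", {
  set.seed(21)
  p <- pfm(matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.1, 0.6, 0.2, 0.1,
                    0.25, 0.25, 0.25, 0.25,
                    0.05, 0.05, 0.8, 0.1), 4, 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL)))
  seqs <- c(x = paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""))
  fwd <- scan_pwm(seqs, p, threshold = -Inf)
  rev <- scan_pwm(setNames(revcomp(seqs), "x"), p, threshold = -Inf)
  key <- function(h, L, W) {
    h$mirror <- L - W - h$offset
    h[order(h$strand, h$offset), ]
  }
  fwd_sorted <- fwd[order(fwd$strand, fwd$offset), ]
  rev_sorted <- rev[order(rev$strand == "+", 50 - 4 - rev$offset), ]
  expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-12)
  f_plus <- fwd[fwd$strand == "+", ]
  r_minus <- rev[rev$strand == "-", ]
  r_minus$offset <- 50 - 4 - r_minus$offset
  r_minus <- r_minus[order(r_minus$offset), ]
  expect_equal(f_plus$score, r_minus$score, tolerance = 1e-12)
})

test_that("hypergeometric tails are exact", {
  expect_equal(hypergeom_enrichment(5, 10, 5, 20), 3003 / 184756)
  expect_equal(hypergeom_enrichment(0, 10, 5, 20), 1)
  expect_equal(hypergeom_enrichment(6, 6, 6, 6), 1)
  expect_error(hypergeom_enrichment(7, 6, 6, 6), "inconsistent")
  set.seed(12)
  for (i in 1:200) {
    N <- sample(2:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_enrichment(k, n, K, N), oracle_hyper(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0,1")
})

test_that("E-scores are rank AUCs with reverse-complement symmetry", {
  # foreground probes all rank above background: E = 0.5
  probes <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6),
    sequence = c("ACGTACGTAA", "ACGTACGTCC", "TTTTGGGGCC",
                 "GGGGCCCCAA", "CCCCAAAATT", "GGGGTTTTAA"),
    intensity = c(10, 9, 1, 2, 3, 4))
  es <- compute_escores(probes, complete = FALSE)
  expect_equal(escore_lookup(es, "ACGTACGT"), 0.5)
  expect_equal(escore_lookup(es, "ACGTACGT"),
               escore_lookup(es, revcomp("ACGTACGT")))

  # invariance under strictly monotone intensity transforms
  es2 <- compute_escores(dplyr::mutate(probes, intensity = exp(intensity)),
                         complete = FALSE)
  expect_equal(es$escore, es2$escore)

  # absent k-mer is missing, not zero
  full <- compute_escores(probes, complete = TRUE)
  expect_true(any(is.na(full$escore)))
  expect_identical(nrow(full), length(bindwave:::all_canonical_kmers(8)))
})

test_that("permuted intensities give near-zero E-scores", {
  set.seed(30)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:1000, function(i) {
    paste(sample(bases, 20, TRUE), collapse = "")
  }, character(1))
  with_kmer <- sample(1000, 500)
  seqs[with_kmer] <- paste0(substr(seqs[with_kmer], 1, 12), "ACGTACGT")
  probes <- tibble::tibble(probe_id = sprintf("p%d", 1:1000),
                           sequence = seqs,
                           intensity = rnorm(1000))  # independent of content
  es <- compute_escores(probes, complete = FALSE)
  expect_lt(abs(escore_lookup(es, "ACGTACGT")), 0.05)
})

test_that("motif construction from aligned 8-mers handles the boundaries", {
  # all passing 8-mers identical: width 8, certainty 1
  es <- tibble::tibble(kmer = c("ACGTACGT", "TTTTTTTA"),
                       escore = c(0.49, 0.1), n_probes = 5L)
  got <- pwm_align(es)
  expect_identical(ncol(got), 8L)
  expect_true(all(apply(unclass(got), 2, max) == 1))

  # two 8-mers offset by one: width 9, half-covered flanks retained
  es2 <- tibble::tibble(kmer = c("ACGTACGT", "CGTACGTA"),
                        escore = c(0.49, 0.48), n_probes = 5L)
  got2 <- pwm_align(es2, weight = "uniform")
  expect_identical(ncol(got2), 9L)

  # exactly at the threshold: excluded (strict >)
  es3 <- tibble::tibble(kmer = c("ACGTACGT", "GGGGGGGA"),
                        escore = c(0.46, 0.45), n_probes = 5L)
  got3 <- pwm_align(es3)
  expect_identical(ncol(got3), 8L)
  expect_identical(pfm_consensus(got3), "ACGTACGT")

  expect_error(pwm_align(es3, e_threshold = 0.5), "no k-mer")
})

test_that("planted-motif recovery beats a shuffled decoy cross-design", {
  cfg <- sim_config(seed = 7)
  probes <- default_pbm()
  planted <- cfg$pbm_spec$pfm
  rec <- list()
  for (d in cfg$pbm_spec$designs) {
    rec[[d]] <- pwm_align(default_escores(d))
    cc <- pfm_column_correlation(rec[[d]], planted)
    expect_gte(cc$correlation, 0.9)
  }
  sets <- split(probes, probes$design)
  cands <- list(list(pfm = planted, design = "ME"),
                list(pfm = shuffle_pfm(planted, 3), design = "ME"),
                list(pfm = shuffle_pfm(planted, 5), design = "ME"))
  best <- select_best_pfm(cands, sets)
  expect_identical(pfm_consensus(best), pfm_consensus(planted))

  # evaluation sanity: perfect and inverted predictors
  sub <- sets$ME[1:50, ]
  sub$intensity <- max_pwm_score(sub$sequence, planted)
  expect_equal(evaluate_pfm(planted, sub), 1)
  sub$intensity <- -sub$intensity
  expect_equal(evaluate_pfm(planted, sub), -1)

  single <- select_best_pfm(list(list(pfm = planted, design = "ME")), sets)
  expect_identical(pfm_consensus(single), pfm_consensus(planted))
})

test_that("promoter over-representation uses the exact tail", {
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n, len) {
    vapply(seq_len(n), function(i) paste(sample(bases, len, TRUE),
                                         collapse = ""), character(1))
  }
  universe <- sprintf("g%04d", 1:300)
  proms <- setNames(rand_seq(300, 60), universe)
  regulated <- universe[1:60]
  with_motif <- c(universe[1:30], universe[61:75])
  for (g in with_motif) {
    proms[g] <- paste0(substr(proms[g], 1, 26), "ATGTATCT",
                       substr(proms[g], 35, 60))
  }
  p <- perfect_pfm("ATGTATCT")
  got <- promoter_overrepresentation(p, regulated, universe, proms,
                                     scan_threshold = 15.9)
  expect_gte(got$k, 30)
  expect_equal(got$p, oracle_hyper(got$k, got$n, got$K, got$N))
  expect_true(got$flagged)

  # a motif absent everywhere scores p = 1
  absent <- perfect_pfm("GTCAGTCA")
  got2 <- promoter_overrepresentation(absent, regulated, universe, proms,
                                      scan_threshold = 15.9)
  expect_equal(got2$p, 1)

  # regulated = universe cannot be enriched
  got3 <- promoter_overrepresentation(p, universe, universe, proms,
                                      scan_threshold = 15.9)
  expect_equal(got3$p, 1)

  expect_error(promoter_overrepresentation(p, character(), universe, proms),
               "empty regulated")
})

test_that("region shuffling preserves lengths and chromosomes", {
  st <- default_study()
  regions <- default_consensus()$regions
  shuf <- shuffle_regions(regions, st$config$chrom_sizes, seed = 2)
  expect_equal(shuf$end - shuf$start, regions$end - regions$start)
  expect_identical(shuf$chrom, regions$chrom)
  expect_true(all(shuf$start >= 0 &
                    shuf$end <= st$config$chrom_sizes[shuf$chrom]))
})

test_that("MEME round trip preserves motifs", {
  p <- default_planted_pfm()
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(planted = p), path)
  back <- read_meme(path)
  expect_identical(names(back), "planted")
  expect_equal(unclass(back$planted), unclass(p), tolerance = 1e-5)
})
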