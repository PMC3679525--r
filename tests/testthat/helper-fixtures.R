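# Shared fixtures, generated once per test run and memoised; all
# randomness is seed-fixed through sim_config.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_study <- function() {
  memo_fixture("study", simulate_study(sim_config(seed = 7)))
}

noise_free_study <- function() {
  memo_fixture("study0", simulate_study(sim_config_noise_free(sim_config(seed = 3))))
}

default_pbm <- function() {
  memo_fixture("pbm", simulate_pbm(sim_config(seed = 7)))
}

default_escores <- function(design) {
  memo_fixture(paste0("escores_", design), {
    probes <- default_pbm()
    compute_escores(probes[probes$design == design, ])
  })
}

# consensus -> regions -> counts -> normalised RPKM for a study
consensus_pipeline <- function(study) {
  cons <- majority_vote(study$peaks, callers = study$config$caller_spec$caller)
  regions <- unify_regions(cons)
  counts <- transfer_counts(regions, study$truth$regions, study$counts)
  rpkm <- median_normalize(quantify_regions(regions, counts))
  list(consensus = cons, regions = regions, rpkm = rpkm)
}

default_consensus <- function() {
  memo_fixture("consensus", consensus_pipeline(default_study()))
}

default_de <- function() {
  memo_fixture("de", call_de(default_study()$expression))
}

# ---- independent oracles ------------------------------------------------

# brute-force pairwise closure: merge any two same-chrom intervals with
# gap < max_gap until a fixed point, then sort
oracle_merge <- function(intervals, max_gap) {
  xs <- split(intervals, intervals$chrom)
  out <- lapply(names(xs), function(ch) {
    iv <- as.data.frame(xs[[ch]][c("start", "end")])
    repeat {
      merged <- FALSE
      n <- nrow(iv)
      if (n < 2) break
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
          if (gap < max_gap) {
            iv$start[i] <- min(iv$start[i], iv$start[j])
            iv$end[i] <- max(iv$end[i], iv$end[j])
            iv <- iv[-j, , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    iv$chrom <- ch
    iv
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end")]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, chroms = c("c1", "c2"), span = 2000) {
  start <- sample.int(span, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(300, n, replace = TRUE))
}

# exact hypergeometric upper tail by direct enumeration
oracle_hyper <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
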