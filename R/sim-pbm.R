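#' De Bruijn sequence over the DNA alphabet
#'
#' Cycle of length 4^n containing every n-mer exactly once (as a circular
#' sequence), built with the Lyndon-word (FKM) construction. Used to lay
#' out synthetic universal-array probes that jointly cover all 8-mers.
#'
#' @param n word length.
#' @param alphabet permutation of A,C,G,T; different permutations give
#'   different (but equally covering) designs.
#' @return a single character string of length 4^n.
#' @export
de_bruijn_dna <- function(n, alphabet = DNA_BASES) {
  stopifnot(length(alphabet) == 4, n >= 1)
  k <- 4L
  a <- integer(n + 1L)
  out <- integer(k^n)
  pos <- 0L
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) {
        out[(pos + 1L):(pos + p)] <<- a[2:(p + 1L)]
        pos <<- pos + p
      }
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= k - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  paste(alphabet[out[seq_len(pos)] + 1L], collapse = "")
}

#' Simulate two-design protein-binding microarrays
#'
#' Each design is a tiling of a distinct de Bruijn order-8 cycle into
#' probes of `probe_length` with 7 bp overlap (so every 8-mer occurs at
#' least once per design). A probe's intensity is the maximum log-odds
#' window score of the planted PFM over both strands, plus Gaussian noise
#' of sd `noise_sd`.
#'
#' @param config a [sim_config()]; uses `config$pbm_spec`.
#' @return tibble (probe_id, sequence, intensity, design) covering both
#'   designs.
#' @export
simulate_pbm <- function(config) {
  ps <- config$pbm_spec
  if (ps$probe_length < 8) stop_bad_arg("probe_length must be >= 8")
  set.seed(sim_seed(config, "pbm"))
  alphabets <- list(DNA_BASES, c("T", "G", "A", "C"))
  out <- list()
  for (d in seq_along(ps$designs)) {
    design <- ps$designs[d]
    cyc <- de_bruijn_dna(8, alphabets[[((d - 1) %% 2) + 1]])
    wrapped <- paste0(cyc, substr(cyc, 1, 7))
    step <- ps$probe_length - 7L
    starts <- seq(1L, nchar(cyc), by = step)
    probes <- substring(wrapped, starts, starts + ps$probe_length - 1L)
    score <- max_pwm_score(probes, ps$pfm)
    out[[d]] <- tibble(
      probe_id = sprintf("%s_%05d", design, seq_along(probes)),
      sequence = probes,
      intensity = score + rnorm(length(probes), 0, ps$noise_sd),
      design = design
    )
  }
  list_rbind(out)
}
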