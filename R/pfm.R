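#' Position frequency matrices
#'
#' A `pfm` is a 4 x width numeric matrix of base frequencies (rows A, C,
#' G, T; every column sums to 1). It is the exchange format between the
#' PBM-derived motif constructor, the cross-array evaluator and the
#' promoter scanner.
#'
#' @param x numeric matrix, 4 rows (A,C,G,T) by width columns; columns
#'   must each sum to 1 within 1e-9.
#' @return a `pfm` object.
#' @export
pfm <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != 4) stop_bad_arg("a PFM needs 4 rows (A,C,G,T), got %d", nrow(x))
  if (ncol(x) < 1) stop_bad_arg("a PFM needs width >= 1")
  if (is.null(rownames(x))) rownames(x) <- DNA_BASES
  x <- x[DNA_BASES, , drop = FALSE]
  cs <- colSums(x)
  if (any(abs(cs - 1) > 1e-9) || any(x < 0)) {
    stop_bad_arg("PFM columns must be nonnegative and sum to 1 (max deviation %.3g)",
                 max(abs(cs - 1)))
  }
  structure(x, class = c("pfm", "matrix", "array"))
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> width", ncol(x), " consensus", pfm_consensus(x), "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @rdname pfm
#' @export
pfm_consensus <- function(x) {
  paste(DNA_BASES[apply(unclass(x), 2, which.max)], collapse = "")
}

#' @param object,x a `pfm`.
#' @param ... unused.
#' @describeIn pfm long tibble (position, base, freq).
#' @export
tidy.pfm <- function(x, ...) {
  m <- unclass(x)
  tibble(position = rep(seq_len(ncol(m)), each = 4),
         base = rep(DNA_BASES, ncol(m)),
         freq = as.vector(m))
}

#' Reverse complement of a PFM
#' @param x a [pfm()].
#' @return the reverse-complemented `pfm`.
#' @export
revcomp_pfm <- function(x) {
  m <- unclass(x)[rev(DNA_BASES), rev(seq_len(ncol(x))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pfm(m)
}

#' Log-odds (PWM) form of a PFM
#'
#' score contribution of base b at position i is
#' log2((f_i(b) + pseudocount * bg(b)) / ((1 + pseudocount) * bg(b))),
#' so a zero-frequency base stays finite for any positive pseudocount.
#'
#' @param x a [pfm()].
#' @param background named base frequencies summing to 1, all positive.
#' @param pseudocount nonnegative pseudocount weight.
#' @return 4 x width matrix of bit scores.
#' @export
pwm_log_odds <- function(x, background = uniform_background(), pseudocount = 0.01) {
  bg <- check_background(background)
  m <- unclass(x)
  log2((m + pseudocount * bg) / ((1 + pseudocount) * bg))
}

uniform_background <- function() setNames(rep(0.25, 4), DNA_BASES)

check_background <- function(background) {
  if (is.null(names(background))) names(background) <- DNA_BASES
  bg <- background[DNA_BASES]
  if (anyNA(bg) || any(bg <= 0) || abs(sum(bg) - 1) > 1e-6) {
    stop_bad_arg("background must be positive frequencies over A,C,G,T summing to 1")
  }
  bg
}

# score all windows of an integer code matrix (n sequences x L) under a
# 4 x W log-odds matrix; returns n x (L - W + 1)
score_windows <- function(codes, lo) {
  W <- ncol(lo)
  L <- ncol(codes)
  nw <- L - W + 1
  out <- matrix(0, nrow = nrow(codes), ncol = nw)
  for (w in seq_len(nw)) {
    s <- 0
    for (i in seq_len(W)) s <- s + lo[cbind(codes[, w + i - 1L], i)]
    out[, w] <- s
  }
  out
}

#' Scan sequences with a PFM
#'
#' Log-odds scanning of both strands in the style of matrix-screening
#' tools: every window scoring at or above `threshold` bits is reported.
#' Offsets are 0-based positions of the window on the given (plus-strand)
#' sequence; minus-strand hits are windows whose reverse complement
#' matches the motif.
#'
#' @param sequences named character vector of DNA sequences.
#' @param x a [pfm()].
#' @param background,pseudocount see [pwm_log_odds()].
#' @param threshold minimum score in bits; default 60% of the maximum
#'   achievable score.
#' @param both_strands scan the reverse strand too?
#' @return tibble (sequence_id, offset, strand, score), ordered by
#'   sequence then offset. Sequences shorter than the motif produce no
#'   hits.
#' @export
scan_pwm <- function(sequences, x, background = uniform_background(),
                     threshold = NULL, pseudocount = 0.01,
                     both_strands = TRUE) {
  stopifnot(inherits(x, "pfm"))
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  lo <- pwm_log_odds(x, background, pseudocount)
  lo_rc <- pwm_log_odds(revcomp_pfm(x), background, pseudocount)
  if (is.null(threshold)) threshold <- 0.6 * sum(apply(lo, 2, max))
  W <- ncol(x)

  lens <- nchar(sequences)
  hits <- list()
  for (L in unique(lens[lens >= W])) {
    idx <- which(lens == L)
    codes <- encode_dna(sequences[idx])
    sc_f <- score_windows(codes, lo)
    per_strand <- list(`+` = sc_f)
    if (both_strands) per_strand$`-` <- score_windows(codes, lo_rc)
    for (strand in names(per_strand)) {
      sc <- per_strand[[strand]]
      hit <- which(sc >= threshold, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        hits[[length(hits) + 1]] <- tibble(
          sequence_id = names(sequences)[idx][hit[, 1]],
          offset = as.integer(hit[, 2] - 1L),
          strand = strand,
          score = sc[hit]
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(sequence_id = character(), offset = integer(),
                  strand = character(), score = numeric()))
  }
  list_rbind(hits) %>% arrange(.data$sequence_id, .data$offset, .data$strand)
}

#' Best window score per sequence
#'
#' The maximum log-odds window score over both strands, used as the
#' PFM's intensity prediction for a probe sequence.
#'
#' @inheritParams scan_pwm
#' @return numeric vector, one score per sequence.
#' @export
max_pwm_score <- function(sequences, x, background = uniform_background(),
                          pseudocount = 0.01, both_strands = TRUE) {
  stopifnot(inherits(x, "pfm"))
  W <- ncol(x)
  lens <- nchar(sequences)
  if (any(lens < W)) stop_bad_arg("all sequences must be at least motif width")
  lo <- pwm_log_odds(x, background, pseudocount)
  lo_rc <- pwm_log_odds(revcomp_pfm(x), background, pseudocount)
  out <- numeric(length(sequences))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    codes <- encode_dna(sequences[idx])
    sc <- apply(score_windows(codes, lo), 1, max)
    if (both_strands) {
      sc <- pmax(sc, apply(score_windows(codes, lo_rc), 1, max))
    }
    out[idx] <- sc
  }
  out
}

#' Column-wise similarity of two PFMs
#'
#' Slides one PFM against the other (both orientations), and for the
#' ungapped offset maximizing the mean per-column Pearson correlation over
#' the overlap (requiring at least `min_overlap` columns) returns that
#' mean correlation. Used to compare a recovered motif with a planted one.
#'
#' @param a,b [pfm()] objects.
#' @param min_overlap minimum overlapping columns considered.
#' @return list(correlation, offset, orientation).
#' @export
pfm_column_correlation <- function(a, b, min_overlap = 4L) {
  best <- list(correlation = -Inf, offset = NA_integer_, orientation = "+")
  for (orient in c("+", "-")) {
    bb <- if (orient == "+") unclass(b) else unclass(revcomp_pfm(b))
    aa <- unclass(a)
    for (off in seq(-(ncol(bb) - min_overlap), ncol(aa) - min_overlap)) {
      ia <- max(1, 1 + off):min(ncol(aa), ncol(bb) + off)
      ib <- ia - off
      if (length(ia) < min_overlap) next
      cc <- mean(vapply(seq_along(ia), function(j) {
        ca <- aa[, ia[j]]
        cb <- bb[, ib[j]]
        if (sd(ca) == 0 || sd(cb) == 0) return(as.numeric(all(ca == cb)))
        cor(ca, cb)
      }, numeric(1)))
      if (cc > best$correlation) {
        best <- list(correlation = cc, offset = off, orientation = orient)
      }
    }
  }
  best
}

#' Column-shuffled decoy PFM
#'
#' Permutes the columns of a PFM (never the identity permutation), giving
#' a decoy with identical information content but scrambled positional
#' structure.
#'
#' @param x a [pfm()].
#' @param seed integer seed.
#' @return a `pfm`.
#' @export
shuffle_pfm <- function(x, seed = 1L) {
  set.seed(seed)
  W <- ncol(x)
  repeat {
    perm <- sample(W)
    if (!all(perm == seq_len(W)) || W == 1) break
  }
  pfm(unclass(x)[, perm, drop = FALSE])
}

#' Read and write motifs in MEME minimal format
#'
#' @param path file path.
#' @return `read_meme`: named list of [pfm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (length(starts) == 0) stop_bad_arg("no MOTIF blocks in %s", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > s][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4), USE.NAMES = FALSE))
    mm <- t(m)
    rownames(mm) <- DNA_BASES
    # renormalise against printed rounding
    mm <- sweep(mm, 2, colSums(mm), "/")
    out[[name]] <- pfm(mm)
  }
  out
}

#' @param motifs named list of [pfm()] objects (or a single `pfm`).
#' @param background named background frequencies recorded in the header.
#' @rdname read_meme
#' @export
write_meme <- function(motifs, path, background = uniform_background()) {
  if (inherits(motifs, "pfm")) motifs <- list(motif1 = motifs)
  bg <- check_background(background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (name in names(motifs)) {
    m <- unclass(motifs[[name]])
    writeLines(sprintf("MOTIF %s", name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)), con)
    writeLines(apply(m, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}
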