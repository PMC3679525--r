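# Internal validation and small shared helpers.

stop_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "bindwave_error")

# Intervals are 0-based half-open throughout, mirroring BED.
validate_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop_bad_arg("%s must have columns %s (missing: %s)", what,
                 paste(need, collapse = ", "), paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(as.character(x$chrom)))) {
    stop_bad_arg("%s: chrom must be nonempty", what)
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop_bad_arg("%s: malformed interval at row %d (need 0 <= start < end, got [%s, %s))",
                 what, bad[1], x$start[bad[1]], x$end[bad[1]])
  }
  invisible(x)
}

# tibble of half-open intervals -> GRanges (1-based closed) and back
intervals_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges   = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand   = strand
  )
}

granges_to_intervals <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  tibble(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = BiocGenerics::start(gr) - 1L,
    end    = BiocGenerics::end(gr),
    strand = strand
  )
}

region_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper used for k-mer bookkeeping.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse-complement-collapsed canonical form of a k-mer
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

DNA_BASES <- c("A", "C", "G", "T")

# sequences -> integer code matrix (rows = sequences, all same length), codes 1..4
encode_dna <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop_bad_arg("encode_dna expects equal-length sequences")
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop_bad_arg("sequences contain letters outside A/C/G/T")
  m
}
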