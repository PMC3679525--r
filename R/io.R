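# Readers and writers for the plain-text interchange formats. Genomic
# formats go through rtracklayer/Biostrings; flat tables through readr.
# All tibble coordinates are 0-based half-open (BED convention).

#' Read and write BED6 peak files
#'
#' @param path BED file path.
#' @param caller,replicate,timepoint metadata attached to every record on
#'   read (the simulator encodes them in file names, real pipelines know
#'   them from their sample sheet).
#' @return `read_peaks_bed`: tibble (chrom, start, end, strand, caller,
#'   replicate, timepoint, score).
#' @export
read_peaks_bed <- function(path, caller = NA_character_, replicate = NA_integer_,
                           timepoint = NA_real_) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  out$score <- if (!is.null(gr$score)) gr$score else NA_real_
  out %>% mutate(caller = caller, replicate = replicate, timepoint = timepoint) %>%
    select("chrom", "start", "end", "strand", "caller", "replicate",
           "timepoint", "score")
}

#' @param peaks tibble with chrom, start, end and optionally score.
#' @rdname read_peaks_bed
#' @export
write_peaks_bed <- function(peaks, path) {
  validate_intervals(peaks, "peaks")
  gr <- intervals_to_granges(peaks)
  gr$name <- if ("caller" %in% names(peaks)) {
    sprintf("%s_%d", peaks$caller, seq_len(nrow(peaks)))
  } else sprintf("peak_%d", seq_len(nrow(peaks)))
  gr$score <- if ("score" %in% names(peaks)) round(peaks$score, 3) else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write the gene annotation as GFF3
#'
#' Genes are written as single `gene` features carrying their ID; on read
#' the TSS is recomputed from the strand (body start on +, body end on -).
#'
#' @param annotation tibble as returned by [simulate_genome()].
#' @param path GFF3 file path.
#' @param chrom_sizes optional named vector recorded as sequence regions.
#' @export
write_annotation_gff3 <- function(annotation, path, chrom_sizes = NULL) {
  gr <- intervals_to_granges(annotation)
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  gr$source <- "bindwave"
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @return `read_annotation_gff3`: tibble (gene_id, chrom, strand, start,
#'   end, tss).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  out <- granges_to_intervals(gr)
  out$gene_id <- gr$ID
  out %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end)) %>%
    select("gene_id", "chrom", "strand", "start", "end", "tss") %>%
    as_tibble()
}

#' Read the flat TSV tables of the pipeline
#'
#' Column-typed wrappers around [readr::read_tsv()] for the expression
#' table (gene_id, timepoint, replicate, rpkm), the binding count table
#' (region_id, timepoint, replicate, count, library_size) and probe
#' tables (probe_id, sequence, intensity).
#'
#' @param path TSV file path.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", timepoint = "d", replicate = "i", rpkm = "d"))
}

#' @rdname read_tables
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    region_id = "c", timepoint = "d", replicate = "i",
    count = "d", library_size = "d"))
}

#' @rdname read_tables
#' @param design design label attached to every probe on read.
#' @export
read_probes_tsv <- function(path, design = NA_character_) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = "c", sequence = "c", intensity = "d")) %>%
    mutate(design = design)
}

#' Read and write promoter sequences as FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path FASTA file path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
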