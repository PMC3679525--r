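HORMONE_LABELS <- c("ABA", "BR", "CK", "ETH", "GA", "IAA", "MJ", "SA")

#' Assemble the hormone co-regulation network
#'
#' Merges protein-protein (PPI, undirected) and protein-DNA (PDI,
#' directed TF -> gene) edge lists into one deduplicated network; an edge
#' seen in several sources keeps one record listing all sources. Node
#' attributes carry hormone labels and target status. A PDI self-loop is
#' kept with a warning.
#'
#' @param ppi tibble (a, b) of undirected protein interactions, optional
#'   `source` column.
#' @param pdi tibble (a, b) of TF -> gene interactions, optional `source`
#'   column; several PDI sources may be concatenated beforehand.
#' @param annotations optional tibble (gene_id, hormone) with labels from
#'   the eight-hormone vocabulary.
#' @param targets optional character vector of TF candidate target ids.
#' @return a `coreg_network` with tibbles `nodes` (id, hormones
#'   (list-col), n_hormones, is_target) and `edges` (a, b, kind, source).
#' @export
assemble_network <- function(ppi, pdi, annotations = NULL, targets = character()) {
  norm <- function(x, kind) {
    if (is.null(x) || nrow(x) == 0) {
      return(tibble(a = character(), b = character(), kind = character(),
                    source = character()))
    }
    if (!all(c("a", "b") %in% names(x))) stop_bad_arg("%s edges need columns a, b", kind)
    if (any(!nzchar(x$a) | !nzchar(x$b) | is.na(x$a) | is.na(x$b))) {
      stop_bad_arg("%s edges contain malformed ids", kind)
    }
    x <- mutate(x, kind = kind,
                source = if ("source" %in% names(x)) .data$source else kind)
    if (kind == "PPI") {
      # undirected: canonical endpoint order
      x <- mutate(x, a2 = pmin(.data$a, .data$b), b2 = pmax(.data$a, .data$b),
                  a = .data$a2, b = .data$b2) %>% select(-"a2", -"b2")
    }
    x %>%
      group_by(.data$a, .data$b, .data$kind) %>%
      summarise(source = paste(sort(unique(.data$source)), collapse = ";"),
                .groups = "drop")
  }
  edges <- bind_rows(norm(ppi, "PPI"), norm(pdi, "PDI")) %>%
    arrange(.data$kind, .data$a, .data$b)
  loops <- edges$kind == "PDI" & edges$a == edges$b
  if (any(loops)) {
    warn(sprintf("%d PDI self-loop(s) retained (autoregulation)", sum(loops)))
  }

  ids <- sort(unique(c(edges$a, edges$b)))
  hormones <- rep(list(character()), length(ids))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    bad <- setdiff(unique(annotations$hormone), HORMONE_LABELS)
    if (length(bad) > 0) {
      stop_bad_arg("unknown hormone label(s): %s", paste(bad, collapse = ", "))
    }
    sets <- annotations %>%
      group_by(.data$gene_id) %>%
      summarise(h = list(sort(unique(.data$hormone))), .groups = "drop")
    m <- match(ids, sets$gene_id)
    hormones[!is.na(m)] <- sets$h[m[!is.na(m)]]
  }
  nodes <- tibble(id = ids, hormones = hormones,
                  n_hormones = lengths(hormones),
                  is_target = ids %in% targets)
  structure(list(nodes = nodes, edges = edges), class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat("<coreg_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$kind == "PPI"), "PPI /", sum(x$edges$kind == "PDI"),
      "PDI ),", sum(x$nodes$is_target), "targets\n")
  invisible(x)
}

#' Hormone-annotation fraction and enrichment of a gene set
#'
#' Percentage of a gene set carrying at least one hormone label, the
#' corresponding genome-wide percentage, and the exact hypergeometric
#' upper-tail probability of the overlap against the genome universe.
#' Genome totals are supplied as inputs (they depend on the annotation
#' release), e.g. 5729 hormone genes of 27416.
#'
#' @param gene_set character vector of gene ids (nonempty, at most
#'   `genome_size` genes).
#' @param annotation tibble (gene_id, hormone) or a character vector of
#'   hormone-annotated gene ids.
#' @param genome_size total genes in the genome universe.
#' @param genome_hormone_count hormone-annotated genes in the genome.
#' @return tibble (n_set, k_set, fraction_set, fraction_genome, p) with
#'   fractions as percentages.
#' @export
hormone_fraction <- function(gene_set, annotation, genome_size,
                             genome_hormone_count) {
  if (length(gene_set) == 0) stop_bad_arg("empty gene set")
  if (length(gene_set) > genome_size) {
    stop_bad_arg("gene set (%d) larger than the genome (%d)",
                 length(gene_set), genome_size)
  }
  if (genome_hormone_count > genome_size) {
    stop_bad_arg("genome hormone count exceeds genome size")
  }
  hormone_ids <- if (is.data.frame(annotation)) unique(annotation$gene_id)
                 else unique(annotation)
  k <- sum(unique(gene_set) %in% hormone_ids)
  n <- length(unique(gene_set))
  tibble(n_set = n, k_set = k,
         fraction_set = 100 * k / n,
         fraction_genome = 100 * genome_hormone_count / genome_size,
         p = hypergeom_enrichment(k, n, genome_hormone_count, genome_size))
}

#' Neighborhood of the target genes in the network
#'
#' Induced subnetwork on the targets plus every node within `radius`
#' undirected steps of a target; node attributes are preserved.
#'
#' @param network a [assemble_network()] result.
#' @param targets character vector of target ids (default: the network's
#'   `is_target` nodes).
#' @param radius neighborhood radius in edges (>= 0, default 1).
#' @return a `coreg_network` restricted to the neighborhood.
#' @export
target_neighborhood <- function(network, targets = NULL, radius = 1) {
  if (radius < 0) stop_bad_arg("radius must be >= 0")
  if (is.null(targets)) targets <- network$nodes$id[network$nodes$is_target]
  targets <- intersect(targets, network$nodes$id)
  g <- igraph::graph_from_data_frame(
    network$edges[c("a", "b")], directed = FALSE,
    vertices = network$nodes$id)
  keep <- if (length(targets) == 0) character() else
    unique(names(unlist(igraph::ego(g, order = radius, nodes = targets))))
  nodes <- filter(network$nodes, .data$id %in% keep)
  edges <- filter(network$edges, .data$a %in% keep & .data$b %in% keep)
  structure(list(nodes = nodes, edges = edges), class = "coreg_network")
}

#' Export a network in SIF plus node-attribute form
#'
#' Writes `<a> <kind> <b>` lines (Cytoscape simple-interaction format)
#' and a companion node-attribute TSV with hormone labels (multi-hormone
#' nodes additionally carry the derived ">1" label) and target status.
#'
#' @param network a [assemble_network()] result.
#' @param path SIF file path; attributes go to `<path>.nodes.tsv`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  writeLines(sprintf("%s\t%s\t%s", network$edges$a, network$edges$kind,
                     network$edges$b), path)
  attrs <- network$nodes %>%
    mutate(hormone = map_chr(.data$hormones, function(h) {
      lab <- if (length(h) > 1) c(h, ">1") else h
      paste(lab, collapse = ",")
    })) %>%
    select("id", "hormone", "is_target")
  readr::write_tsv(attrs, paste0(path, ".nodes.tsv"))
  invisible(path)
}
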