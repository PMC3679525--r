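#' Keep genes changing at least twofold
#'
#' Retains genes whose log2 trajectory reaches an absolute value of at
#' least `min_abs_log2` (1 = twofold, up or down) at some timepoint.
#'
#' @param trajectories long tibble (gene_id, timepoint, log2fc), log2
#'   ratios versus 0 hr.
#' @param min_abs_log2 threshold on max |log2fc| (default 1).
#' @return the trajectories of the retained genes.
#' @export
filter_twofold <- function(trajectories, min_abs_log2 = 1) {
  keep <- trajectories %>%
    group_by(.data$gene_id) %>%
    summarise(mx = max(abs(.data$log2fc)), .groups = "drop") %>%
    filter(.data$mx >= min_abs_log2) %>%
    pull("gene_id")
  filter(trajectories, .data$gene_id %in% keep)
}

#' Fit a Gaussian split tree to timecourse trajectories
#'
#' A transparent model of bifurcating expression programs: genes start in
#' one root state at the first timepoint; at every subsequent timepoint
#' each current group of genes is tested for divergence by fitting 1- to
#' `max_children`-component univariate Gaussian mixtures to the group's
#' values at that timepoint and accepting the BIC-best model; genes are
#' hard-assigned to components by maximum posterior. Each root-to-leaf
#' path is a candidate transcriptional wave. Groups smaller than
#' `3 * max_children` genes never split. The fit depends only on the
#' multiset of values (input order does not matter).
#'
#' @param trajectories long tibble (gene_id, timepoint, log2fc); if a
#'   `replicate` column is present, replicates are averaged first.
#' @param max_children maximum components per split (default 3).
#' @param seed integer seed (the mixture fits are deterministic; the seed
#'   guards any RNG a mixture backend might use).
#' @return a `split_tree` with tibbles `nodes` (node_id, timepoint,
#'   parent_id, mean, sd, n_genes), `edges`, `assignments` (gene_id,
#'   timepoint, node_id), `paths` (gene_id, path_id) and the wide
#'   trajectory matrix used.
#' @export
fit_split_tree <- function(trajectories, max_children = 3, seed = 1L) {
  if ("replicate" %in% names(trajectories)) {
    trajectories <- trajectories %>%
      group_by(.data$gene_id, .data$timepoint) %>%
      summarise(log2fc = mean(.data$log2fc), .groups = "drop")
  }
  wide <- trajectories %>%
    pivot_wider(names_from = "timepoint", values_from = "log2fc") %>%
    arrange(.data$gene_id)
  tps <- sort(as.numeric(setdiff(names(wide), "gene_id")))
  if (length(tps) < 2) stop_bad_arg("need >= 2 timepoints")
  if (nrow(wide) < 10) stop_bad_arg("need >= 10 genes, got %d", nrow(wide))
  x <- as.matrix(wide[as.character(tps)])
  rownames(x) <- wide$gene_id
  if (anyNA(x)) stop_bad_arg("trajectories contain missing values")
  set.seed(seed)
  min_node <- 3 * max_children

  nodes <- list()
  assignments <- list()
  new_node <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      sprintf("n%03d", counter)
    }
  })
  # members: named list node_id -> gene ids at the current timepoint
  root <- new_node()
  members <- setNames(list(rownames(x)), root)
  nodes[[root]] <- tibble(node_id = root, timepoint = tps[1],
                          parent_id = NA_character_,
                          mean = mean(x[, 1]), sd = sd_or0(x[, 1]),
                          n_genes = nrow(x))
  assignments[[1]] <- tibble(gene_id = rownames(x), timepoint = tps[1],
                             node_id = root)

  for (ti in seq_along(tps)[-1]) {
    nxt <- list()
    for (parent in names(members)) {
      genes <- members[[parent]]
      vals <- x[genes, ti]
      classes <- split_node_values(vals, max_children, min_node)
      for (cl in sort(unique(classes))) {
        child <- new_node()
        sub <- genes[classes == cl]
        nodes[[child]] <- tibble(node_id = child, timepoint = tps[ti],
                                 parent_id = parent,
                                 mean = mean(x[sub, ti]),
                                 sd = sd_or0(x[sub, ti]),
                                 n_genes = length(sub))
        nxt[[child]] <- sub
      }
    }
    members <- nxt
    assignments[[ti]] <- list_rbind(imap(members, function(g, id) {
      tibble(gene_id = g, timepoint = tps[ti], node_id = id)
    }))
  }

  nodes <- list_rbind(nodes)
  paths <- list_rbind(imap(members, function(g, id) {
    tibble(gene_id = g, path_id = id)
  })) %>% arrange(.data$gene_id)
  structure(list(
    nodes = nodes,
    edges = nodes %>% filter(!is.na(.data$parent_id)) %>%
      select(parent_id = "parent_id", child_id = "node_id"),
    assignments = list_rbind(assignments),
    paths = paths,
    timepoints = tps,
    trajectories = wide
  ), class = "split_tree")
}

sd_or0 <- function(v) if (length(v) < 2) 0 else sd(v)

# BIC-selected 1..G component assignment of one node's values. EM
# (unequal-variance univariate Gaussians) is started from kmeans and
# equal-count initial partitions of the sorted values, keeping the best
# log-likelihood per G; the sort makes the fit depend only on the value
# multiset. Solutions with a component smaller than `min_component`
# genes are treated as degenerate and skipped in BIC order.
split_node_values <- function(vals, max_children, min_node,
                              min_component = 5L) {
  n <- length(vals)
  if (n < min_node || sd_or0(vals) < 1e-8) return(rep(1L, n))
  ord <- order(vals)
  sv <- vals[ord]

  cands <- list()
  for (G in seq_len(max_children)) {
    best <- NULL
    if (G == 1) {
      s2 <- var(sv) * (n - 1) / n
      best <- list(loglik = sum(stats::dnorm(sv, mean(sv), sqrt(s2),
                                             log = TRUE)),
                   cls = rep(1L, n))
    } else {
      inits <- list(cut(seq_len(n), breaks = G, labels = FALSE))
      km <- tryCatch(stats::kmeans(sv, centers = G, nstart = 10),
                     error = function(e) NULL)
      if (!is.null(km)) inits$km <- km$cluster
      for (init in inits) {
        z <- matrix(1e-8, n, G)
        z[cbind(seq_len(n), init)] <- 1
        z <- z / rowSums(z)
        fit <- tryCatch(
          suppressWarnings(me(data = sv, modelName = "V", z = z)),
          error = function(e) NULL)
        if (is.null(fit) || is.na(fit$loglik)) next
        if (is.null(best) || fit$loglik > best$loglik) {
          best <- list(loglik = fit$loglik, cls = max.col(fit$z))
        }
      }
    }
    if (is.null(best)) next
    best$G <- G
    best$bic <- 2 * best$loglik - (3 * G - 1) * log(n)
    cands[[length(cands) + 1]] <- best
  }

  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "bic"))]
  for (cand in cands) {
    if (cand$G == 1) return(rep(1L, n))
    sizes <- table(cand$cls)
    if (length(sizes) < cand$G || any(sizes < min_component)) next
    mu <- vapply(split(sv, cand$cls), mean, numeric(1))
    if (anyDuplicated(round(mu, 8))) next
    # relabel children in increasing order of component mean
    rank_map <- setNames(rank(mu), names(mu))
    cls <- integer(n)
    cls[ord] <- as.integer(rank_map[as.character(cand$cls)])
    return(cls)
  }
  rep(1L, n)
}

#' @export
print.split_tree <- function(x, ...) {
  cat("<split_tree>", nrow(x$trajectories), "genes,",
      length(x$timepoints), "timepoints,",
      n_distinct(x$paths$path_id), "paths\n")
  invisible(x)
}

#' @param x,object a `split_tree`.
#' @param ... unused.
#' @describeIn fit_split_tree node table as a tibble.
#' @export
tidy.split_tree <- function(x, ...) x$nodes

#' @describeIn fit_split_tree one-row fit summary.
#' @export
glance.split_tree <- function(x, ...) {
  tibble(n_genes = nrow(x$trajectories),
         n_timepoints = length(x$timepoints),
         n_nodes = nrow(x$nodes),
         n_paths = n_distinct(x$paths$path_id),
         n_splits = sum(table(x$edges$parent_id) > 1))
}

#' Genes on each root-to-leaf path
#'
#' @param tree a `split_tree`.
#' @return named list path_id -> character vector of gene ids.
#' @export
path_members <- function(tree) {
  split(tree$paths$gene_id, tree$paths$path_id)
}

# timepoint at which each path last diverged from a sibling; root-only
# paths report the first timepoint
path_split_timepoints <- function(tree) {
  kids <- table(tree$edges$parent_id)
  split_parents <- names(kids)[kids > 1]
  node_tp <- setNames(tree$nodes$timepoint, tree$nodes$node_id)
  node_parent <- setNames(tree$nodes$parent_id, tree$nodes$node_id)
  vapply(unique(tree$paths$path_id), function(leaf) {
    cur <- leaf
    while (!is.na(node_parent[[cur]])) {
      if (node_parent[[cur]] %in% split_parents) return(node_tp[[cur]])
      cur <- node_parent[[cur]]
    }
    tree$timepoints[1]
  }, numeric(1))
}

#' Timepoint-resolved TF target sets from binding signal
#'
#' A region is bound at a timepoint when its (replicate-averaged) RPKM
#' strictly exceeds the region's cutoff, the mean of its two input
#' control RPKM values (0 and 4 hr); a gene is bound at a timepoint when
#' any region assigned to it is bound.
#'
#' @param rpkm long tibble (region_id, timepoint, replicate, rpkm).
#' @param input_control tibble (region_id, input_0h, input_4h); every
#'   region must appear.
#' @param assignments tibble (region_id, gene_id) from
#'   [assign_targets()] (unassigned regions are dropped).
#' @return tibble (timepoint, gene_id) of bound genes, one row per bound
#'   gene-timepoint.
#' @export
temporal_target_set <- function(rpkm, input_control, assignments) {
  missing <- setdiff(unique(rpkm$region_id), input_control$region_id)
  if (length(missing) > 0) {
    stop_bad_arg("missing input control for region(s), e.g. %s", missing[1])
  }
  assignments <- assignments %>% filter(!is.na(.data$gene_id))
  rpkm %>%
    group_by(.data$region_id, .data$timepoint) %>%
    summarise(rpkm = mean(.data$rpkm), .groups = "drop") %>%
    left_join(input_control, by = "region_id") %>%
    mutate(bound = .data$rpkm > (.data$input_0h + .data$input_4h) / 2) %>%
    filter(.data$bound) %>%
    inner_join(assignments %>% select("region_id", "gene_id"),
               by = "region_id", relationship = "many-to-many") %>%
    distinct(.data$timepoint, .data$gene_id) %>%
    arrange(.data$timepoint, .data$gene_id)
}

#' Annotate split-tree paths with TF target enrichment
#'
#' For every root-to-leaf path, the upper-tail hypergeometric probability
#' of the observed overlap between the path's genes and the TF's target
#' set, drawn from the analyzed gene universe. With a temporal target set
#' (tibble timepoint x gene_id) the targets bound at the path's split
#' timepoint are used. A path is annotated (a TF-modulated wave) when
#' p < `p_threshold` and the target fraction of its genes exceeds
#' `min_fraction`.
#'
#' @param tree a [fit_split_tree()] result.
#' @param targets character vector of target gene ids, or a temporal set
#'   as returned by [temporal_target_set()].
#' @param universe gene universe (default: the genes in the tree). Path
#'   genes must be a subset.
#' @param tf_name label recorded in the output.
#' @param p_threshold significance threshold (default 1e-10, strict <).
#' @param min_fraction minimum target fraction of path genes (default
#'   0.15, strict >).
#' @return tibble (path_id, tf_name, split_timepoint, k, n, K, N, p,
#'   target_fraction, annotated).
#' @export
annotate_paths <- function(tree, targets, universe = NULL, tf_name = "TF",
                           p_threshold = 1e-10, min_fraction = 0.15) {
  if (is.null(universe)) universe <- tree$trajectories$gene_id
  if (length(universe) == 0) stop_bad_arg("empty gene universe")
  members <- path_members(tree)
  if (!all(unlist(members) %in% universe)) {
    stop_bad_arg("path genes must be a subset of the universe")
  }
  split_tp <- path_split_timepoints(tree)
  temporal <- is.data.frame(targets)
  N <- length(universe)
  list_rbind(imap(members, function(genes, pid) {
    tset <- if (temporal) {
      targets$gene_id[targets$timepoint == split_tp[[pid]]]
    } else targets
    tset <- intersect(tset, universe)
    k <- length(intersect(genes, tset))
    n <- length(genes)
    K <- length(tset)
    tibble(path_id = pid, tf_name = tf_name,
           split_timepoint = split_tp[[pid]],
           k = k, n = n, K = K, N = N,
           p = hypergeom_enrichment(k, n, K, N),
           target_fraction = k / n)
  })) %>%
    mutate(annotated = .data$p < p_threshold &
             .data$target_fraction > min_fraction) %>%
    arrange(.data$p)
}

#' Per-wave summary statistics
#'
#' For each annotated path: gene count, onset (first timepoint at which
#' the path's mean |log2fc| reaches 1, i.e. twofold), the mean trajectory,
#' the pooled within-wave sd of member trajectories around the wave mean,
#' and the target fraction.
#'
#' @param tree a [fit_split_tree()] result.
#' @param annotations output of [annotate_paths()]; only rows with
#'   `annotated` are summarised (all paths if none is annotated is an
#'   error).
#' @return tibble (path_id, n_genes, onset, sd, target_fraction) with a
#'   `mean_trajectory` list-column of (timepoint, mean) tibbles.
#' @export
wave_statistics <- function(tree, annotations) {
  ann <- filter(annotations, .data$annotated)
  if (nrow(ann) == 0) stop_bad_arg("no annotated path to summarise")
  members <- path_members(tree)
  x <- as.matrix(tree$trajectories[as.character(tree$timepoints)])
  rownames(x) <- tree$trajectories$gene_id
  list_rbind(map(ann$path_id, function(pid) {
    sub <- x[members[[pid]], , drop = FALSE]
    mu <- colMeans(sub)
    resid <- sweep(sub, 2, mu)
    onset_idx <- which(abs(mu) >= 1)
    tibble(path_id = pid, n_genes = nrow(sub),
           onset = if (length(onset_idx) == 0) NA_real_
                   else tree$timepoints[min(onset_idx)],
           sd = sqrt(mean(resid^2)),
           target_fraction = ann$target_fraction[ann$path_id == pid],
           mean_trajectory = list(tibble(timepoint = tree$timepoints,
                                         mean = unname(mu))))
  })) %>% arrange(.data$onset)
}

#' Pairwise temporal distinctness of waves
#'
#' Mann-Whitney comparison of the member genes' first
#' differential-expression timepoints between every pair of annotated
#' waves; waves are temporally distinct when every pairwise p-value falls
#' below `p_threshold`.
#'
#' @param tree a [fit_split_tree()] result.
#' @param annotations output of [annotate_paths()].
#' @param de_calls output of [call_de()] for the same genes.
#' @param p_threshold distinctness threshold (default 0.001).
#' @return tibble (path_a, path_b, p, distinct).
#' @export
wave_distinctness <- function(tree, annotations, de_calls,
                              p_threshold = 0.001) {
  ann <- filter(annotations, .data$annotated)
  if (nrow(ann) < 2) {
    return(tibble(path_a = character(), path_b = character(),
                  p = numeric(), distinct = logical()))
  }
  members <- path_members(tree)
  first_tp <- de_calls %>%
    group_by(.data$gene_id) %>%
    summarise(first_tp = min(.data$timepoint), .groups = "drop")
  onsets <- map(ann$path_id, function(pid) {
    first_tp$first_tp[first_tp$gene_id %in% members[[pid]]]
  })
  names(onsets) <- ann$path_id
  combos <- utils::combn(ann$path_id, 2)
  list_rbind(map(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    p <- suppressWarnings(
      wilcox.test(onsets[[a]], onsets[[b]], exact = FALSE)$p.value)
    if (is.na(p)) p <- 1  # no rank variation (fully tied onsets)
    tibble(path_a = a, path_b = b, p = p, distinct = p < p_threshold)
  }))
}
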