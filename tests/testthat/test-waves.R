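mk_traj <- function(mat, genes = sprintf("g%03d", seq_len(nrow(mat))),
                    tps = as.numeric(colnames(mat))) {
  tibble::tibble(gene_id = rep(genes, each = ncol(mat)),
                 timepoint = rep(tps, nrow(mat)),
                 log2fc = as.vector(t(mat)))
}

test_that("the twofold filter keeps only trajectories reaching |log2fc| 1", {
  m <- rbind(c(0, 0.4, 0.9), c(0, 1.1, 0.2), c(0, 0, 0))
  colnames(m) <- c(0, 1, 4)
  got <- filter_twofold(mk_traj(m))
  expect_identical(sort(unique(got$gene_id)), "g002")
})

test_that("a homogeneous cluster never splits", {
  set.seed(3)
  m <- cbind(0, matrix(rnorm(60 * 3, 1, 0.2), 60, 3))
  colnames(m) <- c(0, 1, 4, 24)
  tree <- fit_split_tree(mk_traj(m), seed = 1)
  expect_identical(glance(tree)$n_paths, 1L)
  expect_identical(glance(tree)$n_splits, 0L)
})

test_that("two groups diverging at one timepoint produce one accurate split", {
  set.seed(4)
  n <- 60
  up <- cbind(0, matrix(rnorm(n * 1, 0, 0.2), n, 1),
              matrix(rnorm(n * 2, 2, 0.2), n, 2))
  dn <- cbind(0, matrix(rnorm(n * 1, 0, 0.2), n, 1),
              matrix(rnorm(n * 2, -2, 0.2), n, 2))
  m <- rbind(up, dn)
  colnames(m) <- c(0, 1, 4, 24)
  tree <- fit_split_tree(mk_traj(m), seed = 1)
  expect_identical(glance(tree)$n_paths, 2L)
  # the split happens where the groups diverge
  split_nodes <- tree$nodes$timepoint[!is.na(tree$nodes$parent_id) &
                                        tree$nodes$node_id %in%
                                          tree$edges$child_id[duplicated(tree$edges$parent_id) |
                                                                duplicated(tree$edges$parent_id, fromLast = TRUE)]]
  expect_true(all(split_nodes == 4))
  truth <- rep(1:2, each = n)
  acc <- max(table(tree$paths$path_id[order(tree$paths$gene_id)],
                   truth[order(sprintf("g%03d", 1:(2 * n)))]))
  agree <- mclust::adjustedRandIndex(tree$paths$path_id,
                                     truth[match(tree$paths$gene_id,
                                                 sprintf("g%03d", 1:(2 * n)))])
  expect_gte(agree, 0.9)
})

test_that("three groups at one timepoint give a three-way split", {
  set.seed(5)
  n <- 40
  mid <- function(mu) cbind(0, matrix(rnorm(n * 2, mu, 0.2), n, 2))
  m <- rbind(mid(-2), mid(0), mid(2.5))
  colnames(m) <- c(0, 4, 24)
  tree <- fit_split_tree(mk_traj(m), seed = 1)
  expect_identical(glance(tree)$n_paths, 3L)
  kids <- table(tree$edges$parent_id)
  expect_identical(max(kids), 3L)
})

test_that("every timepoint slice of the tree conserves the gene count", {
  st <- default_study()
  traj <- filter_twofold(log2_profile(st$expression, id = "gene_id"))
  tree <- memo_fixture("tree", fit_split_tree(traj, seed = 11))
  per_tp <- tapply(tree$assignments$gene_id, tree$assignments$timepoint,
                   length)
  expect_true(all(per_tp == glance(tree)$n_genes))
  # nodes at one timepoint partition the genes
  expect_identical(sum(tree$nodes$n_genes[tree$nodes$timepoint == 4]),
                   glance(tree)$n_genes)
})

test_that("gene order does not change path memberships", {
  set.seed(6)
  n <- 30
  m <- rbind(cbind(0, matrix(rnorm(n, 2, 0.2), n, 1)),
             cbind(0, matrix(rnorm(n, -1, 0.2), n, 1)))
  colnames(m) <- c(0, 4)
  traj <- mk_traj(m)
  t1 <- fit_split_tree(traj, seed = 2)
  t2 <- fit_split_tree(traj[sample(nrow(traj)), ], seed = 2)
  expect_equal(t1$paths, t2$paths)
})

test_that("temporal target sets apply the strict input-control cutoff", {
  rpkm <- tibble::tibble(region_id = c("r1", "r1", "r2", "r2"),
                         timepoint = c(0, 4, 0, 4),
                         replicate = 1L,
                         rpkm = c(12, 5, 1, 2))
  ctrl <- tibble::tibble(region_id = c("r1", "r2"),
                         input_0h = c(4, 0), input_4h = c(6, 0))
  asg <- tibble::tibble(region_id = c("r1", "r2"),
                        gene_id = c("gA", "gB"))
  got <- temporal_target_set(rpkm, ctrl, asg)
  # r1 cutoff 5: bound at 0 hr (12 > 5), unbound at 4 hr (5 == 5, strict)
  expect_true(any(got$gene_id == "gA" & got$timepoint == 0))
  expect_false(any(got$gene_id == "gA" & got$timepoint == 4))
  # zero controls: any positive RPKM is bound
  expect_identical(sum(got$gene_id == "gB"), 2L)
  expect_error(temporal_target_set(rpkm, ctrl[1, ], asg), "missing input")
})

test_that("path enrichment matches the exact enumeration oracle", {
  set.seed(9)
  n <- 12
  m <- rbind(cbind(0, matrix(rnorm(n, 2, 0.15), n, 1)),
             cbind(0, matrix(rnorm(n, -2, 0.15), n, 1)))
  colnames(m) <- c(0, 4)
  genes <- sprintf("g%03d", 1:(2 * n))
  tree <- fit_split_tree(mk_traj(m, genes = genes), seed = 3)
  targets <- genes[c(1:9, 13)]           # 9 in the up group, 1 down
  ann <- annotate_paths(tree, targets, p_threshold = 0.01,
                        min_fraction = 0.15)
  for (i in seq_len(nrow(ann))) {
    expect_equal(ann$p[i],
                 oracle_hyper(ann$k[i], ann$n[i], ann$K[i], ann$N[i]))
  }
  # zero overlap gives p = 1 and no annotation
  none <- annotate_paths(tree, "not_a_gene_in_tree")
  expect_true(all(none$p == 1))
  expect_false(any(none$annotated))
})

test_that("temporal target sets annotate paths with time-matched targets", {
  st <- default_study()
  traj <- filter_twofold(log2_profile(st$expression, id = "gene_id"))
  tree <- memo_fixture("tree", fit_split_tree(traj, seed = 11))
  # quantify the regions that carry input controls, assign them to genes
  rpkm <- quantify_regions(st$truth$regions, st$counts)
  asg <- assign_targets(st$truth$regions, st$annotation,
                        call_expressed(st$expression))
  tts <- temporal_target_set(rpkm, st$input_control, asg)
  ann <- annotate_paths(tree, tts)
  expect_true(all(ann$K[ann$split_timepoint == 0] <=
                    ann$K[ann$split_timepoint == 4]))
  expect_gte(sum(ann$annotated), 3)
})

test_that("wave statistics report planted noise ordering and onsets", {
  st <- default_study()
  traj <- filter_twofold(log2_profile(st$expression, id = "gene_id"))
  tree <- memo_fixture("tree", fit_split_tree(traj, seed = 11))
  targets <- st$truth$genes$gene_id[st$truth$genes$is_target]
  ann <- annotate_paths(tree, targets)
  ws <- wave_statistics(tree, ann)
  expect_identical(nrow(ws), 4L)
  expect_equal(ws$onset, c(0.25, 1, 4, 12))
  expect_true(all(diff(ws$sd) < 0))
  expect_true(all(ws$target_fraction > 0.15))

  dist <- wave_distinctness(tree, ann, default_de())
  expect_true(all(dist$distinct))
})

test_that("indistinguishable waves fail the distinctness test", {
  set.seed(10)
  n <- 40
  up <- function() cbind(0, matrix(rnorm(n, 2.5, 0.2), n, 1),
                         matrix(rnorm(n, 2.5, 0.2), n, 1))
  dn <- cbind(0, matrix(rnorm(n, -2, 0.2), n, 1),
              matrix(rnorm(n, -2, 0.2), n, 1))
  m <- rbind(up(), dn)
  colnames(m) <- c(0, 4, 24)
  genes <- sprintf("g%03d", seq_len(nrow(m)))
  tree <- fit_split_tree(mk_traj(m, genes = genes), seed = 4)
  targets <- genes
  ann <- annotate_paths(tree, targets, p_threshold = 2, min_fraction = 0)
  ann$annotated <- TRUE
  # both groups first change at the same timepoint
  de <- tibble::tibble(gene_id = genes, timepoint = 4, direction = "up")
  dist <- wave_distinctness(tree, ann, de)
  expect_true(all(!dist$distinct))
})
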