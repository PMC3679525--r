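test_that("gap merging follows the strict less-than rule", {
  iv <- tibble::tibble(chrom = "c1", start = c(100, 450), end = c(300, 600))
  expect_equal(merge_intervals(iv, max_gap = 200),
               tibble::tibble(chrom = "c1", start = 100L, end = 600L))
  one <- tibble::tibble(chrom = "c1", start = 0, end = 100)
  expect_equal(merge_intervals(one), tibble::tibble(chrom = "c1", start = 0L,
                                                    end = 100L))
  # gap of exactly max_gap stays unmerged
  exact <- tibble::tibble(chrom = "c1", start = c(100, 500), end = c(300, 600))
  expect_identical(nrow(merge_intervals(exact, max_gap = 200)), 2L)
  expect_error(merge_intervals(tibble::tibble(chrom = "c1", start = 10, end = 5)),
               "malformed")
})

test_that("gap merging matches the brute-force closure oracle", {
  set.seed(41)
  for (i in 1:200) {
    iv <- random_intervals(sample(1:8, 1))
    gap <- sample(c(0, 1, 50, 200), 1)
    got <- as.data.frame(merge_intervals(iv, max_gap = gap))
    want <- oracle_merge(iv, gap)
    got$start <- as.integer(got$start); got$end <- as.integer(got$end)
    want$start <- as.integer(want$start); want$end <- as.integer(want$end)
    expect_identical(got, want[names(got)])
  }
})

test_that("majority vote retains regions called by more than one caller", {
  base <- tibble::tibble(chrom = "c1", start = 100, end = 300,
                         replicate = 1L, timepoint = 1)
  two <- dplyr::bind_rows(dplyr::mutate(base, caller = "a"),
                          dplyr::mutate(base, caller = "b"))
  got <- majority_vote(two, callers = c("a", "b"))
  expect_identical(nrow(got), 1L)
  expect_equal(got$start, 100L)
  expect_equal(got$end, 300L)

  one <- dplyr::mutate(base, caller = "a")
  expect_identical(nrow(majority_vote(one, callers = c("a", "b"))), 0L)

  three <- dplyr::bind_rows(dplyr::mutate(base, caller = "a"),
                            dplyr::mutate(base, caller = "b"))
  got3 <- majority_vote(three, callers = c("a", "b", "c"))
  expect_identical(nrow(got3), 1L)

  expect_error(majority_vote(dplyr::mutate(base, caller = "zzz"),
                             callers = c("a", "b")), "unknown caller")
})

test_that("adding a caller's calls never removes a retained region", {
  set.seed(17)
  for (i in 1:20) {
    mk <- function(caller) {
      iv <- random_intervals(6, chroms = "c1")
      dplyr::mutate(iv, caller = caller, replicate = 1L, timepoint = 1)
    }
    calls2 <- dplyr::bind_rows(mk("a"), mk("b"))
    calls3 <- dplyr::bind_rows(calls2, mk("c"))
    r2 <- majority_vote(calls2, callers = c("a", "b", "c"))
    r3 <- majority_vote(calls3, callers = c("a", "b", "c"))
    if (nrow(r2) == 0) next
    ov <- GenomicRanges::findOverlaps(
      bindwave:::intervals_to_granges(r2),
      bindwave:::intervals_to_granges(r3))
    expect_identical(length(unique(S4Vectors::queryHits(ov))), nrow(r2))
  }
})

test_that("unification is idempotent, unions disjoint sets and bridges gaps", {
  cons <- tibble::tibble(replicate = 1L, timepoint = c(0, 4),
                         chrom = "c1", start = c(100, 100), end = c(400, 400))
  got <- unify_regions(cons)
  expect_identical(nrow(got), 1L)
  expect_identical(got$n_conditions, 2L)

  disjoint <- tibble::tibble(replicate = 1L, timepoint = c(0, 4),
                             chrom = "c1", start = c(100, 5000),
                             end = c(400, 5400))
  expect_equal(unify_regions(disjoint)$start, c(100L, 5000L))

  near <- tibble::tibble(replicate = 1L, timepoint = c(0, 4), chrom = "c1",
                         start = c(100, 599), end = c(400, 900))
  got_near <- unify_regions(near)  # gap 199 < 200
  expect_identical(nrow(got_near), 1L)
  expect_equal(got_near$end, 900L)
})

test_that("rpkm follows its closed form and rejects degenerate input", {
  expect_equal(compute_rpkm(10, 500, 1e6), 20)
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  expect_equal(compute_rpkm(1000, 1000, 1e7), 100)
  expect_error(compute_rpkm(1, 0, 1e6), "region_length")
  expect_error(compute_rpkm(1, 100, 0), "library_size")
})

test_that("median normalization equalises replicate medians and keeps order", {
  x <- tibble::tibble(replicate = rep(1:2, each = 3),
                      rpkm = c(5, 10, 20, 10, 20, 40))
  got <- median_normalize(x)
  meds <- tapply(got$rpkm, got$replicate, median)
  expect_equal(as.vector(meds), c(15, 15))
  expect_equal(order(got$rpkm[got$replicate == 2]), order(c(10, 20, 40)))

  single <- tibble::tibble(replicate = 1L, rpkm = c(1, 5, 9))
  expect_equal(median_normalize(single)$rpkm, single$rpkm)

  zero <- tibble::tibble(replicate = rep(1:2, each = 3),
                         rpkm = c(1, 2, 3, 0, 0, 0))
  expect_error(median_normalize(zero), "median")
})

test_that("log2 ratios are exact and antisymmetric", {
  expect_equal(log2_vs_control(8, 2, 1e-9), 2, tolerance = 1e-6)
  expect_equal(log2_vs_control(5, 5, 0.5), 0)
  a <- 7.3; b <- 2.1
  expect_equal(log2_vs_control(a, b, 0.5), -log2_vs_control(b, a, 0.5))
  expect_error(log2_vs_control(1, 1, 0), "pseudocount")
})

test_that("delta-delta-Ct fold changes match hand computation", {
  expect_equal(ddct_fold_change(10, 8, 14, 10), 4)   # ddCt = 2 - 4 = -2
  expect_equal(ddct_fold_change(10, 8, 12, 10), 1)
  expect_equal(ddct_fold_change(11, 8, 12, 10), 0.5) # ddCt = +1
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})

test_that("count transfer re-keys counts by genomic overlap", {
  regions <- tibble::tibble(region_id = "u1", chrom = "c1", start = 90,
                            end = 310)
  source_regions <- tibble::tibble(region_id = c("t1", "t2"), chrom = "c1",
                                   start = c(100, 5000), end = c(300, 5200))
  counts <- tidyr::expand_grid(region_id = c("t1", "t2"), timepoint = c(0, 4),
                               replicate = 1L) %>%
    dplyr::mutate(count = c(10, 20, 100, 200), library_size = 1e6)
  got <- transfer_counts(regions, source_regions, counts)
  expect_identical(nrow(got), 2L)           # u1 at both timepoints
  expect_equal(got$count, c(10, 20))        # only t1 overlaps
})

test_that("zero-noise consensus equals the planted region set exactly", {
  st <- noise_free_study()
  pipe <- consensus_pipeline(st)
  truth <- st$truth$regions[order(st$truth$regions$chrom,
                                  st$truth$regions$start), ]
  expect_equal(pipe$regions$start, truth$start)
  expect_equal(pipe$regions$end, truth$end)
  expect_equal(pipe$regions$chrom, truth$chrom)
})
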