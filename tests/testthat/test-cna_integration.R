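test_that("threshold caller uses strict inequalities at the cutoffs", {
  v <- matrix(c(0.0, 0.3, -0.2, 0.2, -0.21, NA), 2, 3)
  calls <- call_from_log_ratios(v, -0.2, 0.2)
  expect_equal(as.vector(calls), c(0, 1, 0, 0, -1, NA))
  expect_error(call_from_log_ratios(v, -Inf, 0.2), "finite")
  expect_error(call_from_log_ratios(v, 0.1, 0.2), "loss_cut < 0")
})

test_that("anchors are probe boundaries with half-open coverage", {
  ds <- make_pcd("chr1", 10, 20, matrix(c(1, 0), 1, 2))
  at <- build_anchor_table(list(ds))
  expect_equal(at$anchors$pos, c(10, 20))
  # start anchor covered, end anchor not (half-open), but kept (<=1 missing)
  expect_equal(at$anchors$n_informative, c(2L, 0L))
  expect_equal(at$anchors$gain_count, c(1L, 0L))
  expect_equal(at$anchors$gain_freq[1], 0.5)
})

test_that("anchors missing from more than one dataset are removed", {
  d1 <- make_pcd("chr1", 0, 100, matrix(1, 1, 1))
  d2 <- make_pcd("chr1", 0, 100, matrix(1, 1, 1))
  d3 <- make_pcd("chr1", 200, 300, matrix(1, 1, 1))
  at <- build_anchor_table(list(d1, d2, d3))
  # 0 is missing only in d3 (kept); 200 is covered only by d3 (dropped, two
  # datasets missing); 100 and 300 are probe ends covered nowhere (dropped)
  expect_equal(at$anchors$pos, 0)
  expect_equal(at$anchors$n_informative, 2L)
})

test_that("two overlapping probe grids pool their calls at shared anchors", {
  d1 <- make_pcd("chr1", 0, 10, matrix(1, 1, 1))
  d2 <- make_pcd("chr1", 5, 15, matrix(1, 1, 1))
  at <- build_anchor_table(list(d1, d2))
  # of the four boundary anchors {0,5,10,15}, 15 is missing in both
  expect_equal(at$anchors$pos, c(0, 5, 10))
  a5 <- at$anchors[at$anchors$pos == 5, ]
  expect_equal(a5$n_informative, 2L)
  expect_equal(a5$gain_freq, 1.0)
})

test_that("within a dataset the smaller probe wins a contested anchor", {
  # both probes cover position 0; the shorter [0,6) carries a loss
  ds <- probe_call_dataset(
    data.frame(chrom = "chr1", start = c(0, 0), end = c(10, 6)),
    matrix(c(1, -1), 2, 1, dimnames = list(NULL, "s1")))
  at <- build_anchor_table(list(ds))
  a0 <- at$anchors[at$anchors$pos == 0, ]
  expect_equal(a0$loss_count, 1L)
  expect_equal(a0$gain_count, 0L)
})

test_that("identical probe grids integrate like concatenated samples", {
  probes <- data.frame(chrom = "chr1", start = c(0, 50, 100),
                       end = c(50, 100, 150))
  withr::with_seed(5, {
    c1 <- matrix(sample(c(-1, 0, 1), 12, TRUE), 3,
                 dimnames = list(NULL, paste0("a", 1:4)))
    c2 <- matrix(sample(c(-1, 0, 1), 12, TRUE), 3,
                 dimnames = list(NULL, paste0("b", 1:4)))
  })
  at <- build_anchor_table(list(probe_call_dataset(probes, c1),
                                probe_call_dataset(probes, c2)))
  pooled <- cbind(c1, c2)
  covered <- at$anchors$n_informative > 0
  expect_equal(at$anchors$gain_count[covered],
               unname(rowSums(pooled == 1)))
  expect_equal(at$anchors$loss_count[covered],
               unname(rowSums(pooled == -1)))
})

test_that("datasets without a shared chromosome are rejected", {
  d1 <- make_pcd("chr1", 0, 10, matrix(0, 1, 1))
  d2 <- make_pcd("chr2", 0, 10, matrix(0, 1, 1))
  expect_error(build_anchor_table(list(d1, d2)), "share no chromosomes")
})

test_that("all-neutral data gives permutation p-values of exactly 1", {
  ds <- make_pcd("chr1", c(0, 10, 20), c(10, 20, 30), matrix(0, 3, 4))
  at <- anchor_frequency_test(build_anchor_table(list(ds)), n_perm = 99,
                              seed = 1)
  expect_true(all(at$anchors$p_gain == 1))
  expect_true(all(at$anchors$p_loss == 1))
  expect_error(anchor_frequency_test(build_anchor_table(list(ds)), n_perm = 0),
               "n_perm")
})

test_that("permutation p matches the exhaustive null on a small toy", {
  # 3 samples, 4 probes, each sample gains at exactly one probe (the first):
  # under per-sample shuffles each gain lands uniformly on one of 4 anchors,
  # so P(all three at anchor 1) = (1/4)^3 = 1/64 exactly.
  calls <- matrix(0, 4, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  calls[1, ] <- 1
  ds <- make_pcd("chr1", c(0, 10, 20, 30), c(10, 20, 30, 40), calls)
  n_perm <- 6000
  at <- anchor_frequency_test(build_anchor_table(list(ds)), n_perm = n_perm,
                              seed = 2)
  p <- at$anchors$p_gain[1]
  expected <- 1 / 64
  mc_sd <- sqrt(expected * (1 - expected) / n_perm)
  expect_lt(abs(p - expected), 3 * mc_sd + 2 / n_perm)
})

test_that("permutation p is stable when the permutation count doubles", {
  cohort <- simulate_cna_datasets(small_config(seed = 37))
  at <- build_anchor_table(cohort$datasets)
  a1 <- anchor_frequency_test(at, n_perm = 400, seed = 1)
  a2 <- anchor_frequency_test(at, n_perm = 800, seed = 1)
  p1 <- a1$anchors$p_gain
  p2 <- a2$anchors$p_gain
  mc <- sqrt(pmax(p1 * (1 - p1), 0.25 / 400) / 400)
  expect_true(all(abs(p1 - p2) <= 2 * mc + 3 / 400))
  # pooled-count invariant
  an <- a1$anchors
  expect_true(all(an$gain_count + an$loss_count <= an$n_informative))
})

test_that("significant anchors merge into direction-consistent regions", {
  mk <- function(pos, p_gain, p_loss, gf = 0.3, lf = 0.3) {
    at <- list(anchors = data.frame(
      chrom = "chr1", pos = pos,
      gain_count = 1L, loss_count = 1L, n_informative = 10L,
      gain_freq = gf, loss_freq = lf,
      p_gain = p_gain, p_loss = p_loss), alpha = 0.05)
    class(at) <- "anchor_table"
    at
  }
  # nothing significant -> empty
  expect_equal(nrow(merge_significant_anchors(mk(c(0, 10), 0.5, 0.5),
                                              max_gap = 100)), 0L)
  # two adjacent significant gains -> one region
  r <- merge_significant_anchors(mk(c(0, 10), c(0.01, 0.01), c(1, 1),
                                    gf = c(0.2, 0.4)),
                                 max_gap = 100)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 0); expect_equal(r$end, 11)
  expect_equal(r$direction, 1L)
  expect_equal(r$frequency, 0.4)  # peak anchor frequency
  # a significant loss anchor interrupts a gain run
  r2 <- merge_significant_anchors(
    mk(c(0, 10, 20), c(0.01, 0.9, 0.01), c(0.9, 0.01, 0.9)), max_gap = 100)
  expect_equal(r2$direction, c(1L, -1L, 1L))
  expect_equal(nrow(r2), 3L)
  # a gap larger than max_gap splits a run
  r3 <- merge_significant_anchors(mk(c(0, 500), c(0.01, 0.01), c(1, 1)),
                                  max_gap = 100)
  expect_equal(nrow(r3), 2L)
})
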