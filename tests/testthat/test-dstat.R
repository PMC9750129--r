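test_that("pattern counting follows the transversions-only rules", {
  # single informative site per call; outgroup defines the ancestral state
  abba <- count_patterns("A", "T", "T", "A", block_size = 10)
  expect_equal(abba$nABBA, 1)
  expect_equal(abba$nBABA, 0)

  baba <- count_patterns("A", "C", "A", "C", block_size = 10)
  expect_equal(baba$nBABA, 1)

  # transition pair is skipped entirely
  skipped <- count_patterns("C", "T", "T", "C", block_size = 10)
  expect_equal(nrow(skipped), 0)

  # N anywhere, three alleles, monomorphic: all skipped
  expect_equal(nrow(count_patterns("N", "T", "T", "A", block_size = 10)), 0)
  expect_equal(nrow(count_patterns("A", "T", "C", "A", block_size = 10)), 0)
  expect_equal(nrow(count_patterns("A", "A", "A", "A", block_size = 10)), 0)
  # derived singleton in P2 only: biallelic but neither ABBA nor BABA
  expect_equal(nrow(count_patterns("A", "T", "A", "A", block_size = 10)), 0)
  expect_error(count_patterns("AA", "A", "A", "A"), "equal length")
})

test_that("the D statistic is the normalized count difference", {
  expect_equal(d_statistic(30, 10), 0.5)
  expect_equal(d_statistic(7, 7), 0)
  expect_equal(d_statistic(7, 0), 1)
  expect_error(d_statistic(0, 0), "undefined")
})

test_that("equal-weight blocks reduce the weighted jackknife to delete-1", {
  set.seed(31)
  for (rep in 1:20) {
    g <- sample(5:15, 1)
    m <- sample(20:60, 1)               # equal informative sites per block
    nabba <- rbinom(g, m, 0.6)
    nbaba <- m - nabba
    blocks <- tibble::tibble(nABBA = nabba, nBABA = nbaba)
    jk <- weighted_block_jackknife(blocks)
    expect_equal(jk$SE, delete1_jackknife_se(nabba, nbaba),
                 tolerance = 1e-12)
  }
})

test_that("jackknife validates degenerate block structures", {
  expect_error(weighted_block_jackknife(tibble::tibble(nABBA = 3,
                                                       nBABA = 1)),
               "at least 2")
  expect_error(weighted_block_jackknife(
    tibble::tibble(nABBA = c(3, 0), nBABA = c(1, 0))), "at least 2")
})

test_that("Z has the sign of D and swapping P1/P2 negates D", {
  set.seed(32)
  p1 <- paste(sample(c("A", "T"), 4000, TRUE), collapse = "")
  p2 <- paste(sample(c("A", "T"), 4000, TRUE), collapse = "")
  p3 <- paste(sample(c("A", "T"), 4000, TRUE), collapse = "")
  og <- paste(sample(c("A", "T"), 4000, TRUE), collapse = "")
  r12 <- dstat(c(s = p1), c(s = p2), c(s = p3), c(s = og), block_size = 500)
  r21 <- dstat(c(s = p2), c(s = p1), c(s = p3), c(s = og), block_size = 500)
  expect_equal(r12$D, -r21$D)
  expect_equal(r12$nABBA, r21$nBABA)
  if (is.finite(r12$Z) && r12$SE > 0) {
    expect_equal(sign(r12$Z), sign(r12$D))
  }
})

test_that("D is invariant under base complementation", {
  set.seed(33)
  comp <- function(s) chartr("ACGT", "TGCA", s)
  p1 <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  p2 <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  p3 <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  og <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  r <- dstat(c(s = p1), c(s = p2), c(s = p3), c(s = og), block_size = 1000)
  rc <- dstat(c(s = comp(p1)), c(s = comp(p2)), c(s = comp(p3)),
              c(s = comp(og)), block_size = 1000)
  expect_equal(r$D, rc$D)
  expect_equal(r$n_used, rc$n_used)
})

test_that("a roan-to-blue pulse produces a positive D", {
  res <- dstat_study(f = 0.2, n_windows = 250, window_length = 5000,
                     block_size = 125000, rng_seed = 41)
  expect_gt(res$D, 0)
  expect_gt(res$Z, 2)
  expect_equal(sum(res$blocks$m), res$n_used)
})

test_that("tidy and glance expose the jackknife summary", {
  blocks <- tibble::tibble(nABBA = c(30, 25, 28), nBABA = c(10, 12, 9))
  jk <- weighted_block_jackknife(blocks)
  res <- structure(c(jk, list(nABBA = 83, nBABA = 31, significant = TRUE,
                              block_size = 1e6, z_threshold = 3)),
                   class = "dstat_result")
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_equal(td$D, jk$D)
  expect_s3_class(autoplot(res), "ggplot")
})
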