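test_that("path distance proportions are branch-length ratios", {
  tr <- ape::read.tree(
    text = "((roan:0.1,outgroup:0.1):0.1,(blue:0.1,sable:0.1):0);")
  # roan-sable path = 0.1 + 0.1 + 0 + 0.1 = 0.3; tree length 0.5
  expect_equal(path_distance_proportion(tr), 0.6)

  cherry <- ape::read.tree(
    text = "((roan:0.2,sable:0.3):0,(blue:0.1,outgroup:0.4):0);")
  expect_equal(path_distance_proportion(cherry), 0.5 / 1.0)

  zero <- ape::read.tree(text = "((roan:0,sable:0):0,(blue:0,outgroup:0):0);")
  expect_error(path_distance_proportion(zero), "zero")
  expect_error(path_distance_proportion(tr, taxonA = "eland"), "not in tree")
})

test_that("random trees give proportions in (0, 1]", {
  set.seed(61)
  for (i in 1:25) {
    tr <- ape::rtree(4, tip.label = c("roan", "sable", "blue", "outgroup"))
    p <- path_distance_proportion(tr)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("distance filtering keeps the inclusive boundaries", {
  expect_equal(filter_distances(c(0.0001, 0.5, 0.95)), 0.5)
  expect_equal(filter_distances(numeric(0)), numeric(0))
  expect_equal(filter_distances(c(0.0002, 0.9)), c(0.0002, 0.9))
  expect_equal(filter_distances(c(0.00019999, 0.90001)), numeric(0))
  cfg <- direction_config(lo = 0.1, hi = 0.2)
  expect_equal(filter_distances(c(0.05, 0.15, 0.25), cfg), 0.15)
  expect_error(direction_config(lo = 0.5, hi = 0.4), "lo < hi")
})

test_that("the dip statistic separates unimodal from bimodal samples", {
  # evenly spaced sample: minimal possible departure 1/(2n)
  n <- 50
  expect_equal(dip_statistic(seq_len(n) / n), 1 / (2 * n))
  # two well-separated equal atoms approach the theoretical 1/4
  atoms <- c(rep(0, 50), rep(1, 50))
  expect_equal(dip_statistic(atoms), 0.25)
  # unimodal bell vs strongly bimodal mixture
  set.seed(62)
  uni <- rnorm(150)
  bi <- c(rnorm(75, -4), rnorm(75, 4))
  expect_lt(dip_statistic(uni), dip_statistic(bi))
  t_uni <- dip_test(uni, n_mc = 200, rng_seed = 63)
  t_bi <- dip_test(bi, n_mc = 200, rng_seed = 63)
  expect_gt(t_uni$p.value, 0.05)
  expect_lt(t_bi$p.value, 0.01)
})

test_that("identical class samples force a roan_to_blue call", {
  x <- runif(80, 0.2, 0.6)
  res <- direction_test(x, x, rng_seed = 64)
  expect_equal(res$direction_call, "roan_to_blue")
  expect_gt(res$p_median, 0.5)
})

test_that("too few windows yield an indeterminate call", {
  res <- direction_test(runif(10), runif(100),
                        config = direction_config(min_windows = 30))
  expect_equal(res$direction_call, "indeterminate")
  expect_true(is.na(res$p_median))
})

test_that("a shifted-down discordant class flags blue_to_roan", {
  set.seed(65)
  bs <- rnorm(120, mean = 0.5, sd = 0.05)
  br <- c(rnorm(60, mean = 0.5, sd = 0.05), rnorm(60, mean = 0.25, sd = 0.04))
  res <- direction_test(bs, br, rng_seed = 66)
  expect_equal(res$direction_call, "blue_to_roan")
})

test_that("simulated pulses are recovered in both directions", {
  r2b <- direction_study(f = 0.2, direction = "roan_to_blue",
                         n_windows = 250, rng_seed = 67)
  expect_equal(r2b$direction_call, "roan_to_blue")
  b2r <- direction_study(f = 0.2, direction = "blue_to_roan",
                         n_windows = 250, rng_seed = 68)
  expect_equal(b2r$direction_call, "blue_to_roan")
})

test_that("timing classification separates attachment modes", {
  tc <- timing_classification(c("BR", "BR_nested", "BS"))
  expect_equal(tc$category[1], "blue_sister_to_roan_clade")
  expect_equal(tc$fraction, c(1 / 3, 1 / 3, 1 / 3))
  expect_error(timing_classification(character(0)), "no records")
})

test_that("a pulse younger than the roan radiation attaches blue outside", {
  # small roan Ne: the roan pair coalesces well before the 100k-generation
  # pulse, so introgressed blue lineages join the roan stem, not the pair
  ws <- window_study(f = 1, direction = "roan_to_blue", n_windows = 60,
                     window_length = 8000,
                     samples = c(blue = 1, sable = 1, roan = 2),
                     rng_seed = 69,
                     pop_size = c(blue = 30000, sable = 30000, roan = 15000,
                                  outgroup = 30000, bs = 30000, bsr = 30000,
                                  root = 30000))
  tc <- timing_classification(ws)
  sister <- tc$n[tc$category == "blue_sister_to_roan_clade"]
  nested <- tc$n[tc$category == "blue_nested_in_roan"]
  expect_gt(sister, 3 * max(nested, 1))
})

test_that("direction results are deterministic given a seed", {
  set.seed(70)
  bs <- runif(60, 0.3, 0.7)
  br <- runif(60, 0.3, 0.7)
  r1 <- direction_test(bs, br, rng_seed = 71)
  r2 <- direction_test(bs, br, rng_seed = 71)
  expect_identical(tidy(r1), tidy(r2))
})
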