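test_that("consensify site calls follow the majority-of-3 rule", {
  p6 <- consensify_params(max_depth = 6)
  expect_equal(call_consensify_site(c(3, 0, 0, 0), p6, rng_seed = 1), "A")
  # depth above the cap (twice a mean coverage of 3) is masked
  expect_equal(call_consensify_site(c(7, 0, 0, 0), p6, rng_seed = 1), "N")
  expect_equal(call_consensify_site(c(0, 0, 0, 0)), "N")
  expect_equal(call_consensify_site(c(1, 0, 0, 0)), "N")  # below min_depth
  expect_error(call_consensify_site(c(-1, 0, 0, 0)), "non-negative")
})

test_that("three distinct observations can never yield a majority", {
  calls <- vapply(1:50, function(s) {
    call_consensify_site(c(1, 1, 1, 0), consensify_params(), rng_seed = s)
  }, character(1))
  expect_true(all(calls == "N"))
})

test_that("site probabilities match the exhaustive subset oracle", {
  set.seed(42)
  cases <- list(c(1, 1, 0, 0), c(2, 2, 0, 0), c(3, 3, 0, 0),
                c(2, 1, 0, 0), c(4, 2, 0, 0), c(2, 2, 2, 0))
  for (counts in cases) {
    oracle <- consensify_site_probs(counts)
    n_draw <- 3000
    draws <- vapply(seq_len(n_draw), function(i) {
      call_consensify_site(counts, consensify_params(max_depth = 10))
    }, character(1))
    emp <- table(factor(draws, levels = c("A", "C", "G", "T", "N"))) / n_draw
    for (b in names(oracle)) {
      se <- sqrt(max(oracle[b] * (1 - oracle[b]), 1e-9) / n_draw)
      expect_lt(abs(emp[[b]] - oracle[[b]]), 4 * se + 1e-9)
    }
  }
})

test_that("balanced heterozygous sites are called symmetrically", {
  # counts (k, k): oracle gives equal probability to each allele and the
  # enumerable remainder to N
  for (k in 1:3) {
    oracle <- consensify_site_probs(c(k, k, 0, 0))
    expect_equal(oracle[["A"]], oracle[["C"]])
    expect_equal(oracle[["A"]] * 2 + oracle[["N"]], 1)
  }
})

test_that("raising max_depth never converts a called base to N", {
  set.seed(7)
  for (i in 1:60) {
    counts <- as.integer(rmultinom(1, sample(2:9, 1), c(4, 2, 1, 1)))
    lo <- call_consensify_site(counts, consensify_params(max_depth = 5),
                               rng_seed = i)
    hi <- call_consensify_site(counts, consensify_params(max_depth = 10),
                               rng_seed = i)
    if (lo != "N") expect_equal(hi, lo)
  }
})

test_that("error-free depth >= 3 homozygous sites always call the truth", {
  for (base in 1:4) {
    counts <- integer(4); counts[base] <- 5L
    call <- call_consensify_site(counts, consensify_params(max_depth = 10),
                                 rng_seed = base)
    expect_equal(call, c("A", "C", "G", "T")[base])
  }
})

test_that("random-read calls are uniform over observations", {
  p <- consensify_params(min_depth = 1)
  expect_equal(call_random_site(c(5, 0, 0, 0), p, rng_seed = 1), "A")
  expect_equal(call_random_site(c(0, 0, 0, 0), p), "N")
  draws <- vapply(1:4000, function(s) {
    call_random_site(c(1, 0, 0, 1), p, rng_seed = s)
  }, character(1))
  frac_a <- mean(draws == "A")
  expect_true(all(draws %in% c("A", "T")))
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("auto max depth is twice the empirical mean", {
  counts <- matrix(c(2L, 0L, 0L, 0L,
                     0L, 4L, 0L, 0L,
                     0L, 0L, 3L, 0L), nrow = 3, byrow = TRUE)
  expect_equal(auto_max_depth(counts), 6)
})

test_that("genome calling is deterministic and masks zero-coverage sites", {
  zero <- list(s1 = matrix(0L, nrow = 20, ncol = 4))
  g <- call_genome(zero, mode = "consensify", rng_seed = 1)
  expect_equal(g$sequences[["s1"]], strrep("N", 20))

  cnt <- matrix(0L, nrow = 30, ncol = 4)
  cnt[cbind(seq_len(30), rep(1:4, length.out = 30))] <- 5L
  bc <- list(s1 = cnt, s2 = cnt[1:10, ])
  g1 <- call_genome(bc, mode = "random", rng_seed = 3,
                    params = consensify_params(min_depth = 1))
  g2 <- call_genome(bc, mode = "random", rng_seed = 3,
                    params = consensify_params(min_depth = 1))
  expect_identical(g1$sequences, g2$sequences)
  expect_equal(nchar(g1$sequences[["s2"]]), 10)
})

test_that("called pseudohaploids agree with the truth at high coverage", {
  m <- toy_model()
  truth <- simulate_cohort(m, 3, 400, rng_seed = 21)
  for (w in truth$windows) {
    by_ind <- genotypes_by_individual(w$genotypes)
    haps <- by_ind[["blue1"]]
    counts <- apply_damage_and_coverage(haps, clean_params(coverage = 40),
                                        rng_seed = 22)
    g <- call_genome(list(s = unclass(counts)), mode = "consensify",
                     params = consensify_params(max_depth = Inf),
                     rng_seed = 23, individual = "blue1")
    called <- encode_bases(g$sequences[["s"]])
    ok <- called != 0L
    expect_true(all(called[ok] == haps[1, ok] | called[ok] == haps[2, ok]))
    hom <- haps[1, ] == haps[2, ]
    expect_true(all(called[ok & hom] == haps[1, ok & hom]))
  }
})
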