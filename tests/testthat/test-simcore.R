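test_that("expected discordance follows the closed form", {
  expect_equal(expected_discordance(0), 2 / 3)
  expect_equal(expected_discordance(1), (2 / 3) * exp(-1), tolerance = 1e-12)
  expect_equal(round(expected_discordance(1), 4), 0.2453)
  expect_lt(expected_discordance(50), 1e-20)
  expect_error(expected_discordance(-0.1), "non-negative")
})

test_that("demographic model validates its invariants", {
  expect_error(demographic_model(split_time_bs = 4e5, split_time_r = 3e5),
               "split times")
  expect_error(demographic_model(pop_size = -1), "positive")
  expect_error(demographic_model(mu = -1e-9), "mu")
  expect_error(demographic_model(kappa = 0), "kappa")
  expect_error(
    demographic_model(pulse = list(donor = "roan", recipient = "blue",
                                   time = 5e5, proportion = 0.1)),
    "pulse time")
  expect_error(
    demographic_model(pulse = list(donor = "roan", recipient = "blue",
                                   time = 1e5, proportion = 1.5)),
    "proportion")
})

test_that("gene trees are ultrametric with the right leaf count", {
  m <- demographic_model(samples = c(blue = 2, sable = 1, roan = 1))
  gt <- simulate_gene_tree(m, rng_seed = 11)
  expect_s3_class(gt$phylo, "phylo")
  # 2 + 1 + 1 diploids = 8 haplotypes, + 1 haploid outgroup
  expect_length(gt$phylo$tip.label, 9)
  expect_true(ape::is.ultrametric(gt$phylo, tol = 1e-8))
  expect_true(all(gt$phylo$edge.length >= 0))
})

test_that("topology-class frequencies match the coalescent prediction", {
  n <- 4000
  cal <- discordance_calibration(T_coal = 1, n_windows = n, rng_seed = 5)
  expect_lt(abs(cal$observed - cal$expected), 3 * cal$mc_se)
  # the two discordant classes are exchangeable
  p <- cal$proportions
  se_diff <- sqrt((p[["BR"]] + p[["RS"]]) / n)
  expect_lt(abs(p[["BR"]] - p[["RS"]]), 3 * se_diff)
})

test_that("a forced recent pulse makes blue sister to roan", {
  m <- toy_model(pulse = list(donor = "roan", recipient = "blue",
                              time = 1000, proportion = 1))
  classes <- simulate_topology_classes(m, 300, rng_seed = 2)
  p <- attr(classes, "proportions")
  expect_gt(p[["BR"]], p[["BS"]])
  expect_gt(p[["BR"]], p[["RS"]])
  expect_gt(p[["BR"]], 0.6)
})

test_that("deep splits relative to Ne remove almost all discordance", {
  m <- toy_model(pop_size = 500)  # internal branch ~ 149 coalescent units
  classes <- simulate_topology_classes(m, 200, rng_seed = 3)
  expect_equal(attr(classes, "proportions")[["BS"]], 1)
})

test_that("pulse migrants are flagged and only when f > 0", {
  m0 <- toy_model()
  gt0 <- simulate_gene_tree(m0, rng_seed = 4)
  expect_length(gt0$migrants, 0)
  m1 <- toy_model(pulse = list(donor = "roan", recipient = "blue",
                               time = 1000, proportion = 1))
  gt1 <- simulate_gene_tree(m1, rng_seed = 4)
  expect_true(all(c("blue1_1", "blue1_2") %in% gt1$migrants))
})

test_that("zero mutation rate reproduces the ancestral sequence", {
  gt <- simulate_gene_tree(toy_model(), rng_seed = 7)
  anc <- rep(1:4, length.out = 100)
  h <- simulate_window_genotypes(gt, 100, mu = 0, kappa = 2, rng_seed = 8,
                                 ancestral = anc)
  expect_true(all(apply(h, 1, identical, as.integer(anc))))
})

test_that("pairwise divergence matches the K2P closed form", {
  mu <- 2e-6
  kappa <- 3
  gt <- simulate_gene_tree(toy_model(), rng_seed = 9)
  L <- 60000
  h <- simulate_window_genotypes(gt, L, mu = mu, kappa = kappa,
                                 rng_seed = 10)
  t_path <- 2 * gt$tmrca[["bs"]]
  p_exp <- k2p_expected_pdist(mu, kappa, t_path)
  p_obs <- mean(h["blue1_1", ] != h["sable1_1", ])
  mc_se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * mc_se)
})

test_that("huge kappa makes haplotypes identical under RY coding", {
  gt <- simulate_gene_tree(toy_model(), rng_seed = 12)
  h <- simulate_window_genotypes(gt, 5000, mu = 1e-6, kappa = 1e6,
                                 rng_seed = 13)
  ry <- h %% 2L  # purine/pyrimidine parity of the 1:4 coding
  expect_true(all(apply(ry, 2, function(col) length(unique(col)) == 1)))
})

test_that("damage model hits terminal cytosines at the nominal rate", {
  # read_len = 1 puts every observed base at fragment position 0
  h <- rbind(rep(2L, 4000), rep(2L, 4000))
  p <- damage_params(delta_ss = 0.3, lambda = 0.3, delta_ox = 0, eps = 0,
                     coverage = 5, read_len = 1)
  bc <- apply_damage_and_coverage(h, p, rng_seed = 14)
  n_reads <- sum(bc)
  frac_t <- sum(bc[, 4]) / n_reads
  se <- sqrt(0.3 * 0.7 / n_reads)
  expect_lt(abs(frac_t - 0.3), 3 * se)
  expect_equal(sum(bc[, c(1, 3)]), 0)  # only C and T can be observed
})

test_that("oxidation converts guanines uniformly and errors are uniform", {
  h <- rbind(rep(3L, 4000), rep(3L, 4000))
  p <- damage_params(delta_ss = 0.3, lambda = 0.3, delta_ox = 0.1, eps = 0,
                     coverage = 5, read_len = 60)
  bc <- apply_damage_and_coverage(h, p, rng_seed = 15)
  frac_t <- sum(bc[, 4]) / sum(bc)
  se <- sqrt(0.1 * 0.9 / sum(bc))
  expect_lt(abs(frac_t - 0.1), 3 * se)
})

test_that("zero coverage produces zero counts and clean high coverage
           recovers the truth", {
  h <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L))
  bc0 <- apply_damage_and_coverage(h, damage_params(coverage = 0),
                                   rng_seed = 16)
  expect_equal(sum(bc0), 0)
  bc <- apply_damage_and_coverage(h, clean_params(coverage = 50),
                                  rng_seed = 17)
  expect_equal(unname(apply(bc, 1, which.max)), c(1, 2, 3, 4))
  # reads are conserved: every sampled observation lands in some count
  expect_true(all(rowSums(bc) > 0))
})

test_that("the damage layer conserves read depth across damage settings", {
  h <- rbind(sample(1:4, 3000, TRUE), sample(1:4, 3000, TRUE))
  p1 <- damage_params(delta_ss = 0, lambda = 0.3, delta_ox = 0, eps = 0,
                      coverage = 4, read_len = 60)
  p2 <- damage_params(delta_ss = 1, lambda = 0.3, delta_ox = 0.5, eps = 0,
                      coverage = 4, read_len = 60)
  bc1 <- apply_damage_and_coverage(h, p1, rng_seed = 18)
  bc2 <- apply_damage_and_coverage(h, p2, rng_seed = 18)
  # damage changes identities, never depth
  expect_equal(rowSums(bc2), rowSums(bc1))
})

test_that("the same seed reproduces an identical truth bundle", {
  m <- toy_model()
  t1 <- simulate_cohort(m, 5, 300, rng_seed = 19)
  t2 <- simulate_cohort(m, 5, 300, rng_seed = 19)
  expect_identical(lapply(t1$windows, `[[`, "genotypes"),
                   lapply(t2$windows, `[[`, "genotypes"))
  expect_identical(vapply(t1$windows, `[[`, character(1), "topology"),
                   vapply(t2$windows, `[[`, character(1), "topology"))
})
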