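test_that("clean-difference counting excludes damage-prone classes", {
  r1 <- pairwise_clean_differences("ACGT", "ACGA")  # T/A: clean
  expect_equal(r1$n_clean_differences, 1)
  r2 <- pairwise_clean_differences("AG", "TT")      # A/T clean, G/T damage
  expect_equal(r2$n_clean_differences, 1)
  r3 <- pairwise_clean_differences("ACGT", "ACGT")
  expect_equal(r3$n_clean_differences, 0)
  expect_equal(r3$normalized, 0)
  # exhaustive: only A/T and C/G pairs ever count
  for (a in 1:4) {
    for (b in 1:4) {
      n <- pairwise_clean_differences(a, b)$n_clean_differences
      clean <- (a != b) && (a + b == 5) && !(a %in% c(2, 3) && b %in% c(2, 3))
      # codes: A=1 T=4 sum 5; C=2 G=3 sum 5 -> both sums are 5
      expect_equal(n, as.integer(a + b == 5 && a != b))
    }
  }
})

test_that("pairwise differences over a filtered matrix share a denominator", {
  m <- filter_sites(site_matrix(rbind(a = c("A", "G", "T", "C"),
                                      b = c("T", "G", "T", "G"),
                                      c = c("A", "A", "T", "C"))))$matrix
  r <- pairwise_clean_differences("a", "b", m)
  expect_equal(r$n_filtered_sites, ncol(m))
  expect_equal(r$normalized, r$n_clean_differences / ncol(m))
  expect_error(pairwise_clean_differences("a", "zzz", m), "not found")
})

test_that("the substitution spectrum matches the mutation model", {
  # small Ne keeps the within-individual path short, so multiple hits are
  # rare and the raw mutation spectrum shows through
  gt <- simulate_gene_tree(toy_model(kappa = 2, pop_size = 5000),
                           rng_seed = 81)
  h <- simulate_window_genotypes(gt, 50000, mu = 1e-6, kappa = 2,
                                 rng_seed = 82)
  sp <- substitution_spectrum(h["blue1_1", ], h["blue1_2", ])
  ts_frac <- sum(sp$n[sp$class == "transition"]) / sum(sp$n)
  se <- sqrt(ts_frac * (1 - ts_frac) / sum(sp$n))
  expect_lt(abs(ts_frac - 2 / 3), 4 * se)
  # identical sequences: empty spectrum
  sp0 <- substitution_spectrum("ACGT", "ACGT")
  expect_equal(sum(sp0$n), 0)
})

test_that("damage elevates the C/T and G/T channels", {
  gt <- simulate_gene_tree(toy_model(), rng_seed = 83)
  h <- simulate_window_genotypes(gt, 20000, mu = 5e-7, kappa = 2,
                                 rng_seed = 84)
  pair <- h[c("blue1_1", "blue1_2"), ]
  clean_counts <- apply_damage_and_coverage(pair, clean_params(coverage = 8),
                                            rng_seed = 85)
  dmg <- damage_params(delta_ss = 0.3, lambda = 0.3, delta_ox = 0.1,
                       eps = 0, coverage = 8, read_len = 60)
  dmg_counts <- apply_damage_and_coverage(pair, dmg, rng_seed = 85)
  p <- consensify_params(max_depth = 16)
  ref <- decode_bases(h["sable1_1", ], collapse = TRUE)
  g_clean <- call_genome(list(s = unclass(clean_counts)), "consensify",
                         params = p, rng_seed = 86)$sequences[["s"]]
  g_dmg <- call_genome(list(s = unclass(dmg_counts)), "consensify",
                       params = p, rng_seed = 86)$sequences[["s"]]
  s_clean <- substitution_spectrum(ref, g_clean)
  s_dmg <- substitution_spectrum(ref, g_dmg)
  get <- function(s, t) s$n[s$type == t]
  expect_gt(get(s_dmg, "G/T") + get(s_dmg, "C/T"),
            get(s_clean, "G/T") + get(s_clean, "C/T"))
})

test_that("species diversity ordering follows effective size", {
  study <- diversity_study(n_windows = 12, window_length = 10000,
                           n_per_species = 3, rng_seed = 87)
  means <- study$diversity$species_means
  v <- stats::setNames(means$mean_normalized, means$species)
  expect_gt(v[["roan"]], v[["sable"]])
  expect_gt(v[["sable"]], v[["blue"]])
  het <- study$heterozygosity
  sp_het <- tapply(het, sub("[0-9].*$", "", names(het)), mean)
  expect_equal(cor(v[names(sp_het)], sp_het, method = "spearman"), 1)
})

test_that("true heterozygosity matches the coalescent expectation", {
  ne <- 20000
  mu <- 5e-7
  m <- demographic_model(pop_size = ne, mu = mu,
                         samples = c(blue = 1, sable = 1, roan = 1))
  truth <- simulate_cohort(m, 40, 2000, rng_seed = 88)
  per_window <- vapply(truth$windows, function(w) {
    mean(w$genotypes["blue1_1", ] != w$genotypes["blue1_2", ])
  }, numeric(1))
  h <- true_heterozygosity(truth, "blue1")
  expect_equal(h, mean(per_window), tolerance = 1e-12)
  expected <- 4 * ne * mu
  mc_se <- stats::sd(per_window) / sqrt(length(per_window))
  expect_lt(abs(h - expected), 3 * mc_se)
  # zero mutation rate: no heterozygosity
  m0 <- demographic_model(mu = 0, samples = c(blue = 1, sable = 1, roan = 1))
  t0 <- simulate_cohort(m0, 2, 500, rng_seed = 89)
  expect_equal(true_heterozygosity(t0, "blue1"), 0)
  expect_error(true_heterozygosity(list(), "blue1"), "simulation truth")
})

test_that("heterozygosity grows with effective size", {
  hets <- vapply(c(2e3, 2e4, 2e5), function(ne) {
    m <- demographic_model(pop_size = ne, mu = 2.5e-7,
                           samples = c(blue = 1, sable = 1, roan = 1))
    true_heterozygosity(simulate_cohort(m, 15, 2000, rng_seed = 90), "blue1")
  }, numeric(1))
  expect_true(all(diff(hets) > 0))
})

test_that("diversity tables warn about singleton species", {
  g <- list(blue1 = c(s = "ACGTACGTAA"), blue2 = c(s = "ACGAACGTAA"),
            roan1 = c(s = "TCGTACGTTT"))
  expect_warning(res <- diversity_table(g), "roan")
  expect_equal(res$pairs$species, "blue")
})
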