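# Self-contained simulation studies used to verify each inference stage
# against simulation truth. These functions define the study conditions
# (sample sizes, rates, effect sizes) in one place so that tests, the
# reproduction script and the vignette all run the same experiments.

#' Model with a prescribed internal branch in coalescent units
#'
#' Keeps the dated splits of the default model and sets the blue-sable
#' ancestor size so that the internal branch equals `T_coal` coalescent
#' units.
#'
#' @param T_coal Target internal branch length (coalescent units).
#' @param ... Passed to [demographic_model()].
#' @return A [demographic_model()].
#' @export
model_with_internal_branch <- function(T_coal, ...) {
  base <- demographic_model(...)
  ne <- (base$split_time_r - base$split_time_bs) / (2 * T_coal)
  ps <- base$pop_size
  ps[c("bs", "bsr", "root", "blue", "sable", "roan", "outgroup")] <- ne
  demographic_model(split_time_bs = base$split_time_bs,
                    split_time_r = base$split_time_r,
                    split_time_o = base$split_time_o,
                    pop_size = ps, pulse = base$pulse, mu = base$mu,
                    kappa = base$kappa, samples = base$samples)
}

#' Calibrate the simulator against the analytic discordance probability
#'
#' Simulates gene trees with no gene flow and an internal branch of
#' `T_coal` coalescent units and compares the discordant-genealogy fraction
#' with `(2/3) exp(-T_coal)`.
#'
#' @param T_coal Internal branch (default 1).
#' @param n_windows Number of windows (default 10000).
#' @param rng_seed Integer seed.
#' @return List with `observed`, `expected`, `mc_se`, `n_windows`, and the
#'   per-class proportions.
#' @export
discordance_calibration <- function(T_coal = 1, n_windows = 10000,
                                    rng_seed = 1) {
  model <- model_with_internal_branch(T_coal)
  classes <- simulate_topology_classes(model, n_windows, rng_seed = rng_seed)
  props <- attr(classes, "proportions")
  expected <- expected_discordance(T_coal)
  observed <- unname(props["BR"] + props["RS"])
  list(observed = observed, expected = expected,
       mc_se = sqrt(expected * (1 - expected) / n_windows),
       n_windows = n_windows, proportions = props)
}

#' Model for the introgression studies
#'
#' The default demography plus a pulse of proportion `f` between roan and
#' blue at 100,000 generations (0.8 Ma at 8 years/generation, after the
#' blue-sable split as inferred for the study system).
#'
#' @param f Pulse proportion (0 disables the pulse).
#' @param direction `"roan_to_blue"` or `"blue_to_roan"`.
#' @param samples Diploid sample sizes (default 1 per species).
#' @param ... Passed to [demographic_model()].
#' @return A [demographic_model()].
#' @export
pulse_model <- function(f = 0.2, direction = c("roan_to_blue",
                                               "blue_to_roan"),
                        samples = c(blue = 1, sable = 1, roan = 1), ...) {
  direction <- match.arg(direction)
  pulse <- if (f > 0) {
    if (direction == "roan_to_blue") {
      list(donor = "roan", recipient = "blue", time = 1e5, proportion = f)
    } else {
      list(donor = "blue", recipient = "roan", time = 1e5, proportion = f)
    }
  }
  demographic_model(pulse = pulse, samples = samples, ...)
}

#' D-statistic recovery study
#'
#' Simulates `n_windows` windows under a pulse model, pseudohaploidizes the
#' true genotypes (high-coverage damage-free limit), and runs the
#' transversions-only ABBA-BABA test with sable in position 1, blue in
#' position 2, roan in position 3.
#'
#' @param f Pulse proportion.
#' @param direction Pulse direction (see [pulse_model()]).
#' @param n_windows Number of windows (default 2000).
#' @param window_length Window length in bp (default 5000).
#' @param block_size Jackknife block size in bp (default 1e6).
#' @param rng_seed Integer seed.
#' @return A `"dstat_result"`.
#' @export
dstat_study <- function(f = 0.2, direction = "roan_to_blue",
                        n_windows = 2000, window_length = 5000,
                        block_size = 1e6, rng_seed = 1) {
  model <- pulse_model(f = f, direction = direction)
  truth <- simulate_cohort(model, n_windows, window_length,
                           rng_seed = rng_seed)
  genomes <- pseudohaploids_from_cohort(truth, rng_seed = rng_seed + 1L)
  dstat(genomes$sable1, genomes$blue1, genomes$roan1, genomes$outgroup,
        block_size = block_size)
}

#' Window-tree study
#'
#' Simulates windows, pseudohaploidizes the truth, and runs the
#' window-tree stage with one window per simulated locus (window size =
#' simulated window length, no gap: the simulation already provides
#' independent loci).
#'
#' @inheritParams dstat_study
#' @param samples Diploid sample sizes.
#' @param return_truth Also return the truth bundle.
#' @param ... Passed to [pulse_model()] (e.g. `pop_size`).
#' @return Window-record tibble (see [window_trees()]); with
#'   `return_truth = TRUE`, a list `(records, truth)`.
#' @export
window_study <- function(f = 0, direction = "roan_to_blue", n_windows = 500,
                         window_length = 20000,
                         samples = c(blue = 1, sable = 1, roan = 1),
                         rng_seed = 1, return_truth = FALSE, ...) {
  model <- pulse_model(f = f, direction = direction, samples = samples, ...)
  truth <- simulate_cohort(model, n_windows, window_length,
                           rng_seed = rng_seed)
  genomes <- pseudohaploids_from_cohort(truth, rng_seed = rng_seed + 1L)
  cfg <- window_config(window_size = window_length, gap = 0)
  recs <- window_trees(genomes, cfg)
  if (return_truth) list(records = recs, truth = truth) else recs
}

#' Gene-flow direction recovery study
#'
#' Runs [window_study()] under a pulse scenario and applies the
#' branch-length direction test to the BS and BR window classes. The study
#' demography uses a smaller effective size (`pop_size = 30000`, giving an
#' internal branch of about 2.5 coalescent units) than the
#' discordance-anchored default, so that introgressed windows dominate the
#' discordant class and the test's directional signal is identifiable at
#' desk scale: the study validates the estimator, not the power of the
#' high-ILS empirical regime.
#'
#' @inheritParams window_study
#' @param config A [direction_config()].
#' @param pop_size Effective size for all branches (default 30000).
#' @return A `"direction_result"`.
#' @export
direction_study <- function(f = 0.2, direction = "roan_to_blue",
                            n_windows = 300, window_length = 10000,
                            config = direction_config(), rng_seed = 1,
                            pop_size = 30000, ...) {
  recs <- window_study(f = f, direction = direction, n_windows = n_windows,
                       window_length = window_length, rng_seed = rng_seed,
                       pop_size = pop_size, ...)
  direction_test(recs$rs_path_proportion[recs$topology_class == "BS"],
                 recs$rs_path_proportion[recs$topology_class == "BR"],
                 config, rng_seed = rng_seed + 7L)
}

#' Model for the diversity validation study
#'
#' Three species with contrasting effective sizes (`blue` 1e3, `sable` 1e4,
#' `roan` 1e5 by default) under the dated species tree, with a mutation
#' rate scaled up so that a desk-scale genome carries the information of a
#' much larger one.
#'
#' @param ne Named vector of per-species Ne (ancestral branches get the
#'   roan value).
#' @param n_per_species Diploid individuals per species.
#' @param mu Mutation rate (default 1e-7, a 100 kb-emulates-10 Mb scaling
#'   of a typical mammalian 1e-8 per-generation rate).
#' @return A [demographic_model()].
#' @export
diversity_model <- function(ne = c(blue = 1e3, sable = 1e4, roan = 1e5),
                            n_per_species = 4, mu = 1e-7) {
  demographic_model(
    pop_size = c(blue = ne[["blue"]], sable = ne[["sable"]],
                 roan = ne[["roan"]], outgroup = ne[["roan"]],
                 bs = ne[["roan"]], bsr = ne[["roan"]],
                 root = ne[["roan"]]),
    mu = mu,
    samples = c(blue = n_per_species, sable = n_per_species,
                roan = n_per_species)
  )
}

#' Diversity validation study
#'
#' Simulates a three-species cohort, pushes every individual through the
#' read-level observation model and Consensify calling, and compares the
#' damage-aware diversity statistic against simulation-truth
#' heterozygosity. Damage (when requested) is applied to two blue
#' individuals -- both deaminated, one additionally oxidized -- emulating an
#' ancient/historical specimen pair among modern comparators.
#'
#' @param n_windows Number of windows (default 50).
#' @param window_length Window length in bp (default 20000).
#' @param n_per_species Diploid individuals per species (default 4).
#' @param with_damage Apply the aDNA damage channels to the two blue
#'   specimens (default FALSE).
#' @param coverage Mean depth for every individual (default 5).
#' @param delta_ss,delta_ox Damage intensities for the damaged specimens.
#' @param rng_seed Integer seed.
#' @return List with `diversity` (a `"diversity_result"`), `heterozygosity`
#'   (named per-individual truth), `truth`, `genomes`, and `raw_differences`
#'   (tibble of unfiltered differing-site counts per within-species pair).
#' @export
diversity_study <- function(n_windows = 50, window_length = 20000,
                            n_per_species = 4, with_damage = FALSE,
                            coverage = 5, delta_ss = 0.3, delta_ox = 0.1,
                            rng_seed = 1) {
  model <- diversity_model(n_per_species = n_per_species)
  truth <- simulate_cohort(model, n_windows, window_length,
                           rng_seed = rng_seed)
  clean <- clean_params(coverage = coverage)
  damage <- if (with_damage) {
    list(
      blue1 = damage_params(delta_ss = delta_ss, lambda = 0.3,
                            delta_ox = delta_ox, eps = 0,
                            coverage = coverage, read_len = 60),
      blue2 = damage_params(delta_ss = delta_ss, lambda = 0.3, delta_ox = 0,
                            eps = 0, coverage = coverage, read_len = 60)
    )
  } else {
    clean
  }
  params <- consensify_params(max_depth = floor(2 * coverage))
  genomes <- pseudohaploids_from_cohort(truth, damage = damage,
                                        mode = "consensify",
                                        params = params,
                                        rng_seed = rng_seed + 1L)
  div <- diversity_table(genomes)
  inds <- names(genomes)[!startsWith(names(genomes), "outgroup")]
  het <- vapply(inds, function(i) true_heterozygosity(truth, i), numeric(1))
  raw <- raw_difference_table(genomes)
  list(diversity = div, heterozygosity = het, truth = truth,
       genomes = genomes, raw_differences = raw)
}

# unfiltered differing-site counts (any class, both bases called) per
# within-species pair
raw_difference_table <- function(genomes) {
  ids <- names(genomes)[!startsWith(names(genomes), "outgroup")]
  sp <- sub("[0-9_].*$", "", ids)
  rows <- list()
  for (s in unique(sp)) {
    inds <- ids[sp == s]
    if (length(inds) < 2) next
    for (i in seq_len(length(inds) - 1)) {
      for (j in (i + 1):length(inds)) {
        ia <- encode_bases(genomes[[inds[i]]][[1]])
        ib <- encode_bases(genomes[[inds[j]]][[1]])
        ok <- ia > 0L & ib > 0L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species = s, ind_a = inds[i], ind_b = inds[j],
          n_raw_differences = sum(ia[ok] != ib[ok]), n_comparable = sum(ok)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Synthetic low-diversity mitochondrial-like alignment
#'
#' Simulates a small panmictic low-diversity cohort and returns an aligned
#' set of haploid sequences, mimicking the handful of closely related
#' mitogenomes of a bottlenecked species. Purely synthetic: used to
#' exercise the mitochondrial statistics without external data.
#'
#' @param n_seq Number of sequences (default 3).
#' @param length Alignment length (default 16500).
#' @param theta Per-site pairwise diversity of the simulated population
#'   (default 5e-4).
#' @param missing_frac Fraction of columns turned into `N` in one sequence
#'   to exercise the ambiguity filter (default 0.002).
#' @param rng_seed Integer seed.
#' @return Named character vector of aligned sequences.
#' @export
synthetic_mito_alignment <- function(n_seq = 3, length = 16500,
                                     theta = 5e-4, missing_frac = 0.002,
                                     rng_seed = 1) {
  set.seed(rng_seed)
  ne <- 5000
  mu <- theta / (4 * ne)
  model <- demographic_model(pop_size = ne, mu = mu,
                             samples = c(blue = max(2, ceiling(n_seq / 2)),
                                         sable = 1, roan = 1))
  gt <- simulate_gene_tree(model)
  haps <- simulate_window_genotypes(gt, length, mu = model$mu,
                                    kappa = model$kappa)
  blue_rows <- grep("^blue", rownames(haps), value = TRUE)[seq_len(n_seq)]
  seqs <- apply(haps[blue_rows, , drop = FALSE], 1, decode_bases,
                collapse = TRUE)
  names(seqs) <- paste0("synthetic_mito_", seq_len(n_seq))
  if (missing_frac > 0) {
    chars <- strsplit(seqs[[1]], "")[[1]]
    idx <- sample.int(length, max(1, round(missing_frac * length)))
    chars[idx] <- "N"
    seqs[1] <- paste(chars, collapse = "")
  }
  seqs
}
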