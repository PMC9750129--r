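#' Simulate a cohort of independent windows with full truth
#'
#' Runs the structured coalescent, mutation and (optionally) the
#' damage/coverage layer for `n_windows` freely recombining windows,
#' retaining the truth needed by every downstream oracle: the gene trees,
#' the true diploid genotypes, the quartet topology class of each window
#' genealogy, and the migrant flags.
#'
#' @param model A [demographic_model()].
#' @param n_windows Number of windows.
#' @param window_length Window length in bp.
#' @param rng_seed Integer seed; windows use sequential draws from one
#'   seeded stream, so the whole bundle is reproducible bit for bit.
#' @param keep_genotypes Keep per-window genotype matrices (default TRUE;
#'   disable for topology-only calibrations).
#' @param keep_trees Keep the `gene_tree` objects (default FALSE to bound
#'   memory; topology classes and migrant flags are always kept).
#' @return Object of class `"truth_bundle"`: list with `model`,
#'   `window_length`, `windows` (list of per-window lists with elements
#'   `topology`, `migrants`, and optionally `genotypes`, `tree`), and
#'   `topology_counts`.
#' @export
simulate_cohort <- function(model, n_windows, window_length, rng_seed = 1,
                            keep_genotypes = TRUE, keep_trees = FALSE) {
  set.seed(rng_seed)
  windows <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    gt <- simulate_gene_tree(model)
    w <- list(topology = gt$topology, migrants = gt$migrants)
    if (keep_genotypes) {
      w$genotypes <- simulate_window_genotypes(gt, window_length,
                                               mu = model$mu,
                                               kappa = model$kappa)
    }
    if (keep_trees) w$tree <- gt
    windows[[i]] <- w
  }
  topo <- vapply(windows, `[[`, character(1), "topology")
  structure(
    list(model = model, window_length = as.integer(window_length),
         windows = windows, seed = rng_seed,
         topology_counts = table(factor(topo, levels = c("BS", "BR", "RS")))),
    class = "truth_bundle"
  )
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle>", length(x$windows), "windows of", x$window_length,
      "bp (seed", paste0(x$seed, ")"), "\n")
  print(x$topology_counts)
  invisible(x)
}

#' Pseudohaploid genomes from a truth bundle
#'
#' Concatenates the windows of a [simulate_cohort()] bundle into one
#' synthetic scaffold per individual and produces pseudohaploid sequences,
#' either by direct allele sampling (`damage = NULL`: the high-coverage
#' damage-free limit) or through the full read-level observation model and
#' a calling mode.
#'
#' @param truth A `"truth_bundle"` with genotypes.
#' @param damage `NULL`, a single [damage_params()] applied to every
#'   individual, or a named list (individual -> [damage_params()]) applying
#'   the read layer only to the named individuals (others get
#'   [clean_params()] at the same coverage).
#' @param mode Calling mode when `damage` is used: `"consensify"` or
#'   `"random"`.
#' @param params A [consensify_params()] for the caller.
#' @param rng_seed Integer seed.
#' @return Named list: individual -> named character vector with one
#'   scaffold `"scaffold_1"`.
#' @export
pseudohaploids_from_cohort <- function(truth, damage = NULL,
                                       mode = c("consensify", "random"),
                                       params = consensify_params(),
                                       rng_seed = 1) {
  stopifnot(inherits(truth, "truth_bundle"))
  mode <- match.arg(mode)
  set.seed(rng_seed)
  inds <- unique(sub("_[12]$", "",
                     rownames(truth$windows[[1]]$genotypes)))
  chunks <- stats::setNames(
    lapply(inds, function(i) vector("list", length(truth$windows))), inds)
  for (wi in seq_along(truth$windows)) {
    g <- truth$windows[[wi]]$genotypes
    by_ind <- genotypes_by_individual(g)
    for (ind in inds) {
      haps <- by_ind[[ind]]
      called <- if (is.null(damage)) {
        pseudohaploid_from_truth(haps)
      } else {
        dp <- if (inherits(damage, "damage_params")) damage
              else if (!is.null(damage[[ind]])) damage[[ind]]
              else clean_params(coverage = damage_coverage(damage))
        counts <- apply_damage_and_coverage(haps, dp)
        if (mode == "consensify") call_consensify_idx(counts, params)
        else call_random_idx(counts, params)
      }
      chunks[[ind]][[wi]] <- decode_bases(called, collapse = TRUE)
    }
  }
  lapply(chunks, function(ch) c(scaffold_1 = paste(unlist(ch), collapse = "")))
}

# coverage shared by a per-individual damage list (first entry's coverage)
damage_coverage <- function(damage) {
  dp <- damage[[which(vapply(damage, inherits, logical(1),
                             "damage_params"))[1]]]
  dp$coverage
}
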