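#' Demographic model for the Hippotragus-like species quartet
#'
#' Describes a four-species tree `(((blue, sable), roan), outgroup)` with
#' per-branch diploid effective population sizes, an optional unidirectional
#' introgression pulse, and a two-parameter (Kimura-type) mutation model.
#' Times are in generations before present; population sizes are diploid
#' effective sizes.
#'
#' The default values anchor the split times to the dated species divergences
#' of the blue/sable/roan antelope system (blue-sable split 1.67 Ma, roan
#' split 2.86 Ma, outgroup calibration around 4.05 Ma) converted to
#' generations with a generation time of 8 years.
#'
#' @param split_time_bs Generations at which blue and sable lineages merge.
#' @param split_time_r Generations at which the blue+sable ancestor merges
#'   with roan. Must exceed `split_time_bs`.
#' @param split_time_o Generations at which the ingroup ancestor merges with
#'   the outgroup. Must exceed `split_time_r`.
#' @param pop_size Named numeric vector of diploid effective sizes for the
#'   branches `blue`, `sable`, `roan`, `outgroup`, `bs` (blue+sable ancestor),
#'   `bsr` (ingroup ancestor) and `root`. A single unnamed value is recycled
#'   to all branches.
#' @param pulse `NULL` for no gene flow, or a list with elements `donor`,
#'   `recipient` (species names), `time` (generations, before the donor and
#'   recipient share a population) and `proportion` (`f`, in `[0, 1]`): at
#'   `time`, each recipient-population lineage independently switches to the
#'   donor population with probability `f`.
#' @param mu Mutation rate per site per generation.
#' @param kappa Transition/transversion rate ratio (a new mutation is a
#'   transition with probability `kappa / (kappa + 1)`).
#' @param samples Named integer vector: number of diploid individuals sampled
#'   per ingroup species. The outgroup is always sampled as a single haploid
#'   lineage used for rooting/polarization.
#'
#' @return An object of class `"demographic_model"`.
#' @examples
#' m <- demographic_model()
#' m$split_time_bs
#' coalescent_internal_branch(m)  # internal branch in coalescent units
#' @export
demographic_model <- function(split_time_bs = 208750,
                              split_time_r = 357500,
                              split_time_o = 506250,
                              pop_size = 150000,
                              pulse = NULL,
                              mu = 1.25e-8,
                              kappa = 2,
                              samples = c(blue = 1, sable = 1, roan = 1)) {
  branches <- c("blue", "sable", "roan", "outgroup", "bs", "bsr", "root")
  if (is.null(names(pop_size))) {
    if (length(pop_size) != 1) {
      stop("`pop_size` must be a single value or a named vector", call. = FALSE)
    }
    pop_size <- stats::setNames(rep(pop_size, length(branches)), branches)
  } else {
    missing_br <- setdiff(branches, names(pop_size))
    if (length(missing_br)) {
      stop("`pop_size` missing branches: ", paste(missing_br, collapse = ", "),
           call. = FALSE)
    }
    pop_size <- pop_size[branches]
  }
  if (!(split_time_bs > 0 && split_time_bs < split_time_r &&
        split_time_r < split_time_o)) {
    stop("split times must satisfy 0 < split_time_bs < split_time_r < split_time_o",
         call. = FALSE)
  }
  if (any(pop_size <= 0)) stop("all population sizes must be positive", call. = FALSE)
  if (mu < 0) stop("`mu` must be non-negative", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  if (is.null(names(samples)) ||
      !all(names(samples) %in% c("blue", "sable", "roan"))) {
    stop("`samples` must be named with ingroup species (blue, sable, roan)",
         call. = FALSE)
  }
  samples <- samples[intersect(c("blue", "sable", "roan"), names(samples))]
  if (any(samples < 1) || any(samples != round(samples))) {
    stop("`samples` must be positive integers", call. = FALSE)
  }
  if (!is.null(pulse)) {
    pulse <- validate_pulse(pulse, split_time_bs, split_time_r, split_time_o)
  }
  structure(
    list(split_time_bs = split_time_bs, split_time_r = split_time_r,
         split_time_o = split_time_o, pop_size = pop_size, pulse = pulse,
         mu = mu, kappa = kappa, samples = samples),
    class = "demographic_model"
  )
}

validate_pulse <- function(pulse, t_bs, t_r, t_o) {
  need <- c("donor", "recipient", "time", "proportion")
  if (!is.list(pulse) || !all(need %in% names(pulse))) {
    stop("`pulse` needs elements donor, recipient, time, proportion", call. = FALSE)
  }
  sp <- c("blue", "sable", "roan", "outgroup")
  if (!pulse$donor %in% sp || !pulse$recipient %in% sp) {
    stop("pulse donor/recipient must be species names", call. = FALSE)
  }
  if (pulse$donor == pulse$recipient) {
    stop("pulse donor and recipient must differ", call. = FALSE)
  }
  if (pulse$proportion < 0 || pulse$proportion > 1) {
    stop("pulse proportion f must be in [0, 1]", call. = FALSE)
  }
  # both named populations must still exist at the pulse: a species
  # population is absorbed into its ancestor at its own split time
  absorbed_at <- c(blue = t_bs, sable = t_bs, roan = t_r, outgroup = t_o)
  tj <- min(absorbed_at[[pulse$donor]], absorbed_at[[pulse$recipient]])
  if (pulse$time <= 0 || pulse$time >= tj) {
    stop("pulse time must lie strictly between 0 and the first split ",
         "absorbing the donor or recipient (", tj, " generations)",
         call. = FALSE)
  }
  pulse
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> (((blue, sable), roan), outgroup)\n")
  cat(sprintf("  splits (generations): bs=%g  r=%g  o=%g\n",
              x$split_time_bs, x$split_time_r, x$split_time_o))
  cat("  Ne:", paste(sprintf("%s=%g", names(x$pop_size), x$pop_size),
                     collapse = " "), "\n")
  if (is.null(x$pulse)) {
    cat("  pulse: none\n")
  } else {
    cat(sprintf("  pulse: %s -> %s at %g generations, f=%g\n",
                x$pulse$donor, x$pulse$recipient, x$pulse$time,
                x$pulse$proportion))
  }
  cat(sprintf("  mu=%g  kappa=%g  samples: %s (+1 haploid outgroup)\n",
              x$mu, x$kappa,
              paste(sprintf("%s=%d", names(x$samples), x$samples),
                    collapse = " ")))
  invisible(x)
}

#' Internal branch length of the species tree in coalescent units
#'
#' The branch between the blue+sable ancestor and the ingroup ancestor,
#' `(split_time_r - split_time_bs) / (2 * Ne_bs)`, which controls the
#' probability of gene-tree discordance by incomplete lineage sorting.
#'
#' @param model A [demographic_model()].
#' @return Length in coalescent units (dimensionless).
#' @export
coalescent_internal_branch <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  (model$split_time_r - model$split_time_bs) / (2 * model$pop_size[["bs"]])
}

#' Expected gene-tree discordance under the multispecies coalescent
#'
#' For a species quartet with internal branch `T` coalescent units, the
#' probability that the gene tree of one lineage per species is discordant
#' with the species tree is `(2/3) * exp(-T)`, split equally between the two
#' discordant resolutions.
#'
#' @param T_coal Internal branch length in coalescent units (non-negative).
#' @return Discordance probability.
#' @examples
#' expected_discordance(0)   # 2/3
#' expected_discordance(1)   # 0.2453
#' @export
expected_discordance <- function(T_coal) {
  if (any(T_coal < 0)) stop("`T_coal` must be non-negative", call. = FALSE)
  (2 / 3) * exp(-T_coal)
}

#' Ancient-DNA damage and sequencing-coverage parameters
#'
#' Parameters of the read-level observation model layered on top of true
#' diploid genotypes: Poisson-distributed depth, single-stranded-library
#' cytosine deamination decaying exponentially from both fragment ends,
#' position-independent oxidative G-to-T damage, and uniform sequencing error.
#'
#' @param delta_ss Maximum terminal C-to-T deamination probability (at
#'   fragment position 0).
#' @param lambda Per-position exponential decay rate of deamination with
#'   distance from the nearer fragment end.
#' @param delta_ox Uniform G-to-T oxidation probability per observed base.
#' @param eps Per-base sequencing error probability (error picks one of the
#'   other three bases uniformly).
#' @param coverage Mean sequencing depth; per-site depth is Poisson.
#' @param read_len Fragment length in bp; the position of each observed base
#'   is uniform on `0 .. read_len - 1`, measured from the nearer end.
#' @return An object of class `"damage_params"`.
#' @examples
#' damage_params()               # study-like defaults
#' damage_params(coverage = 0)   # produces empty base counts
#' @export
damage_params <- function(delta_ss = 0.3, lambda = 0.3, delta_ox = 0.1,
                          eps = 0.001, coverage = 3, read_len = 60) {
  probs <- c(delta_ss = delta_ss, delta_ox = delta_ox, eps = eps)
  if (any(probs < 0 | probs > 1)) {
    stop("delta_ss, delta_ox and eps must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  if (coverage < 0) stop("`coverage` must be non-negative", call. = FALSE)
  if (read_len < 1) stop("`read_len` must be at least 1", call. = FALSE)
  structure(list(delta_ss = delta_ss, lambda = lambda, delta_ox = delta_ox,
                 eps = eps, coverage = coverage, read_len = read_len),
            class = "damage_params")
}

#' @export
print.damage_params <- function(x, ...) {
  cat("<damage_params>\n")
  cat(sprintf("  deamination: delta_ss=%g lambda=%g (both fragment ends)\n",
              x$delta_ss, x$lambda))
  cat(sprintf("  oxidation: delta_ox=%g (uniform)  error: eps=%g\n",
              x$delta_ox, x$eps))
  cat(sprintf("  coverage=%g (Poisson)  read_len=%d bp\n",
              x$coverage, as.integer(x$read_len)))
  invisible(x)
}

#' No-damage, effectively complete-coverage observation parameters
#'
#' Convenience wrapper used in tests and simulation studies where the read
#' layer should be transparent.
#'
#' @param coverage Mean depth (default 30).
#' @return A [damage_params()] object with all damage and error rates zero.
#' @export
clean_params <- function(coverage = 30) {
  damage_params(delta_ss = 0, lambda = 0, delta_ox = 0, eps = 0,
                coverage = coverage, read_len = 60)
}
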