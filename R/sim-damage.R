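#' Apply the ancient-DNA damage and coverage observation model
#'
#' Turns one individual's true haplotypes into per-site base counts, the
#' read-level evidence downstream callers consume. Per site, depth is
#' Poisson(`coverage`); each observation samples one haplotype uniformly and
#' a fragment position `p` uniform on `0 .. read_len - 1` measured from the
#' nearer end; a true `C` is read as `T` with probability
#' `delta_ss * exp(-lambda * p)` (single-stranded libraries deaminate at both
#' ends), a true `G` is read as `T` with probability `delta_ox`
#' (position-independent oxidation), and finally the base is replaced by one
#' of the other three uniformly with probability `eps`.
#'
#' @param haplotypes Integer matrix (rows = haplotypes, usually 2; `1:4`
#'   coding) of one individual's true sequences. A `0` (missing) base yields
#'   no read.
#' @param params A [damage_params()].
#' @param rng_seed Optional integer seed.
#' @return Integer matrix `L x 4` of base counts, columns `A, C, G, T`,
#'   class attribute `"base_counts"`.
#' @examples
#' h <- rbind(rep(2L, 50), rep(2L, 50))  # homozygous C
#' bc <- apply_damage_and_coverage(h, damage_params(coverage = 20), rng_seed = 1)
#' colSums(bc)  # some C reads show up as T
#' @export
apply_damage_and_coverage <- function(haplotypes, params, rng_seed = NULL) {
  stopifnot(inherits(params, "damage_params"))
  if (is.null(dim(haplotypes))) haplotypes <- matrix(haplotypes, nrow = 1)
  if (nrow(haplotypes) < 1 || ncol(haplotypes) < 1) {
    stop("`haplotypes` must be a non-empty matrix", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  L <- ncol(haplotypes)
  n_hap <- nrow(haplotypes)

  depth <- stats::rpois(L, params$coverage)
  n_reads <- sum(depth)
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, PQ_BASES))
  if (n_reads > 0) {
    site <- rep.int(seq_len(L), depth)
    hap <- sample.int(n_hap, n_reads, replace = TRUE)
    base <- haplotypes[cbind(hap, site)]
    ok <- base > 0L
    site <- site[ok]; base <- base[ok]
    if (length(base)) {
      pos <- sample.int(params$read_len, length(base), replace = TRUE) - 1L
      # deamination: C -> T, strongest at fragment ends
      deam <- base == 2L &
        stats::runif(length(base)) < params$delta_ss * exp(-params$lambda * pos)
      base[deam] <- 4L
      # oxidation: G -> T, uniform along the fragment
      oxo <- base == 3L & stats::runif(length(base)) < params$delta_ox
      base[oxo] <- 4L
      # sequencing error: any base to one of the other three
      err <- stats::runif(length(base)) < params$eps
      if (any(err)) {
        shift <- sample.int(3L, sum(err), replace = TRUE)
        base[err] <- (base[err] - 1L + shift) %% 4L + 1L
      }
      tab <- tabulate((site - 1L) * 4L + base, nbins = 4L * L)
      counts <- matrix(as.integer(tab), nrow = L, ncol = 4, byrow = TRUE,
                       dimnames = list(NULL, PQ_BASES))
    }
  }
  class(counts) <- c("base_counts", class(counts))
  counts
}

#' Tidy base counts into the interchange table format
#'
#' @param counts A `base_counts` matrix (or plain `L x 4` matrix).
#' @param individual Individual identifier.
#' @param scaffold Scaffold name.
#' @param start 1-based coordinate of the first site.
#' @return Tibble with columns `scaffold`, `pos` (1-based), `individual`,
#'   `nA`, `nC`, `nG`, `nT`.
#' @export
base_counts_table <- function(counts, individual, scaffold = "scaffold_1",
                              start = 1L) {
  tibble::tibble(
    scaffold = scaffold,
    pos = start + seq_len(nrow(counts)) - 1L,
    individual = individual,
    nA = as.integer(counts[, 1]), nC = as.integer(counts[, 2]),
    nG = as.integer(counts[, 3]), nT = as.integer(counts[, 4])
  )
}
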