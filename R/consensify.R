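#' Parameters for pseudohaploid calling
#'
#' @param max_depth Sites with depth above this are masked to `N`. The
#'   convention used throughout is twice the individual's mean coverage
#'   (see [auto_max_depth()]); `Inf` disables the cap.
#' @param min_depth Sites with depth below this are masked to `N` (default 2,
#'   the Consensify rule).
#' @param sample_size Number of observations sampled without replacement at
#'   each site for the majority rule (default 3).
#' @return An object of class `"consensify_params"`.
#' @export
consensify_params <- function(max_depth = Inf, min_depth = 2, sample_size = 3) {
  if (min_depth < 1) stop("`min_depth` must be at least 1", call. = FALSE)
  if (identical(max_depth, "auto")) {
    # resolved against the data by call_genome()
  } else if (!is.numeric(max_depth) || max_depth < min_depth) {
    stop("`max_depth` must be numeric and at least `min_depth`, or \"auto\"",
         call. = FALSE)
  }
  if (sample_size < 2) stop("`sample_size` must be at least 2", call. = FALSE)
  structure(list(max_depth = max_depth, min_depth = min_depth,
                 sample_size = as.integer(sample_size)),
            class = "consensify_params")
}

#' Depth cap from the empirical mean depth
#'
#' `floor(2 * mean depth)` of the individual's base counts, the conventional
#' maxDepth for Consensify-style calling.
#'
#' @param counts `L x 4` base-count matrix.
#' @return Integer depth cap.
#' @export
auto_max_depth <- function(counts) {
  floor(2 * mean(rowSums(counts)))
}

#' Consensify-style pseudohaploid call at a single site
#'
#' Depth outside `[min_depth, max_depth]` gives `N`. Otherwise
#' `min(sample_size, depth)` observations are drawn without replacement; the
#' base observed at least twice in the draw is emitted, and `N` if the draw
#' has no majority (with the default 3-sample a majority is a base seen
#' twice; three distinct bases give `N`).
#'
#' @param counts Integer vector of length 4 (`A, C, G, T` observations).
#' @param params A [consensify_params()].
#' @param rng_seed Optional integer seed.
#' @return Single character: one of `"A","C","G","T","N"`.
#' @examples
#' call_consensify_site(c(3, 0, 0, 0), consensify_params(max_depth = 6))  # "A"
#' call_consensify_site(c(1, 1, 1, 0), consensify_params())               # "N"
#' @export
call_consensify_site <- function(counts, params = consensify_params(),
                                 rng_seed = NULL) {
  check_site_counts(counts)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  idx <- call_consensify_idx(matrix(as.integer(counts), nrow = 1), params)
  c("N", PQ_BASES)[idx + 1L]
}

#' Random-read pseudohaploid call at a single site
#'
#' Depth outside `[min_depth, max_depth]` gives `N` (with `min_depth` lowered
#' to 1 by convention for random sampling only when requested); otherwise one
#' observation is drawn uniformly and emitted.
#'
#' @inheritParams call_consensify_site
#' @return Single character base or `"N"`.
#' @examples
#' call_random_site(c(5, 0, 0, 0), consensify_params(min_depth = 1))  # "A"
#' @export
call_random_site <- function(counts, params = consensify_params(),
                             rng_seed = NULL) {
  check_site_counts(counts)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  idx <- call_random_idx(matrix(as.integer(counts), nrow = 1), params)
  c("N", PQ_BASES)[idx + 1L]
}

check_site_counts <- function(counts) {
  if (length(counts) != 4 || any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be 4 non-negative integers (A, C, G, T)",
         call. = FALSE)
  }
}

# vectorized Consensify over an L x 4 count matrix; returns 0:4 codes
call_consensify_idx <- function(counts, params) {
  depth <- rowSums(counts)
  out <- integer(nrow(counts))
  ok <- depth >= params$min_depth & depth <= params$max_depth
  if (!any(ok)) return(out)
  cnt <- counts[ok, , drop = FALSE]
  k <- pmin(params$sample_size, rowSums(cnt))
  # draw k observations per site without replacement (sequential
  # multivariate hypergeometric, vectorized across sites)
  drawn <- matrix(0L, nrow = nrow(cnt), ncol = 4)
  remaining <- cnt
  left <- rowSums(cnt)
  for (step in seq_len(max(k))) {
    active <- k >= step
    if (!any(active)) break
    u <- stats::runif(nrow(cnt)) * left
    cum1 <- remaining[, 1]
    cum2 <- cum1 + remaining[, 2]
    cum3 <- cum2 + remaining[, 3]
    pick <- 1L + (u >= cum1) + (u >= cum2) + (u >= cum3)
    sel <- which(active)
    idx <- cbind(sel, pick[sel])
    drawn[idx] <- drawn[idx] + 1L
    remaining[idx] <- remaining[idx] - 1L
    left[sel] <- left[sel] - 1L
  }
  maj <- max.col(drawn, ties.method = "first")
  has_majority <- drawn[cbind(seq_len(nrow(drawn)), maj)] >= 2L
  out[ok] <- ifelse(has_majority, maj, 0L)
  out
}

# vectorized random-read sampling; returns 0:4 codes
call_random_idx <- function(counts, params) {
  depth <- rowSums(counts)
  out <- integer(nrow(counts))
  ok <- depth >= params$min_depth & depth <= params$max_depth
  if (!any(ok)) return(out)
  cnt <- counts[ok, , drop = FALSE]
  u <- stats::runif(nrow(cnt)) * rowSums(cnt)
  cum1 <- cnt[, 1]
  cum2 <- cum1 + cnt[, 2]
  cum3 <- cum2 + cnt[, 3]
  out[ok] <- 1L + (u >= cum1) + (u >= cum2) + (u >= cum3)
  out
}

#' Call a pseudohaploid genome from per-scaffold base counts
#'
#' Site-wise application of [call_consensify_site()] or [call_random_site()]
#' over whole scaffolds, producing one sequence over `A, C, G, T, N` per
#' scaffold.
#'
#' @param base_counts Named list: scaffold -> `L x 4` base-count matrix.
#' @param mode `"consensify"` or `"random"`.
#' @param params A [consensify_params()]; `max_depth = "auto"` is resolved to
#'   [auto_max_depth()] over all scaffolds of the individual.
#' @param rng_seed Integer seed (calling is stochastic).
#' @param individual Identifier stored in the result.
#' @return Object of class `"pseudohaploid_genome"`: list with `individual`,
#'   `sequences` (named character vector, one string per scaffold), `mode`,
#'   `seed`.
#' @export
call_genome <- function(base_counts, mode = c("consensify", "random"),
                        params = consensify_params(), rng_seed = 1,
                        individual = "sample") {
  mode <- match.arg(mode)
  if (!is.list(base_counts) || is.null(names(base_counts))) {
    stop("`base_counts` must be a named list of scaffold count matrices",
         call. = FALSE)
  }
  if (identical(params$max_depth, "auto")) {
    params$max_depth <- auto_max_depth(do.call(rbind, base_counts))
  }
  set.seed(rng_seed)
  seqs <- vapply(base_counts, function(cnt) {
    idx <- if (mode == "consensify") call_consensify_idx(cnt, params)
           else call_random_idx(cnt, params)
    decode_bases(idx, collapse = TRUE)
  }, character(1))
  structure(list(individual = individual, sequences = seqs, mode = mode,
                 seed = rng_seed),
            class = "pseudohaploid_genome")
}

#' @export
print.pseudohaploid_genome <- function(x, ...) {
  cat("<pseudohaploid_genome>", x$individual, "-", length(x$sequences),
      "scaffold(s),", sum(nchar(x$sequences)), "bp, mode", x$mode, "\n")
  invisible(x)
}

#' Pseudohaploidize true haplotypes directly
#'
#' The high-coverage, damage-free limit of random-read calling: at every
#' site one of the individual's true alleles is chosen uniformly. Used in
#' simulation studies where the read layer is not under test.
#'
#' @param haplotypes Integer matrix of the individual's haplotypes
#'   (rows = 1 or 2).
#' @return Integer vector (`1:4`) of length `ncol(haplotypes)`.
#' @export
pseudohaploid_from_truth <- function(haplotypes) {
  if (is.null(dim(haplotypes))) return(as.integer(haplotypes))
  if (nrow(haplotypes) == 1) return(as.integer(haplotypes[1, ]))
  pick <- stats::runif(ncol(haplotypes)) < 0.5
  out <- haplotypes[1, ]
  out[!pick] <- haplotypes[2, !pick]
  as.integer(out)
}
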