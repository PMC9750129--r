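#' Roan-sable path length as a proportion of tree length
#'
#' Sum of branch lengths on the unique path between the roan and sable tips,
#' divided by the total tree length. With two roan individuals the first (by
#' tip-label order) is used.
#'
#' @param tree An [ape::as.phylo] tree with branch lengths.
#' @param taxonA,taxonB Tip labels or role prefixes (defaults `"roan"` and
#'   `"sable"`).
#' @return Proportion in `(0, 1]`.
#' @examples
#' tr <- ape::read.tree(
#'   text = "((roan:0.1,outgroup:0.1):0.1,(blue:0.1,sable:0.1):0.0):0;")
#' path_distance_proportion(tr)  # 0.3 / 0.5 = 0.6
#' @export
path_distance_proportion <- function(tree, taxonA = "roan",
                                     taxonB = "sable") {
  tipA <- match_tip(tree, taxonA)
  tipB <- match_tip(tree, taxonB)
  total <- sum(tree$edge.length)
  if (!isTRUE(total > 0)) stop("tree length is zero", call. = FALSE)
  d <- ape::cophenetic.phylo(tree)[tipA, tipB]
  d / total
}

match_tip <- function(tree, taxon) {
  if (taxon %in% tree$tip.label) return(taxon)
  hits <- sort(tree$tip.label[startsWith(tree$tip.label, taxon)])
  if (!length(hits)) stop("taxon not in tree: ", taxon, call. = FALSE)
  hits[1]
}

#' Configuration of the direction test
#'
#' @param lo Minimum retained roan-sable distance proportion (default
#'   0.0002). Bounds are inclusive: only values strictly below `lo` or
#'   strictly above `hi` are dropped.
#' @param hi Maximum retained proportion (default 0.9).
#' @param min_windows Minimum windows per topology class after filtering
#'   (default 30); below it the call is `"indeterminate"`.
#' @param alpha Significance level of the permutation median test and the
#'   unimodality test (default 0.01).
#' @param n_perm Permutations / Monte-Carlo draws (default 2000).
#' @return Object of class `"direction_config"`.
#' @export
direction_config <- function(lo = 0.0002, hi = 0.9, min_windows = 30,
                             alpha = 0.01, n_perm = 2000) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  }
  structure(list(lo = lo, hi = hi, min_windows = as.integer(min_windows),
                 alpha = alpha, n_perm = as.integer(n_perm)),
            class = "direction_config")
}

#' Filter extreme distance proportions
#'
#' Drops values strictly below `lo` or strictly above `hi` (boundary values
#' are retained); such extremes reflect windows with negligible information.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param config A [direction_config()].
#' @return The retained values.
#' @examples
#' filter_distances(c(0.0001, 0.5, 0.95))  # 0.5
#' @export
filter_distances <- function(values, config = direction_config()) {
  values[!is.na(values) & values >= config$lo & values <= config$hi]
}

#' Dip-style departure from unimodality
#'
#' Sup-norm distance from the empirical CDF to its best unimodal fit,
#' computed by minimizing over candidate modes the larger of the deviations
#' from the greatest convex minorant (left of the mode) and the least
#' concave majorant (right of the mode), halved. Zero-adjacent values
#' indicate a unimodal sample; well-separated equal modes approach 0.25.
#' Calibration is by Monte Carlo against uniform samples of the same size
#' ([dip_test()]), so the statistic is its own null reference.
#'
#' @param x Numeric sample (n >= 4).
#' @return The statistic (non-negative scalar).
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  # collapse ties: the empirical CDF at unique jump point j rises from
  # flo[j] to fhi[j]
  xs <- unique(x)
  cnt <- tabulate(match(x, xs))
  fhi <- cumsum(cnt) / n
  flo <- fhi - cnt / n
  k <- length(xs)
  # a unimodal CDF is convex left of the mode and concave right of it; for
  # each candidate mode, the minimal sup-norm error of a convex fit to the
  # step band [flo, fhi] is half the largest gap between fhi and the
  # greatest convex minorant of flo (and symmetrically on the right)
  best <- Inf
  for (m in seq_len(k)) {
    dl <- gap_convex(xs[1:m], flo[1:m], fhi[1:m])
    dr <- gap_concave(xs[m:k], flo[m:k], fhi[m:k])
    best <- min(best, max(dl, dr))
    if (best == 0) break
  }
  best / 2
}

# largest amount by which the upper CDF envelope exceeds the greatest
# convex minorant of the lower envelope at the jump points
gap_convex <- function(x, flo, fhi) {
  if (length(x) == 1) return(fhi - flo)
  hull <- lower_hull(x, flo)
  fit <- stats::approx(x[hull], flo[hull], xout = x)$y
  max(fhi - fit)
}

# symmetric: lower envelope vs least concave majorant of the upper one
gap_concave <- function(x, flo, fhi) {
  if (length(x) == 1) return(fhi - flo)
  hull <- upper_hull(x, fhi)
  fit <- stats::approx(x[hull], fhi[hull], xout = x)$y
  max(fit - flo)
}

# indices of the lower convex hull of (x, y), x sorted strictly increasing
lower_hull <- function(x, y) {
  n <- length(x)
  keep <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- keep[top - 1L]; b <- keep[top]
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a])) {
        top <- top - 1L
      } else break
    }
    top <- top + 1L
    keep[top] <- i
  }
  keep[seq_len(top)]
}

upper_hull <- function(x, y) {
  n <- length(x)
  keep <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- keep[top - 1L]; b <- keep[top]
      if ((y[b] - y[a]) * (x[i] - x[a]) <= (y[i] - y[a]) * (x[b] - x[a])) {
        top <- top - 1L
      } else break
    }
    top <- top + 1L
    keep[top] <- i
  }
  keep[seq_len(top)]
}

#' Monte-Carlo dip test of unimodality
#'
#' @param x Numeric sample.
#' @param n_mc Monte-Carlo replicates from the uniform null.
#' @param rng_seed Integer seed.
#' @return List with `statistic` and `p.value` (fraction of uniform samples
#'   with a statistic at least as large).
#' @export
dip_test <- function(x, n_mc = 500, rng_seed = 1) {
  stat <- dip_statistic(x)
  n <- sum(is.finite(x))
  key <- paste(n, n_mc, rng_seed, sep = "_")
  null <- pq_dip_null_cache[[key]]
  if (is.null(null)) {
    set.seed(rng_seed)
    null <- vapply(seq_len(n_mc),
                   function(i) dip_statistic(stats::runif(n)), numeric(1))
    pq_dip_null_cache[[key]] <- null
  }
  list(statistic = stat, p.value = (1 + sum(null >= stat)) / (n_mc + 1))
}

# null distributions depend only on (n, n_mc, seed); cache within a session
pq_dip_null_cache <- new.env(parent = emptyenv())

#' Direction of gene flow from branch-length distributions
#'
#' Compares the roan-sable path-length proportions of windows whose tree
#' matches the species topology (class BS) against windows where blue and
#' roan are sisters (class BR). Gene flow from roan into blue leaves the
#' roan-sable distance untouched in both classes (equal medians, unimodal
#' BR distribution); gene flow from blue into roan pulls roan ancestry
#' toward the blue-sable divergence in introgressed windows, producing a
#' shorter mode in the BR class.
#'
#' Decision rule (all tests at `config$alpha`): `blue_to_roan` when the BR
#' distribution is significantly bimodal (dip test), or its median is
#' significantly smaller than the BS median (one-sided permutation test:
#' only a shorter roan-sable distance is evidence for introgressed roan
#' ancestry, since conditioning on the discordant topology under pure
#' lineage sorting can only deepen it); `roan_to_blue` when both tests are
#' non-significant; `indeterminate` when either class has fewer than
#' `min_windows` windows after filtering.
#'
#' @param class_bs,class_br Numeric vectors of roan-sable path proportions
#'   for the two window classes (unfiltered; [filter_distances()] is applied
#'   internally).
#' @param config A [direction_config()].
#' @param rng_seed Integer seed (permutations and Monte Carlo are seeded).
#' @return Object of class `"direction_result"`: list with
#'   `direction_call`, `median_bs`, `median_br`, `p_median`, `p_dip`,
#'   `n_bs`, `n_br` and the retained samples.
#' @export
direction_test <- function(class_bs, class_br, config = direction_config(),
                           rng_seed = 1) {
  bs <- filter_distances(class_bs, config)
  br <- filter_distances(class_br, config)
  res <- list(n_bs = length(bs), n_br = length(br),
              median_bs = stats::median(bs), median_br = stats::median(br),
              p_median = NA_real_, p_dip = NA_real_,
              direction_call = "indeterminate",
              samples = list(BS = bs, BR = br), config = config)
  if (length(bs) < config$min_windows || length(br) < config$min_windows) {
    class(res) <- "direction_result"
    return(res)
  }
  set.seed(rng_seed)
  res$p_median <- permutation_median_test(bs, br, config$n_perm)
  dip <- dip_test(br, n_mc = min(config$n_perm, 500),
                  rng_seed = rng_seed + 1L)
  res$p_dip <- dip$p.value
  median_sig <- res$p_median <= config$alpha
  dip_sig <- res$p_dip <= config$alpha
  res$direction_call <- if (median_sig || dip_sig) {
    "blue_to_roan"
  } else {
    "roan_to_blue"
  }
  class(res) <- "direction_result"
  res
}

# one-sided: only a SHORTER roan-sable distance in the discordant class is
# evidence (a deeper one is the expected by-product of conditioning on the
# blue+roan topology under pure lineage sorting)
permutation_median_test <- function(a, b, n_perm) {
  obs <- stats::median(a) - stats::median(b)
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (stats::median(pool[idx]) - stats::median(pool[-idx]) >= obs) {
      hits <- hits + 1L
    }
  }
  (1 + hits) / (n_perm + 1)
}

#' @export
print.direction_result <- function(x, ...) {
  cat("<direction_result>\n")
  cat(sprintf("  windows: BS=%d BR=%d (after filtering)\n", x$n_bs, x$n_br))
  cat(sprintf("  medians: BS=%.4g BR=%.4g  p_median=%.3g  p_dip=%.3g\n",
              x$median_bs, x$median_br, x$p_median, x$p_dip))
  cat("  call:", x$direction_call, "\n")
  invisible(x)
}

#' Tidy a direction-test result
#'
#' @param x A `"direction_result"`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy direction_result
#' @export
tidy.direction_result <- function(x, ...) {
  tibble::tibble(direction_call = x$direction_call, n_bs = x$n_bs,
                 n_br = x$n_br, median_bs = x$median_bs,
                 median_br = x$median_br, p_median = x$p_median,
                 p_dip = x$p_dip)
}

#' Histogram of roan-sable path proportions by topology class
#'
#' @param object A `"direction_result"`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot faceted by window class.
#' @method autoplot direction_result
#' @export
autoplot.direction_result <- function(object, bins = 40, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(class = "BS (species tree)", value = object$samples$BS),
    tibble::tibble(class = "BR (blue + roan)", value = object$samples$BR)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~class, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "roan-sable path length / tree length",
                  y = "windows",
                  subtitle = paste("call:", object$direction_call)) +
    ggplot2::theme_minimal()
}

#' Timing of roan-blue gene flow relative to the roan radiation
#'
#' With two roan individuals, one blue and an outgroup, each window tree in
#' which blue groups with roan is classified by whether blue attaches
#' outside the roan pair (gene flow before the roan MRCA) or inside it
#' (after the roan MRCA).
#'
#' @param records Window-record tibble from [window_trees()] on a 5-taxon
#'   cohort (needs `topology_class`), or a character vector of classes.
#' @return Tibble with `category` in `blue_sister_to_roan_clade`,
#'   `blue_nested_in_roan`, `other`, with counts and fractions over all
#'   classified windows.
#' @export
timing_classification <- function(records) {
  cls <- if (is.character(records)) records else records$topology_class
  if (!length(cls)) stop("no records", call. = FALSE)
  cat_of <- function(cl) {
    switch(cl, BR = "blue_sister_to_roan_clade",
           BR_nested = "blue_nested_in_roan", "other")
  }
  cats <- vapply(cls, cat_of, character(1))
  levels <- c("blue_sister_to_roan_clade", "blue_nested_in_roan", "other")
  counts <- table(factor(cats, levels = levels))
  tibble::tibble(category = names(counts), n = as.integer(counts),
                 fraction = as.numeric(counts) / length(cats))
}
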