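#' Damage-aware pairwise differences between two pseudohaploid genomes
#'
#' Counts, over a jointly filtered site set, the sites at which the two
#' individuals carry a clean transversion difference (`A/T` or `C/G`) -- the
#' only difference classes that neither cytosine deamination (transitions)
#' nor oxidative damage (`G/T`, `C/A`) can produce. The count is normalized
#' by the shared number of filtered sites so that values are comparable
#' across pairs and species.
#'
#' @param a,b Row names (individual ids) into `filtered`, or two equal
#'   length sequences when `filtered` is `NULL`.
#' @param filtered A filtered [site_matrix()] (from [filter_sites()],
#'   applied jointly across the whole cohort).
#' @return Tibble row: `ind_a`, `ind_b`, `n_clean_differences`,
#'   `n_filtered_sites`, `normalized`.
#' @examples
#' m <- filter_sites(site_matrix(rbind(a = c("A","G","T"),
#'                                     b = c("T","G","T"),
#'                                     c = c("A","A","T"))))$matrix
#' pairwise_clean_differences("a", "b", m)
#' @export
pairwise_clean_differences <- function(a, b, filtered = NULL) {
  if (is.null(filtered)) {
    ia <- as_int_seq(a); ib <- as_int_seq(b)
    if (length(ia) != length(ib)) stop("length mismatch", call. = FALSE)
    n_sites <- length(ia)
    ids <- c("a", "b")
  } else {
    ids <- c(a, b)
    if (!all(ids %in% rownames(filtered))) {
      stop("individuals not found in the filtered matrix", call. = FALSE)
    }
    ia <- filtered[a, ]; ib <- filtered[b, ]
    n_sites <- ncol(filtered)
  }
  if (n_sites == 0) stop("zero filtered sites", call. = FALSE)
  cls <- classify_substitution_idx(ia, ib)
  n_clean <- sum(cls == "clean_transversion")
  tibble::tibble(ind_a = ids[1], ind_b = ids[2],
                 n_clean_differences = n_clean,
                 n_filtered_sites = n_sites,
                 normalized = n_clean / n_sites)
}

#' Substitution spectrum between two sequences
#'
#' Counts of differing comparable sites by unordered substitution type.
#' Elevated `C/T` and `G/T` fractions are the signature of deamination and
#' oxidative damage respectively.
#'
#' @param a,b Equal-length sequences.
#' @return Tibble with `type` (`C/T`, `A/G`, `G/T`, `C/A`, `A/T`, `C/G`),
#'   `class` (substitution class), `n` and `frequency` (over differing
#'   comparable sites; zero row sums give `NaN` frequencies).
#' @export
substitution_spectrum <- function(a, b) {
  ia <- as_int_seq(a); ib <- as_int_seq(b)
  if (length(ia) != length(ib)) stop("length mismatch", call. = FALSE)
  ok <- ia > 0L & ib > 0L & ia != ib
  lo <- pmin(ia[ok], ib[ok]); hi <- pmax(ia[ok], ib[ok])
  pair_code <- paste(PQ_BASES[lo], PQ_BASES[hi], sep = "/")
  types <- c("C/T", "A/G", "G/T", "A/C", "A/T", "C/G")
  counts <- table(factor(pair_code, levels = types))
  cls <- c("transition", "transition", "damage_like", "damage_like",
           "clean_transversion", "clean_transversion")
  n_tot <- sum(counts)
  tibble::tibble(type = types, class = cls, n = as.integer(counts),
                 frequency = as.integer(counts) / n_tot)
}

#' Species-wide pairwise-difference diversity table
#'
#' Applies the joint missing/uninformative site filter across the whole
#' cohort once, then computes the normalized clean-transversion difference
#' for every within-species pair, so that all pairs share a single
#' denominator.
#'
#' @param genomes Named list of genomes (individual -> scaffold sequences or
#'   [call_genome()] objects).
#' @param species_map Named character vector: individual -> species. By
#'   default species are taken from the leading letters of the individual
#'   ids.
#' @param include_in_filter Individuals used for the joint site filter
#'   (default: all of `genomes`, including any outgroup).
#' @return Object of class `"diversity_result"`: list with `pairs` (tibble
#'   of pairwise rows plus `species`), `species_means` (tibble), and
#'   `n_filtered_sites`.
#' @export
diversity_table <- function(genomes, species_map = NULL,
                            include_in_filter = names(genomes)) {
  seqsets <- lapply(genomes, genome_sequences)
  ids <- names(seqsets)
  if (is.null(species_map)) {
    species_map <- stats::setNames(sub("[0-9_].*$", "", ids), ids)
  }
  scaffolds <- names(seqsets[[1]])
  mats <- lapply(scaffolds, function(sc) {
    m <- do.call(rbind, lapply(seqsets[include_in_filter],
                               function(s) encode_bases(s[[sc]])))
    rownames(m) <- include_in_filter
    filter_sites(site_matrix(m, scaffold = sc))$matrix
  })
  filtered <- do.call(cbind, lapply(mats, unclass))
  rownames(filtered) <- include_in_filter
  n_sites <- ncol(filtered)
  if (n_sites == 0) stop("zero filtered sites", call. = FALSE)

  species <- split(ids, species_map[ids])
  rows <- list()
  for (sp in names(species)) {
    inds <- intersect(species[[sp]], include_in_filter)
    if (length(inds) < 2) {
      if (length(species[[sp]]) >= 1 && sp != "outgroup") {
        warning("species ", sp, " has < 2 individuals; skipped")
      }
      next
    }
    for (i in seq_len(length(inds) - 1)) {
      for (j in (i + 1):length(inds)) {
        cls <- classify_substitution_idx(filtered[inds[i], ],
                                         filtered[inds[j], ])
        n_clean <- sum(cls == "clean_transversion")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species = sp, ind_a = inds[i], ind_b = inds[j],
          n_clean_differences = n_clean, n_filtered_sites = n_sites,
          normalized = n_clean / n_sites
        )
      }
    }
  }
  if (!length(rows)) stop("no species with >= 2 individuals", call. = FALSE)
  pairs <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(dplyr::group_by(pairs, .data$species),
                            mean_normalized = mean(.data$normalized),
                            n_pairs = dplyr::n(), .groups = "drop")
  structure(list(pairs = pairs, species_means = means,
                 n_filtered_sites = n_sites),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result>", nrow(x$pairs), "pairs over",
      x$n_filtered_sites, "jointly filtered sites\n")
  print(x$species_means)
  invisible(x)
}

#' Tidy a diversity result
#'
#' @param x A `"diversity_result"`.
#' @param ... Unused.
#' @return The long pair table (one row per within-species pair).
#' @method tidy diversity_result
#' @export
tidy.diversity_result <- function(x, ...) x$pairs

#' @rdname tidy.diversity_result
#' @method glance diversity_result
#' @export
glance.diversity_result <- function(x, ...) {
  tidyr::pivot_wider(x$species_means[, c("species", "mean_normalized")],
                     names_from = "species", values_from = "mean_normalized")
}

#' Dot plot of pairwise diversity by species
#'
#' @param object A `"diversity_result"`.
#' @param ... Unused.
#' @return A ggplot: one dot per pair, crossbar at the species mean.
#' @method autoplot diversity_result
#' @export
autoplot.diversity_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$species, y = .data$normalized)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7, colour = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.35,
                          linewidth = 0.4, colour = "black") +
    ggplot2::labs(x = NULL,
                  y = "clean transversion differences / filtered sites") +
    ggplot2::theme_minimal()
}

#' True per-site heterozygosity from simulation truth
#'
#' Fraction of sites at which an individual's two true haplotypes differ.
#' Only available for simulated data, where it serves as the oracle against
#' which the pairwise-difference diversity statistic is validated.
#'
#' @param truth A `"truth_bundle"` from [simulate_cohort()].
#' @param individual Individual id (e.g. `"blue1"`).
#' @return Heterozygosity (proportion of sites).
#' @export
true_heterozygosity <- function(truth, individual) {
  if (!inherits(truth, "truth_bundle")) {
    stop("true heterozygosity requires simulation truth", call. = FALSE)
  }
  h1 <- paste0(individual, "_1")
  h2 <- paste0(individual, "_2")
  n_diff <- 0
  n_tot <- 0
  for (w in truth$windows) {
    g <- w$genotypes
    if (!all(c(h1, h2) %in% rownames(g))) {
      stop("individual not in truth bundle: ", individual, call. = FALSE)
    }
    n_diff <- n_diff + sum(g[h1, ] != g[h2, ])
    n_tot <- n_tot + ncol(g)
  }
  n_diff / n_tot
}
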