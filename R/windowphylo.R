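#' Sliding-window configuration
#'
#' Non-overlapping windows of `window_size` bp separated by `gap` bp,
#' tiling each scaffold from position 1 (stride `window_size + gap`).
#' Windows in which any taxon exceeds the missing-data threshold are
#' discarded, as are partial terminal windows.
#'
#' @param window_size Window width in bp (default 20000).
#' @param gap Gap between consecutive windows in bp (default 80000).
#' @param missing_threshold Maximum per-taxon fraction of `N` within a
#'   window (default 0.5).
#' @param mode `"ry_binary"` (transversions-only distances; default) or
#'   `"nucleotide"` (raw p-distances).
#' @param tol Internal branch lengths at or below this are classified
#'   `"other"` (default 0: a strictly positive internal branch is required).
#' @return Object of class `"window_config"`.
#' @export
window_config <- function(window_size = 20000, gap = 80000,
                          missing_threshold = 0.5,
                          mode = c("ry_binary", "nucleotide"), tol = 0) {
  mode <- match.arg(mode)
  if (window_size < 1) stop("`window_size` must be >= 1", call. = FALSE)
  if (gap < 0) stop("`gap` must be >= 0", call. = FALSE)
  if (missing_threshold < 0 || missing_threshold > 1) {
    stop("`missing_threshold` must be in [0, 1]", call. = FALSE)
  }
  structure(list(window_size = as.integer(window_size), gap = as.integer(gap),
                 missing_threshold = missing_threshold, mode = mode,
                 tol = tol),
            class = "window_config")
}

#' Extract sliding-window alignments from a set of genomes
#'
#' @param genomes Named list: individual -> named character vector of
#'   scaffold sequences (or [call_genome()] objects). All genomes must share
#'   scaffold names and lengths.
#' @param config A [window_config()].
#' @return Tibble with columns `scaffold`, `start`, `end` (1-based
#'   inclusive) and `sites` (list column of [site_matrix()] objects,
#'   individuals x window sites).
#' @examples
#' g <- list(a = c(s = "ACGTACGTAC"), b = c(s = "ACGTACGTAC"))
#' extract_windows(g, window_config(window_size = 4, gap = 2))
#' @export
extract_windows <- function(genomes, config = window_config()) {
  seqsets <- lapply(genomes, genome_sequences)
  if (is.null(names(seqsets))) {
    stop("`genomes` must be a named list of individuals", call. = FALSE)
  }
  scaffolds <- names(seqsets[[1]])
  if (length(scaffolds) == 0) stop("no scaffolds", call. = FALSE)
  for (s in seqsets) {
    if (!identical(names(s), scaffolds) ||
        !identical(nchar(s), nchar(seqsets[[1]]))) {
      stop("genomes must share scaffold names and lengths", call. = FALSE)
    }
  }
  stride <- config$window_size + config$gap
  rows <- list()
  for (sc in scaffolds) {
    L <- nchar(seqsets[[1]][[sc]])
    if (L < config$window_size) next
    starts <- seq(1L, L - config$window_size + 1L, by = stride)
    mat_full <- encode_matrix(do.call(
      rbind, lapply(seqsets, function(s) strsplit(s[[sc]], "")[[1]])
    ))
    rownames(mat_full) <- names(seqsets)
    for (st in starts) {
      en <- st + config$window_size - 1L
      sub <- mat_full[, st:en, drop = FALSE]
      n_frac <- rowMeans(sub == 0L)
      if (any(n_frac > config$missing_threshold)) next
      sm <- structure(sub, scaffold = sc, pos = st:en,
                      class = c("site_matrix", class(sub)))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(scaffold = sc, start = st, end = en, sites = list(sm))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(scaffold = character(), start = integer(),
                          end = integer(), sites = list()))
  }
  dplyr::bind_rows(rows)
}

#' Transversion (RY) distance between two aligned sequences
#'
#' Pairwise-deletion proportion of sites whose purine/pyrimidine (RY) codes
#' differ; transition differences contribute nothing.
#'
#' @param a,b Equal-length sequences (strings, character vectors, or `0:4`
#'   integer vectors).
#' @return List with `distance` (fraction in `[0, 1]`, `NaN` when no sites
#'   are comparable) and `n_comparable`.
#' @examples
#' transversion_distance("ACGT", "GTAC")$distance  # 0: all transitions
#' transversion_distance("AAAA", "TTTT")$distance  # 1
#' @export
transversion_distance <- function(a, b) {
  ia <- as_int_seq(a); ib <- as_int_seq(b)
  if (length(ia) != length(ib)) stop("length mismatch", call. = FALSE)
  ok <- ia > 0L & ib > 0L
  n <- sum(ok)
  # purine = codes 1, 3 (A, G); pyrimidine = 2, 4 (C, T)
  ry <- function(x) x %% 2L
  d <- if (n > 0) mean(ry(ia[ok]) != ry(ib[ok])) else NaN
  list(distance = d, n_comparable = n)
}

# distance matrix over the rows of a site_matrix
window_distance_matrix <- function(sm, mode = "ry_binary") {
  n <- nrow(sm)
  labs <- rownames(sm)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  ncomp <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ia <- sm[i, ]; ib <- sm[j, ]
      ok <- ia > 0L & ib > 0L
      m <- sum(ok)
      if (m == 0) { D[i, j] <- D[j, i] <- NaN; next }
      d <- if (mode == "ry_binary") {
        mean((ia[ok] %% 2L) != (ib[ok] %% 2L))
      } else {
        mean(ia[ok] != ib[ok])
      }
      D[i, j] <- D[j, i] <- d
      ncomp[i, j] <- ncomp[j, i] <- m
    }
  }
  attr(D, "n_comparable") <- ncomp
  D
}

#' Classify the rooted topology of a window tree
#'
#' Roots the tree at the outgroup and reports which ingroup pair is sister:
#' `"BS"` (blue + sable, the species-tree resolution), `"BR"` (blue + roan)
#' or `"RS"` (roan + sable); `"other"` when the supporting internal branch
#' is at or below `tol` or taxa are missing. With two roan individuals the
#' sister group of blue decides: the whole roan clade gives `"BR"`, a single
#' roan (blue nested inside the roan clade) gives `"BR_nested"`.
#'
#' @param tree An [ape::as.phylo] tree (unrooted or rooted).
#' @param labels Named character vector mapping roles `blue`, `sable`,
#'   `roan` (one or more tips may share the role prefix) to tip labels; by
#'   default tips are matched by their name prefixes `blue`, `sable`,
#'   `roan`, `outgroup`.
#' @param outgroup Outgroup tip label (default the tip whose label starts
#'   with `"outgroup"` or `"oryx"`).
#' @param tol Minimum internal branch length supporting the sister pair.
#' @return One of `"BS"`, `"BR"`, `"RS"`, `"BR_nested"`, `"other"`.
#' @examples
#' tr <- ape::read.tree(text = "((blue:1,sable:1):1,(roan:1,outgroup:1):1);")
#' classify_topology(tr)  # "BS"
#' @export
classify_topology <- function(tree, labels = NULL, outgroup = NULL, tol = 0) {
  tips <- tree$tip.label
  role <- role_of_tips(tips, labels)
  if (is.null(outgroup)) outgroup <- tips[role == "outgroup"][1]
  if (is.na(outgroup) || !outgroup %in% tips) {
    stop("outgroup tip not found in tree", call. = FALSE)
  }
  for (r in c("blue", "sable", "roan")) {
    if (!any(role == r)) return("other")
  }
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  blue_tip <- tips[role == "blue"][1]
  bi <- match(blue_tip, rt$tip.label)
  parent <- rt$edge[match(bi, rt$edge[, 2]), 1]
  sister_tips <- setdiff(tips_under(rt, parent), blue_tip)
  sister_roles <- unique(role[match(sister_tips, tips)])
  n_roan <- sum(role == "roan")
  out <- if (identical(sister_roles, "sable") &&
             length(sister_tips) == sum(role == "sable")) {
    "BS"
  } else if (identical(sister_roles, "roan")) {
    if (length(sister_tips) == n_roan) "BR"
    else if (n_roan > 1) "BR_nested"
    else "other"
  } else if (setequal(sister_roles, c("roan", "sable")) && n_roan == 1 &&
             length(sister_tips) == 2) {
    # blue outside the (roan, sable) cherry => roan and sable are sisters
    "RS"
  } else {
    "other"
  }
  if (out == "other") return(out)
  # support = length of the branch inducing the class-defining split,
  # measured on the tree as given (rooting redistributes edge lengths)
  group <- if (out == "RS") sister_tips else c(blue_tip, sister_tips)
  support <- split_support(tree, group)
  if (support <= tol) "other" else out
}

# length of the edge whose removal separates `group` from the other tips;
# Inf when the split is only induced at the (arbitrary) root
split_support <- function(tree, group) {
  for (side in list(group, setdiff(tree$tip.label, group))) {
    nd <- if (length(side) == 1) match(side, tree$tip.label)
          else ape::getMRCA(tree, side)
    if (is.null(nd) || is.na(nd)) next
    if (!setequal(tips_under(tree, nd), side)) next
    len <- tree$edge.length[match(nd, tree$edge[, 2])]
    if (length(len) == 1 && !is.na(len)) return(len)
  }
  Inf
}

role_of_tips <- function(tips, labels = NULL) {
  if (!is.null(labels)) {
    role <- rep(NA_character_, length(tips))
    for (r in names(labels)) role[tips %in% labels[[r]]] <- r
    role[is.na(role)] <- "outgroup"
    return(role)
  }
  role <- rep(NA_character_, length(tips))
  role[startsWith(tips, "blue")] <- "blue"
  role[startsWith(tips, "sable")] <- "sable"
  role[startsWith(tips, "roan")] <- "roan"
  role[startsWith(tips, "outgroup") | startsWith(tips, "oryx")] <- "outgroup"
  if (anyNA(role)) {
    stop("cannot infer taxon roles from tip labels; pass `labels`",
         call. = FALSE)
  }
  role
}

tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

#' Build window trees and topology records for a cohort
#'
#' The window-tree stage: extracts windows, computes transversion
#' p-distances with pairwise deletion, builds a neighbor-joining tree per
#' window, classifies its rooted topology and measures the roan-sable path
#' length as a proportion of the tree length.
#'
#' @param genomes Named list of genomes (see [extract_windows()]); names
#'   must start with the species role (`blue1`, `sable1`, `roan1`,
#'   `outgroup`, ...).
#' @param config A [window_config()].
#' @return Tibble of window-tree records: `scaffold`, `start`, `end`,
#'   `n_sites_used`, `newick`, `topology_class`, `tree_length`,
#'   `rs_path_proportion`.
#' @export
window_trees <- function(genomes, config = window_config()) {
  wins <- extract_windows(genomes, config)
  if (nrow(wins) == 0) return(empty_window_records())
  recs <- lapply(seq_len(nrow(wins)), function(i) {
    window_tree_record(wins$sites[[i]], config,
                       scaffold = wins$scaffold[i], start = wins$start[i],
                       end = wins$end[i])
  })
  dplyr::bind_rows(recs)
}

empty_window_records <- function() {
  tibble::tibble(scaffold = character(), start = integer(), end = integer(),
                 n_sites_used = integer(), newick = character(),
                 topology_class = character(), tree_length = numeric(),
                 rs_path_proportion = numeric())
}

window_tree_record <- function(sm, config, scaffold = "scaffold_1",
                               start = 1L, end = ncol(sm)) {
  D <- window_distance_matrix(sm, mode = config$mode)
  n_used <- min(attr(D, "n_comparable")[upper.tri(D)])
  rec <- tibble::tibble(scaffold = scaffold, start = as.integer(start),
                        end = as.integer(end),
                        n_sites_used = as.integer(n_used),
                        newick = NA_character_,
                        topology_class = "other",
                        tree_length = NA_real_,
                        rs_path_proportion = NA_real_)
  if (any(!is.finite(D))) return(rec)
  tr <- nj_tree(D)
  rec$newick <- ape::write.tree(tr)
  rec$topology_class <- classify_topology(tr, tol = config$tol)
  rec$tree_length <- sum(tr$edge.length)
  if (rec$tree_length > 0) {
    rec$rs_path_proportion <- path_distance_proportion(tr)
  }
  rec
}

#' Topology proportions over classified windows (gene concordance factors)
#'
#' @param records Window-record tibble from [window_trees()] (needs a
#'   `topology_class` column), or a character vector of classes.
#' @return Tibble with `topology_class`, `n` and `proportion` over the
#'   classes `BS`, `BR`, `RS`, `BR_nested` (when present) and `other`;
#'   proportions sum to 1.
#' @export
topology_summary <- function(records) {
  cls <- if (is.character(records)) records else records$topology_class
  if (length(cls) == 0) stop("no window records", call. = FALSE)
  levels <- c("BS", "BR", "RS",
              if (any(cls == "BR_nested")) "BR_nested", "other")
  counts <- table(factor(cls, levels = levels))
  tibble::tibble(topology_class = names(counts), n = as.integer(counts),
                 proportion = as.numeric(counts) / length(cls))
}

#' Site-concordance factor for the quartet
#'
#' Over biallelic transversion sites with a 2+2 pattern (`xxyy`, `xyxy` or
#' `xyyx` across the four taxa), the fraction supporting the species-tree
#' pairing.
#'
#' @param matrix A [site_matrix()] with exactly 4 rows, in the order used
#'   for the pairing (rownames carry the taxa).
#' @param species_pair Character vector of the two taxa forming the
#'   species-tree sister pair (default the `blue`/`sable` prefixed rows).
#' @return List with `sCF` (fraction), `n_decisive` and per-pattern counts.
#' @export
site_concordance <- function(matrix, species_pair = NULL) {
  if (!inherits(matrix, "site_matrix")) matrix <- site_matrix(matrix)
  if (nrow(matrix) != 4) stop("site concordance needs exactly 4 taxa",
                              call. = FALSE)
  labs <- rownames(matrix)
  if (is.null(species_pair)) {
    species_pair <- c(labs[startsWith(labs, "blue")][1],
                      labs[startsWith(labs, "sable")][1])
  }
  if (anyNA(species_pair) || !all(species_pair %in% labs)) {
    stop("`species_pair` must name two rows of the matrix", call. = FALSE)
  }
  i1 <- match(species_pair[1], labs); i2 <- match(species_pair[2], labs)
  oth <- setdiff(seq_len(4), c(i1, i2))

  ok <- colSums(matrix == 0L) == 0L
  mn <- apply(matrix, 2, min); mx <- apply(matrix, 2, max)
  # biallelic 2+2 transversion patterns
  n_mn <- colSums(matrix == matrix(mn, 4, ncol(matrix), byrow = TRUE))
  biallelic <- ok & mn != mx &
    colSums(matrix == matrix(mn, 4, ncol(matrix), byrow = TRUE) |
              matrix == matrix(mx, 4, ncol(matrix), byrow = TRUE)) == 4
  two_two <- biallelic & n_mn == 2L
  tv <- two_two & PQ_TS_PARTNER[pmax(mn, 1L)] != mx

  pair_match <- matrix[i1, ] == matrix[i2, ]
  other_match <- matrix[oth[1], ] == matrix[oth[2], ]
  concordant <- tv & pair_match & other_match
  disc1 <- tv & (matrix[i1, ] == matrix[oth[1], ]) &
    (matrix[i2, ] == matrix[oth[2], ]) & !pair_match
  disc2 <- tv & (matrix[i1, ] == matrix[oth[2], ]) &
    (matrix[i2, ] == matrix[oth[1], ]) & !pair_match
  n_dec <- sum(tv)
  if (n_dec == 0) stop("no decisive sites", call. = FALSE)
  list(sCF = sum(concordant) / n_dec, n_decisive = n_dec,
       counts = c(concordant = sum(concordant), discordant_1 = sum(disc1),
                  discordant_2 = sum(disc2)))
}

#' Bar chart of window-tree topology proportions
#'
#' @param records Window records or class vector (see [topology_summary()]).
#' @return A ggplot.
#' @export
plot_topology_summary <- function(records) {
  s <- topology_summary(records)
  s$topology_class <- factor(s$topology_class, levels = s$topology_class)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$topology_class,
                                  y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%%", 100 * .data$proportion)), vjust = -0.4) +
    ggplot2::labs(x = "window-tree topology", y = "proportion of windows") +
    ggplot2::theme_minimal()
}
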