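#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with two determinism guarantees: ties in the
#' Q criterion are broken by the smallest (row, column) taxon-index pair, and
#' negative branch-length estimates are clamped to zero. On additive
#' distances the true topology and branch lengths are recovered exactly.
#'
#' @param dm Symmetric numeric matrix with taxon names as dimnames (>= 3
#'   taxa; >= 4 for a non-trivial topology).
#' @return An unrooted [ape::as.phylo] tree.
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 5, 6, 7, 5, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("`dm` must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(dm))) stop("non-finite distances", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12) stop("`dm` must be symmetric", call. = FALSE)
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # node bookkeeping: tips are 1..n; internal nodes get ids n+1, n+2, ...
  node_id <- seq_len(n)
  next_internal <- n + 1L
  edges <- matrix(0L, nrow = 2L * n, ncol = 2)
  lens <- numeric(2L * n)
  n_edge <- 0L
  add_edge <- function(parent, child, len) {
    n_edge <<- n_edge + 1L
    edges[n_edge, ] <<- c(parent, child)
    lens[n_edge] <<- max(0, len)
  }

  D <- dm
  while (nrow(D) > 3) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest Q; ties resolved by smallest (i, j) with i < j
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    u <- next_internal; next_internal <- next_internal + 1L
    add_edge(u, node_id[i], li)
    add_edge(u, node_id[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D_new <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    node_id <- c(node_id[keep], u)
    D <- D_new
  }
  # final star over the last three nodes
  u <- next_internal
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(u, node_id[1], la)
  add_edge(u, node_id[2], lb)
  add_edge(u, node_id[3], lc)

  edges <- edges[seq_len(n_edge), , drop = FALSE]
  lens <- lens[seq_len(n_edge)]
  # renumber internal nodes into ape convention (root-ish last internal
  # becomes n+1, then descending creation order keeps a valid phylo)
  internal_old <- sort(unique(edges[edges > n]))
  remap <- integer(max(internal_old))
  remap[internal_old] <- n + rank(-internal_old)
  big <- edges > n
  edges[big] <- remap[edges[big]]
  phy <- structure(list(edge = edges[rev(seq_len(n_edge)), , drop = FALSE],
                        edge.length = lens[rev(seq_len(n_edge))],
                        tip.label = labels,
                        Nnode = length(internal_old)),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Least-squares best quartet by enumeration
#'
#' Fits all three resolved quartet topologies by ordinary least squares and
#' returns the best. Used as an independent check of [nj_tree()] on
#' quartets: on additive input the residual of the true topology is zero.
#'
#' @param dm 4x4 symmetric distance matrix with dimnames.
#' @return List with `split` (character of the two sister taxa of taxon 1's
#'   partner pair; see details), `topology` (the taxon pair grouped with
#'   taxon 1), `rss` (residuals of all three topologies, named by the taxon
#'   paired with taxon 1).
#' @export
ls_quartet <- function(dm) {
  stopifnot(nrow(dm) == 4, ncol(dm) == 4)
  taxa <- rownames(dm)
  # topology labelled by the taxon paired with taxa[1]
  pairs <- taxa[2:4]
  rss <- stats::setNames(numeric(3), pairs)
  for (p in pairs) {
    others <- setdiff(taxa, c(taxa[1], p))
    # design: d depends on 5 edges e1..e5; tips (t1, p | o1, o2) with
    # internal edge between the cherries
    A <- matrix(0, nrow = 6, ncol = 5)
    y <- numeric(6)
    combs <- utils::combn(taxa, 2)
    edge_of <- stats::setNames(1:4, c(taxa[1], p, others))
    for (q in seq_len(ncol(combs))) {
      a <- combs[1, q]; b <- combs[2, q]
      A[q, edge_of[[a]]] <- 1
      A[q, edge_of[[b]]] <- 1
      same_cherry <- (a %in% c(taxa[1], p)) == (b %in% c(taxa[1], p))
      if (!same_cherry) A[q, 5] <- 1
      y[q] <- dm[a, b]
    }
    fit <- stats::lm.fit(A, y)
    rss[p] <- sum(fit$residuals^2)
  }
  best <- names(rss)[which.min(rss)]
  list(topology = c(taxa[1], best), rss = rss,
       split = setdiff(taxa, c(taxa[1], best)))
}
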