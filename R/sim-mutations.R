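#' Simulate finite-site genotypes along a gene tree
#'
#' Places mutations on a simulated genealogy as a Poisson process with rate
#' `mu * branch_length` per site. Each mutation is a transition with
#' probability `kappa / (kappa + 1)`, otherwise one of the two transversions
#' uniformly (a Kimura two-parameter process). The ancestral sequence is
#' uniform over `A, C, G, T`.
#'
#' @param tree A `"gene_tree"` from [simulate_gene_tree()].
#' @param length Window length in bp (>= 1).
#' @param mu Mutation rate per site per generation.
#' @param kappa Transition/transversion rate ratio.
#' @param rng_seed Optional integer seed.
#' @param ancestral Optional integer vector (`1:4`) of ancestral states;
#'   drawn uniformly when `NULL`.
#' @return Integer matrix (`0:4` coding, see [encode_bases()]) with one row
#'   per haplotype, `length` columns, rownames = tip labels.
#' @examples
#' m <- demographic_model()
#' gt <- simulate_gene_tree(m, rng_seed = 1)
#' h <- simulate_window_genotypes(gt, 100, mu = 1e-8, kappa = 2, rng_seed = 2)
#' dim(h)
#' @export
simulate_window_genotypes <- function(tree, length, mu, kappa,
                                      rng_seed = NULL, ancestral = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  if (length < 1) stop("`length` must be at least 1", call. = FALSE)
  if (mu < 0) stop("`mu` must be non-negative", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  length <- as.integer(length)

  n_tip <- base::length(tree$tip_labels)
  n_nodes <- base::length(tree$node_time)
  if (is.null(ancestral)) {
    ancestral <- sample.int(4L, length, replace = TRUE)
  } else {
    stopifnot(base::length(ancestral) == length, all(ancestral %in% 1:4))
  }

  seqs <- vector("list", n_nodes)
  seqs[[tree$root]] <- as.integer(ancestral)
  p_ts <- kappa / (kappa + 1)

  # preorder: parents appear before children
  stack <- tree$root
  out <- matrix(0L, nrow = n_tip, ncol = length,
                dimnames = list(tree$tip_labels, NULL))
  while (base::length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    s_parent <- seqs[[nd]]
    for (kid in tree$children[nd, ]) {
      bl <- tree$node_time[nd] - tree$node_time[kid]
      s <- s_parent
      n_mut <- stats::rpois(1, mu * bl * length)
      if (n_mut > 0) {
        sites <- sample.int(length, n_mut, replace = TRUE)
        is_ts <- stats::runif(n_mut) < p_ts
        pick2 <- stats::runif(n_mut) < 0.5
        dup <- duplicated(sites) | duplicated(sites, fromLast = TRUE)
        if (any(!dup)) {
          i <- which(!dup)
          cur <- s[sites[i]]
          s[sites[i]] <- mutate_base_vec(cur, is_ts[i], pick2[i])
        }
        for (j in which(dup)) {     # multiple hits applied sequentially
          cur <- s[sites[j]]
          s[sites[j]] <- mutate_base_vec(cur, is_ts[j], pick2[j])
        }
      }
      if (kid <= n_tip) {
        out[kid, ] <- s
      } else {
        seqs[[kid]] <- s
        stack <- c(kid, stack)
      }
    }
    seqs[nd] <- list(NULL)
  }
  out
}

mutate_base_vec <- function(cur, is_ts, pick2) {
  new <- PQ_TS_PARTNER[cur]
  tv <- ifelse(pick2, PQ_TV2[cur], PQ_TV1[cur])
  new[!is_ts] <- tv[!is_ts]
  as.integer(new)
}

#' Group haplotype rows of a genotype matrix by diploid individual
#'
#' Tip labels follow `"<species><i>_<1|2>"`; the haploid outgroup keeps its
#' single sequence.
#'
#' @param haps Integer haplotype matrix from [simulate_window_genotypes()].
#' @return Named list: per individual an integer matrix with 1 or 2 rows.
#' @export
genotypes_by_individual <- function(haps) {
  ind <- sub("_[12]$", "", rownames(haps))
  lapply(split(seq_len(nrow(haps)), factor(ind, levels = unique(ind))),
         function(i) haps[i, , drop = FALSE])
}
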