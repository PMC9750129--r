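# Shared oracles and fixture builders, independent of the code paths they
# check.

# K2P transition/transversion expected difference proportions after time t,
# via eigendecomposition of the rate matrix (alpha = transition rate,
# beta = rate of EACH transversion)
k2p_expected_pdist <- function(mu, kappa, t) {
  alpha <- mu * kappa / (kappa + 1)
  beta <- mu / (2 * (kappa + 1))
  # order A C G T; transitions A<->G, C<->T
  Q <- matrix(beta, 4, 4)
  Q[1, 3] <- Q[3, 1] <- alpha
  Q[2, 4] <- Q[4, 2] <- alpha
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
  1 - mean(diag(P))  # start base uniform; prob end != start
}

# delete-1 (unweighted) jackknife standard error of D over blocks
delete1_jackknife_se <- function(nabba, nbaba) {
  g <- length(nabba)
  nA <- sum(nabba); nB <- sum(nbaba)
  d_minus <- vapply(seq_len(g), function(j) {
    ((nA - nabba[j]) - (nB - nbaba[j])) / ((nA + nB) - (nabba[j] + nbaba[j]))
  }, numeric(1))
  sqrt((g - 1) / g * sum((d_minus - mean(d_minus))^2))
}

# random additive quartet: tree ((a, b), (c, d)) with positive edges
random_additive_quartet <- function() {
  e <- stats::runif(5, 0.05, 1)  # a, b, c, d, internal
  taxa <- c("a", "b", "c", "d")
  dm <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  dm["a", "b"] <- dm["b", "a"] <- e[1] + e[2]
  dm["c", "d"] <- dm["d", "c"] <- e[3] + e[4]
  dm["a", "c"] <- dm["c", "a"] <- e[1] + e[5] + e[3]
  dm["a", "d"] <- dm["d", "a"] <- e[1] + e[5] + e[4]
  dm["b", "c"] <- dm["c", "b"] <- e[2] + e[5] + e[3]
  dm["b", "d"] <- dm["d", "b"] <- e[2] + e[5] + e[4]
  list(dm = dm, edges = e, cherries = list(c("a", "b"), c("c", "d")))
}

# small demographic model used across tests
toy_model <- function(...) {
  demographic_model(samples = c(blue = 1, sable = 1, roan = 1), ...)
}

# exhaustive Consensify site oracle: exact call probabilities for a count
# vector under "sample `k` of the reads without replacement, emit a base
# seen >= 2 times"
consensify_site_probs <- function(counts, sample_size = 3) {
  depth <- sum(counts)
  k <- min(sample_size, depth)
  reads <- rep(1:4, counts)
  combos <- utils::combn(depth, k)
  out <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  for (i in seq_len(ncol(combos))) {
    tab <- tabulate(reads[combos[, i]], nbins = 4)
    if (max(tab) >= 2) {
      out[which.max(tab)] <- out[which.max(tab)] + 1
    } else {
      out["N"] <- out["N"] + 1
    }
  }
  out / ncol(combos)
}

tips_under_test <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under_test, tree = tree))
}
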