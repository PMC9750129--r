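#' Simulate one gene tree under the structured multispecies coalescent
#'
#' Generates a coalescent genealogy of all sampled haplotypes under the
#' piecewise-constant structured coalescent defined by a
#' [demographic_model()]. Each ingroup diploid contributes two haplotypes;
#' the outgroup is a single haploid lineage. If the model carries an
#' introgression pulse, every recipient-population lineage alive at the pulse
#' time independently switches to the donor population with probability `f`.
#'
#' Windows are treated as freely recombining loci: one call simulates one
#' window's genealogy, independent of all others.
#'
#' @param model A [demographic_model()].
#' @param rng_seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (so callers looping over windows seed once).
#' @return An object of class `"gene_tree"`: a list with
#'   * `phylo`: rooted ultrametric [ape::as.phylo] tree, branch lengths in
#'     generations, tip labels like `"blue1_1"` (species, individual,
#'     haplotype) and `"outgroup"`;
#'   * `topology`: the quartet genealogy class (`"BS"`, `"BR"` or `"RS"`) of
#'     one representative haplotype per ingroup species;
#'   * `tmrca`: named vector of the representative pairwise TMRCAs
#'     (generations) for the `bs`, `br` and `rs` pairs;
#'   * `migrants`: tip labels whose ancestral lineage took the pulse;
#'   * internal fields (`children`, `node_time`, `root`, `tip_labels`) used
#'     by the mutation layer.
#' @examples
#' m <- demographic_model(samples = c(blue = 1, sable = 1, roan = 1))
#' gt <- simulate_gene_tree(m, rng_seed = 1)
#' gt$topology
#' @export
simulate_gene_tree <- function(model, rng_seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.null(rng_seed)) set.seed(rng_seed)

  # --- tips -----------------------------------------------------------------
  tip_labels <- character(0)
  tip_pop <- character(0)
  for (sp in names(model$samples)) {
    for (ind in seq_len(model$samples[[sp]])) {
      tip_labels <- c(tip_labels,
                      paste0(sp, ind, "_1"), paste0(sp, ind, "_2"))
      tip_pop <- c(tip_pop, sp, sp)
    }
  }
  tip_labels <- c(tip_labels, "outgroup")
  tip_pop <- c(tip_pop, "outgroup")
  n_tip <- length(tip_labels)

  # --- events ---------------------------------------------------------------
  events <- list(
    list(time = model$split_time_bs, type = "merge",
         from = c("blue", "sable"), to = "bs"),
    list(time = model$split_time_r, type = "merge",
         from = c("bs", "roan"), to = "bsr"),
    list(time = model$split_time_o, type = "merge",
         from = c("bsr", "outgroup"), to = "root")
  )
  if (!is.null(model$pulse)) {
    events <- c(events, list(list(time = model$pulse$time, type = "pulse")))
  }
  events <- events[order(vapply(events, `[[`, numeric(1), "time"))]

  # --- state ----------------------------------------------------------------
  max_nodes <- 2L * n_tip
  node_time <- numeric(max_nodes)
  children <- matrix(0L, nrow = max_nodes, ncol = 2)
  desc <- vector("list", max_nodes)          # tip indices under each node
  for (i in seq_len(n_tip)) desc[[i]] <- i

  active <- seq_len(n_tip)                   # node ids of live lineages
  pop <- tip_pop                             # population of each live lineage
  next_node <- n_tip + 1L
  t_now <- 0
  migrants <- integer(0)
  ev_i <- 1L

  repeat {
    if (length(active) == 1L && ev_i > length(events)) break
    pops_here <- unique(pop)
    k <- vapply(pops_here, function(p) sum(pop == p), integer(1))
    rate_pop <- k * (k - 1) / 2 / (2 * model$pop_size[pops_here])
    total <- sum(rate_pop)
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    next_ev_t <- if (ev_i <= length(events)) events[[ev_i]]$time else Inf

    if (t_now + dt >= next_ev_t) {
      t_now <- next_ev_t
      ev <- events[[ev_i]]
      ev_i <- ev_i + 1L
      if (ev$type == "merge") {
        pop[pop %in% ev$from] <- ev$to
      } else {                               # pulse
        rec <- which(pop == model$pulse$recipient)
        if (length(rec)) {
          mig <- rec[stats::runif(length(rec)) < model$pulse$proportion]
          if (length(mig)) {
            pop[mig] <- model$pulse$donor
            migrants <- c(migrants,
                          unlist(desc[active[mig]], use.names = FALSE))
          }
        }
      }
    } else {
      t_now <- t_now + dt
      p_sel <- pops_here[sample.int(length(pops_here), 1,
                                    prob = rate_pop / total)]
      idx <- which(pop == p_sel)
      pair <- idx[sample.int(length(idx), 2)]
      a <- active[pair[1]]; b <- active[pair[2]]
      node_time[next_node] <- t_now
      children[next_node, ] <- c(a, b)
      desc[[next_node]] <- c(desc[[a]], desc[[b]])
      active <- c(active[-pair], next_node)
      pop <- c(pop[-pair], p_sel)
      next_node <- next_node + 1L
    }
  }

  root <- active
  n_nodes <- next_node - 1L
  node_time <- node_time[seq_len(n_nodes)]
  children <- children[seq_len(n_nodes), , drop = FALSE]

  # --- representative quartet class ----------------------------------------
  reps <- c(blue = match("blue1_1", tip_labels),
            sable = match("sable1_1", tip_labels),
            roan = match("roan1_1", tip_labels))
  parent <- integer(n_nodes)
  for (nd in (n_tip + 1L):n_nodes) parent[children[nd, ]] <- nd
  tmrca_pair <- function(a, b) {
    anc <- logical(n_nodes)
    x <- a
    while (x != 0L) { anc[x] <- TRUE; x <- if (x == root) 0L else parent[x] }
    y <- b
    while (!anc[y]) y <- parent[y]
    node_time[y]
  }
  if (anyNA(reps)) {
    tmrca <- c(bs = NA_real_, br = NA_real_, rs = NA_real_)
    topo <- NA_character_
  } else {
    tmrca <- c(bs = tmrca_pair(reps[["blue"]], reps[["sable"]]),
               br = tmrca_pair(reps[["blue"]], reps[["roan"]]),
               rs = tmrca_pair(reps[["roan"]], reps[["sable"]]))
    topo <- c("BS", "BR", "RS")[which.min(tmrca)]
  }

  phy <- coalescent_to_phylo(children, node_time, root, n_tip, tip_labels)

  structure(
    list(phylo = phy, topology = topo, tmrca = tmrca,
         migrants = tip_labels[migrants],
         children = children, node_time = node_time, root = root,
         tip_labels = tip_labels),
    class = "gene_tree"
  )
}

# build an ape phylo from child pointers + node times (ultrametric from tips)
coalescent_to_phylo <- function(children, node_time, root, n_tip, tip_labels) {
  n_nodes <- length(node_time)
  internal <- (n_tip + 1L):n_nodes
  # ape: tips 1..n, root n+1; assign internal ids in preorder from root
  new_id <- integer(n_nodes)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  counter <- n_tip + 1L
  stack <- root
  order_internal <- integer(0)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    new_id[nd] <- counter; counter <- counter + 1L
    order_internal <- c(order_internal, nd)
    kids <- children[nd, ]
    stack <- c(kids[kids > n_tip], stack)
  }
  edges <- matrix(0L, nrow = n_nodes - 1L, ncol = 2)
  lens <- numeric(n_nodes - 1L)
  e <- 1L
  for (nd in order_internal) {
    for (kid in children[nd, ]) {
      edges[e, ] <- c(new_id[nd], new_id[kid])
      lens[e] <- node_time[nd] - node_time[kid]
      e <- e + 1L
    }
  }
  phy <- structure(list(edge = edges, edge.length = lens,
                        tip.label = tip_labels,
                        Nnode = n_nodes - n_tip),
                   class = "phylo", order = "cladewise")
  phy
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree>", length(x$tip_labels), "tips, quartet class", x$topology,
      "\n")
  if (length(x$migrants)) {
    cat("  pulse migrants:", paste(x$migrants, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate quartet-genealogy topology classes over independent windows
#'
#' Thin wrapper that simulates `n_windows` gene trees and tabulates the
#' representative quartet class of each, used for calibrating the simulator
#' against the closed-form discordance probability [expected_discordance()].
#'
#' @param model A [demographic_model()].
#' @param n_windows Number of independent windows.
#' @param rng_seed Integer seed.
#' @return A tibble with columns `topology` and `n`, and attribute
#'   `"proportions"` (named numeric over BS/BR/RS).
#' @export
simulate_topology_classes <- function(model, n_windows, rng_seed = 1) {
  set.seed(rng_seed)
  cls <- character(n_windows)
  for (i in seq_len(n_windows)) cls[i] <- simulate_gene_tree(model)$topology
  counts <- table(factor(cls, levels = c("BS", "BR", "RS")))
  out <- tibble::tibble(topology = names(counts), n = as.integer(counts))
  attr(out, "proportions") <- stats::setNames(as.numeric(counts) / n_windows,
                                              names(counts))
  out
}
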