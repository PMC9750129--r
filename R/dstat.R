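#' Count ABBA/BABA site patterns (transversions only)
#'
#' Walks four aligned pseudohaploid genomes in the order
#' (P1, P2, P3, outgroup). A site is used only if no genome is `N`, exactly
#' two alleles are present across the four, the allele pair is not a
#' transition (`C/T` or `A/G`), and the outgroup allele matches one of the
#' ingroup alleles (it defines the ancestral state). Then
#' ABBA: P2 == P3 != P1 == outgroup; BABA: P1 == P3 != P2 == outgroup;
#' all other biallelic configurations are ignored.
#'
#' @param p1,p2,p3,og Aligned sequences for one scaffold: equal-length
#'   strings, character vectors, or integer vectors in `0:4` coding.
#' @param block_size Contiguous genomic block length in bp for the jackknife
#'   (default 1e6). Blocks never span scaffolds.
#' @param scaffold Scaffold label for the block table.
#' @return Tibble with one row per non-empty block: `scaffold`, `block`
#'   (1-based index), `start`, `nABBA`, `nBABA`.
#' @examples
#' count_patterns("AT", "TT", "TT", "AT")$nABBA  # 1 (plus 1 ignored site)
#' @export
count_patterns <- function(p1, p2, p3, og, block_size = 1e6,
                           scaffold = "scaffold_1") {
  seqs <- lapply(list(p1, p2, p3, og), as_int_seq)
  L <- unique(lengths(seqs))
  if (length(L) != 1) stop("sequences must have equal length", call. = FALSE)
  if (block_size < 1) stop("`block_size` must be >= 1", call. = FALSE)
  m <- do.call(rbind, seqs)

  ok <- colSums(m == 0L) == 0L
  # exactly two alleles
  mn <- do.call(pmin, seqs)
  mx <- do.call(pmax, seqs)
  two <- ok & mn != mx &
    (m[1, ] == mn | m[1, ] == mx) & (m[2, ] == mn | m[2, ] == mx) &
    (m[3, ] == mn | m[3, ] == mx) & (m[4, ] == mn | m[4, ] == mx)
  # transversion pairs only
  tv <- two & PQ_TS_PARTNER[pmax(mn, 1L)] != mx
  abba <- tv & m[2, ] == m[3, ] & m[1, ] == m[4, ] & m[1, ] != m[2, ]
  baba <- tv & m[1, ] == m[3, ] & m[2, ] == m[4, ] & m[1, ] != m[2, ]

  block <- (seq_len(L) - 1L) %/% as.integer(block_size) + 1L
  tab <- tibble::tibble(
    scaffold = scaffold,
    block = block,
    abba = abba, baba = baba
  )
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$scaffold, .data$block),
    nABBA = sum(.data$abba), nBABA = sum(.data$baba), .groups = "drop"
  )
  out$start <- (out$block - 1L) * as.integer(block_size) + 1L
  informative <- out$nABBA + out$nBABA > 0
  out[informative, c("scaffold", "block", "start", "nABBA", "nBABA")]
}

as_int_seq <- function(x) {
  if (inherits(x, "pseudohaploid_genome")) {
    if (length(x$sequences) != 1) {
      stop("pass one scaffold at a time, or use dstat() for whole genomes",
           call. = FALSE)
    }
    return(encode_bases(x$sequences[[1]]))
  }
  if (is.numeric(x)) return(as.integer(x))
  encode_bases(x)
}

#' The D statistic from pattern counts
#'
#' `D = (nABBA - nBABA) / (nABBA + nBABA)`. Positive values indicate an
#' excess of derived-allele sharing between the taxa in positions 2 and 3.
#'
#' @param nABBA,nBABA Pattern counts.
#' @return D in `[-1, 1]`.
#' @examples
#' d_statistic(30, 10)  # 0.5
#' @export
d_statistic <- function(nABBA, nBABA) {
  if (nABBA + nBABA == 0) {
    stop("D is undefined: no ABBA or BABA sites", call. = FALSE)
  }
  (nABBA - nBABA) / (nABBA + nBABA)
}

#' Weighted block jackknife for the D statistic
#'
#' Busing-style delete-one-block jackknife with blocks weighted by their
#' informative-site counts `m_j` (`m_j = nABBA_j + nBABA_j`). With
#' `h_j = n / m_j` and leave-one-out estimates `D_{-j}`, the jackknife mean
#' is `theta_J = g * D - sum_j (1 - m_j / n) * D_{-j}` and the variance is
#' `(1/g) * sum_j (tau_j - theta_J)^2 / (h_j - 1)` with
#' `tau_j = h_j * D - (h_j - 1) * D_{-j}`. When all blocks carry equal
#' weight this reduces exactly to the unweighted delete-1 jackknife.
#'
#' @param blocks Tibble from [count_patterns()] (needs `nABBA`, `nBABA`).
#' @return List with `D`, `SE`, `Z`, `n_blocks`, `n_used`, and the per-block
#'   tibble augmented with `m` and `D_minus_j`.
#' @export
weighted_block_jackknife <- function(blocks) {
  m <- blocks$nABBA + blocks$nBABA
  keep <- m > 0
  blocks <- blocks[keep, , drop = FALSE]
  m <- m[keep]
  g <- nrow(blocks)
  if (g < 2) stop("need at least 2 informative blocks", call. = FALSE)
  nA <- sum(blocks$nABBA); nB <- sum(blocks$nBABA)
  n <- nA + nB
  if (any(m == n)) {
    stop("a single block holds all informative sites; jackknife undefined",
         call. = FALSE)
  }
  D <- (nA - nB) / n
  D_minus <- ((nA - blocks$nABBA) - (nB - blocks$nBABA)) / (n - m)
  h <- n / m
  theta_j <- g * D - sum((1 - m / n) * D_minus)
  tau <- h * D - (h - 1) * D_minus
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(v)
  list(D = D, SE = se, Z = if (se > 0) D / se else NA_real_,
       n_blocks = g, n_used = n,
       blocks = tibble::tibble(blocks, m = m, D_minus_j = D_minus))
}

#' Transversions-only ABBA-BABA test over whole genomes
#'
#' Convenience wrapper: counts patterns per scaffold, blocks them, and
#' applies the weighted block jackknife.
#'
#' @param p1,p2,p3,og Named lists / named character vectors of scaffold
#'   sequences (or [call_genome()] results), sharing scaffold names and
#'   lengths. P2 and P3 are the taxa whose excess allele sharing a positive
#'   D supports.
#' @param block_size Jackknife block size in bp (default 1 Mb).
#' @param z_threshold Significance threshold on `|Z|` (default 3).
#' @return Object of class `"dstat_result"`: the [weighted_block_jackknife()]
#'   fields plus `nABBA`, `nBABA`, `significant` and the configuration.
#' @examples
#' p1 <- c(s1 = "AAAAATTTTT"); p2 <- c(s1 = "TTTTTTTTTT")
#' p3 <- c(s1 = "TTTTTAAAAA"); og <- c(s1 = "AAAAAAAAAA")
#' res <- dstat(p1, p2, p3, og, block_size = 5)
#' res$D
#' @export
dstat <- function(p1, p2, p3, og, block_size = 1e6, z_threshold = 3) {
  if (z_threshold <= 0) stop("`z_threshold` must be positive", call. = FALSE)
  seqsets <- lapply(list(p1 = p1, p2 = p2, p3 = p3, og = og), genome_sequences)
  scaffolds <- names(seqsets$p1)
  if (is.null(scaffolds) ||
      !all(vapply(seqsets, function(s) identical(names(s), scaffolds),
                  logical(1)))) {
    stop("genomes must share identically named scaffolds", call. = FALSE)
  }
  per_scaffold <- lapply(scaffolds, function(sc) {
    count_patterns(seqsets$p1[[sc]], seqsets$p2[[sc]], seqsets$p3[[sc]],
                   seqsets$og[[sc]], block_size = block_size, scaffold = sc)
  })
  blocks <- dplyr::bind_rows(per_scaffold)
  jk <- weighted_block_jackknife(blocks)
  structure(
    c(jk, list(nABBA = sum(blocks$nABBA), nBABA = sum(blocks$nBABA),
               significant = is.finite(jk$Z) && abs(jk$Z) > z_threshold,
               block_size = block_size, z_threshold = z_threshold)),
    class = "dstat_result"
  )
}

# accept pseudohaploid_genome, named character vector, or named list
genome_sequences <- function(x) {
  if (inherits(x, "pseudohaploid_genome")) return(x$sequences)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x))) names(x) <- paste0("scaffold_", seq_along(x))
  x
}

#' @export
print.dstat_result <- function(x, ...) {
  cat("<dstat_result> transversions-only ABBA-BABA\n")
  cat(sprintf("  nABBA=%d nBABA=%d (n=%d sites, %d blocks of %g bp)\n",
              x$nABBA, x$nBABA, x$n_used, x$n_blocks, x$block_size))
  cat(sprintf("  D = %.4f  SE = %.4f  Z = %.2f%s\n", x$D, x$SE, x$Z,
              if (isTRUE(x$significant)) "  (significant)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a D-statistic result
#'
#' @param x A `"dstat_result"`.
#' @param ... Unused.
#' @return One-row tibble with counts, D, SE, Z and significance.
#' @method tidy dstat_result
#' @export
tidy.dstat_result <- function(x, ...) {
  tibble::tibble(nABBA = x$nABBA, nBABA = x$nBABA, n_used = x$n_used,
                 n_blocks = x$n_blocks, D = x$D, SE = x$SE, Z = x$Z,
                 significant = x$significant)
}

#' @rdname tidy.dstat_result
#' @method glance dstat_result
#' @export
glance.dstat_result <- function(x, ...) tidy.dstat_result(x)

#' Plot a D statistic with its jackknife interval
#'
#' @param object A `"dstat_result"`.
#' @param ... Unused.
#' @return A ggplot: D with +/- 3 SE error bar, the conventional
#'   significance band.
#' @method autoplot dstat_result
#' @export
autoplot.dstat_result <- function(object, ...) {
  df <- tidy.dstat_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "P2-P3", y = .data$D)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$D - 3 * .data$SE,
                                          ymax = .data$D + 3 * .data$SE)) +
    ggplot2::labs(x = NULL, y = "D (ABBA - BABA excess)",
                  title = sprintf("D = %.3f, Z = %.2f", df$D, df$Z)) +
    ggplot2::theme_minimal()
}
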