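#' Classify an unordered base pair by substitution type
#'
#' The damage-aware partition used by the diversity and D-statistic stages:
#' transitions (`C/T`, `A/G`) overlap with cytosine-deamination damage;
#' `G/T` and `C/A` mirror the oxidative damage signature; only `A/T` and
#' `C/G` differences are "clean" transversions that no damage channel can
#' produce. Classification is symmetric in its arguments.
#'
#' @param a,b Single bases in `A, C, G, T, N` (vectorized; recycled to a
#'   common length).
#' @return Character vector over
#'   `c("masked", "identical", "transition", "damage_like",
#'   "clean_transversion")`.
#' @examples
#' classify_substitution("C", "T")  # transition
#' classify_substitution("G", "T")  # damage_like
#' classify_substitution("A", "T")  # clean_transversion
#' @export
classify_substitution <- function(a, b) {
  ia <- code_or_stop(a)
  ib <- code_or_stop(b)
  n <- max(length(ia), length(ib))
  ia <- rep_len(ia, n); ib <- rep_len(ib, n)
  classify_substitution_idx(ia, ib)
}

# integer-coded version used on hot paths (0 = N)
classify_substitution_idx <- function(ia, ib) {
  out <- character(length(ia))
  out[ia == 0L | ib == 0L] <- "masked"
  todo <- out == ""
  same <- todo & ia == ib
  out[same] <- "identical"
  todo <- todo & !same
  ts <- todo & (PQ_TS_PARTNER[pmax(ia, 1L)] == ib)
  out[ts] <- "transition"
  todo <- todo & !ts
  # damage-like: {G,T} (oxidation) and {C,A} (its complementary-strand twin)
  dmg <- todo & ((pmin(ia, ib) == 3L & pmax(ia, ib) == 4L) |
                   (pmin(ia, ib) == 1L & pmax(ia, ib) == 2L))
  out[dmg] <- "damage_like"
  out[todo & !dmg] <- "clean_transversion"
  out
}

code_or_stop <- function(x) {
  if (is.numeric(x)) {
    if (any(!x %in% 0:4)) stop("invalid base code", call. = FALSE)
    return(as.integer(x))
  }
  bad <- !toupper(x) %in% c(PQ_BASES, "N")
  if (any(bad)) {
    stop("invalid base symbol: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  m <- match(toupper(x), PQ_BASES)
  m[is.na(m)] <- 0L
  m
}

#' Purine/pyrimidine (RY) recoding
#'
#' `A, G -> R`; `C, T -> Y`; `N -> N`. After recoding, transition
#' differences are invisible and only transversions remain informative.
#' The input must be over `A, C, G, T, N`; feeding already-recoded
#' sequences is a contract violation and raises an error.
#'
#' @param seq A single string or character vector of bases.
#' @return Same shape as the input, over `R, Y, N`.
#' @examples
#' ry_code("ACGT")  # "RYRY"
#' @export
ry_code <- function(seq) {
  single <- length(seq) == 1 && nchar(seq[1]) > 1
  x <- if (single) strsplit(seq, "")[[1]] else seq
  bad <- !toupper(x) %in% c(PQ_BASES, "N")
  if (any(bad)) {
    stop("ry_code() input must be over A, C, G, T, N (got: ",
         paste(unique(x[bad]), collapse = ", "), ")", call. = FALSE)
  }
  out <- c(A = "R", G = "R", C = "Y", T = "Y", N = "N")[toupper(x)]
  names(out) <- NULL
  if (single) paste(out, collapse = "") else out
}

#' Build a site matrix from aligned sequences
#'
#' @param x Either a character matrix (rows = individuals), an integer
#'   matrix in `0:4` coding, or a named character vector / list of equal
#'   length sequence strings.
#' @param scaffold Scaffold name for the coordinates.
#' @param pos Optional 1-based positions (default `1:L`).
#' @return Integer matrix (individuals x sites, `0:4` coding) with
#'   attributes `scaffold` and `pos`, class `"site_matrix"`.
#' @export
site_matrix <- function(x, scaffold = "scaffold_1", pos = NULL) {
  if (is.matrix(x)) {
    m <- if (is.character(x)) encode_matrix(x) else {
      storage.mode(x) <- "integer"; x
    }
  } else {
    if (is.list(x)) x <- unlist(x)
    m <- strings_to_int(x)
  }
  if (any(!m %in% 0:4)) stop("invalid base codes in site matrix", call. = FALSE)
  if (is.null(pos)) pos <- seq_len(ncol(m))
  stopifnot(length(pos) == ncol(m), !is.unsorted(pos, strictly = TRUE))
  structure(m, scaffold = scaffold, pos = as.integer(pos),
            class = c("site_matrix", class(m)))
}

#' Drop missing and uninformative sites
#'
#' Removes every site where at least one individual is `N` and every site
#' that is monomorphic across all individuals. The retained count is the
#' normalization denominator of the pairwise-difference diversity statistic,
#' shared by all pairs of the cohort. Idempotent.
#'
#' @param matrix A [site_matrix()] (or coercible input).
#' @return List with `matrix` (filtered [site_matrix()], coordinates
#'   preserved) and `n_retained`.
#' @examples
#' m <- site_matrix(rbind(c("A","A","N","G","T"), c("A","C","C","G","G")))
#' filter_sites(m)$n_retained  # 2
#' @export
filter_sites <- function(matrix) {
  if (!inherits(matrix, "site_matrix")) matrix <- site_matrix(matrix)
  if (nrow(matrix) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (ncol(matrix) == 0) stop("empty site matrix", call. = FALSE)
  keep <- colSums(matrix == 0L) == 0L &
    matrixStats_colAnyDiff(matrix)
  out <- matrix[, keep, drop = FALSE]
  res <- structure(out, scaffold = attr(matrix, "scaffold"),
                   pos = attr(matrix, "pos")[keep],
                   class = class(matrix))
  list(matrix = res, n_retained = sum(keep))
}

# TRUE for columns with >= 2 distinct values
matrixStats_colAnyDiff <- function(m) {
  first <- m[1, ]
  colSums(m != matrix(first, nrow = nrow(m), ncol = ncol(m),
                      byrow = TRUE)) > 0L
}

#' Dump retained site coordinates for audit
#'
#' @param matrix A filtered [site_matrix()].
#' @param path TSV output path.
#' @return The path, invisibly.
#' @export
write_site_coordinates <- function(matrix, path) {
  df <- data.frame(scaffold = attr(matrix, "scaffold"),
                   pos = attr(matrix, "pos"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
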