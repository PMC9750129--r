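#' Read an aligned multi-FASTA into an alignment matrix
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return Character matrix (sequences x columns, uppercase) with sequence
#'   ids as rownames.
#' @export
read_alignment <- function(path) {
  bin <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(bin)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(names(bin)))
  m
}

#' Remove alignment columns with ambiguities or missing data
#'
#' Drops every column containing any symbol outside `A, C, G, T` (gaps,
#' `N`, IUPAC ambiguity codes) in any sequence. Idempotent.
#'
#' @param aln Character matrix (sequences x columns) or a named character
#'   vector of aligned strings.
#' @return List with `alignment` (filtered matrix) and `L_filtered`.
#' @examples
#' a <- rbind(x = c("A", "N", "G"), y = c("A", "C", "G"))
#' strip_ambiguous_columns(a)$L_filtered  # 2
#' @export
strip_ambiguous_columns <- function(aln) {
  aln <- as_alignment_matrix(aln)
  bad <- matrix(!toupper(aln) %in% PQ_BASES, nrow = nrow(aln))
  keep <- colSums(bad) == 0
  out <- aln[, keep, drop = FALSE]
  list(alignment = out, L_filtered = ncol(out))
}

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.list(aln)) aln <- unlist(aln)
  stopifnot(length(unique(nchar(aln))) == 1)
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

#' Number of segregating sites
#'
#' Columns with at least two distinct bases. Apply
#' [strip_ambiguous_columns()] first so that ambiguity codes do not count
#' as alleles.
#'
#' @param aln Alignment matrix or named character vector.
#' @return Integer count.
#' @examples
#' segregating_sites(c("AAA", "AAT", "ATT"))  # 2
#' @export
segregating_sites <- function(aln) {
  aln <- as_alignment_matrix(aln)
  if (nrow(aln) < 2) stop("need at least 2 sequences", call. = FALSE)
  first <- matrix(aln[1, ], nrow = nrow(aln), ncol = ncol(aln), byrow = TRUE)
  sum(colSums(aln != first) > 0)
}

#' Nucleotide diversity of an alignment
#'
#' Mean over all unordered sequence pairs of the Hamming difference divided
#' by the alignment length (no sample-size correction, matching the
#' haplotype-network convention).
#'
#' @param aln Alignment matrix or named character vector (filtered).
#' @return Nucleotide diversity in `[0, 1]`.
#' @examples
#' nucleotide_diversity(c("AAA", "AAT", "ATT"))  # 0.4444
#' @export
nucleotide_diversity <- function(aln) {
  aln <- as_alignment_matrix(aln)
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  L <- ncol(aln)
  if (L == 0) stop("alignment has zero columns", call. = FALSE)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(aln[i, ] != aln[j, ])
    }
  }
  (total / (n * (n - 1) / 2)) / L
}

#' Pairwise Hamming difference matrix
#'
#' @param aln Alignment matrix or named character vector (filtered).
#' @return Symmetric integer matrix of pairwise differences.
#' @export
pairwise_difference_matrix <- function(aln) {
  aln <- as_alignment_matrix(aln)
  n <- nrow(aln)
  out <- matrix(0L, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- sum(aln[i, ] != aln[j, ])
    }
  }
  out
}

#' Mitochondrial alignment diversity summary
#'
#' The full mitochondrial stage: strip ambiguous/missing columns, then
#' report the filtered length, segregating sites, nucleotide diversity and
#' the pairwise difference matrix.
#'
#' @param aln Alignment matrix, named character vector, or a FASTA path.
#' @return Object of class `"mito_diversity"`: list with `L_filtered`, `S`,
#'   `pi`, `pairwise`.
#' @examples
#' mito_diversity(c(a = "AARA", b = "AATA", c = "ATTA"))
#' @export
mito_diversity <- function(aln) {
  if (is.character(aln) && length(aln) == 1 && file.exists(aln)) {
    aln <- read_alignment(aln)
  }
  stripped <- strip_ambiguous_columns(as_alignment_matrix(aln))
  if (stripped$L_filtered == 0) {
    stop("all columns removed by ambiguity filtering", call. = FALSE)
  }
  a <- stripped$alignment
  structure(
    list(L_filtered = stripped$L_filtered, S = segregating_sites(a),
         pi = nucleotide_diversity(a), pairwise = pairwise_difference_matrix(a)),
    class = "mito_diversity"
  )
}

#' @export
print.mito_diversity <- function(x, ...) {
  cat("<mito_diversity>\n")
  cat(sprintf("  filtered length: %d bp\n  segregating sites: %d\n  pi: %.5g\n",
              x$L_filtered, x$S, x$pi))
  invisible(x)
}

#' Tidy a mitochondrial diversity summary
#'
#' @param x A `"mito_diversity"`.
#' @param ... Unused.
#' @return One-row tibble with `L_filtered`, `S`, `pi`.
#' @method tidy mito_diversity
#' @export
tidy.mito_diversity <- function(x, ...) {
  tibble::tibble(L_filtered = x$L_filtered, S = x$S, pi = x$pi)
}

#' Accessions of the blue antelope mitochondrial genomes
#'
#' GenBank accessions of the complete (and partial) mitochondrial genomes
#' used for the haplotype-network diversity statistics. Downloading and
#' aligning them requires network access and an aligner; the package only
#' consumes the resulting aligned FASTA.
#'
#' @return List with `complete` and `partial` accession vectors.
#' @export
mito_accessions <- function() {
  list(complete = c("ON101842", "MW222233", "MW222234"),
       partial = c("MW228401", "MW228402"))
}

#' Fetch mitochondrial accessions and build an alignment
#'
#' Downloads the requested GenBank nucleotide accessions (NCBI efetch,
#' needs network access) and aligns them with `mafft` (must be on the
#' PATH). Returns the path to the aligned FASTA, ready for
#' [mito_diversity()].
#'
#' @param accessions Character vector of accession ids.
#' @param dir Working directory for downloads and the alignment.
#' @return Path to the aligned FASTA.
#' @export
fetch_mito_accessions <- function(accessions,
                                  dir = tempfile("mito_accessions")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- file.path(dir, "accessions.fasta")
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=",
                paste(accessions, collapse = ","))
  status <- tryCatch(
    utils::download.file(url, raw, quiet = TRUE, mode = "wb"),
    error = function(e) stop("could not download accessions (",
                             conditionMessage(e), ")", call. = FALSE),
    warning = function(w) stop("could not download accessions (",
                               conditionMessage(w), ")", call. = FALSE)
  )
  if (!file.exists(raw) || file.size(raw) < 1000) {
    stop("accession download incomplete", call. = FALSE)
  }
  aligned <- file.path(dir, "aligned.fasta")
  code <- system2("mafft", c("--auto", "--quiet", shQuote(raw)),
                  stdout = aligned)
  if (code != 0 || !file.exists(aligned) || file.size(aligned) < 1000) {
    stop("mafft alignment failed", call. = FALSE)
  }
  aligned
}
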