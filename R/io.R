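#' Write sequences to FASTA (70 bases per line)
#'
#' @param seqs Named character vector of sequences, or a
#'   `pseudohaploid_genome` (scaffold names become record ids, prefixed by
#'   the individual id).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "pseudohaploid_genome")) {
    nm <- paste(seqs$individual, names(seqs$sequences), sep = "|")
    seqs <- stats::setNames(seqs$sequences, nm)
  }
  if (is.list(seqs)) seqs <- unlist(seqs)
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(s, "")[[1]]))
  ape::write.FASTA(bin, path)
  # ape writes wrapped FASTA; enforce 70-column wrapping explicitly
  lines <- readLines(path)
  con <- file(path, "w")
  for (ln in lines) {
    if (startsWith(ln, ">") || nchar(ln) <= 70) {
      writeLines(ln, con)
    } else {
      starts <- seq(1, nchar(ln), by = 70)
      writeLines(substring(ln, starts, pmin(starts + 69, nchar(ln))), con)
    }
  }
  close(con)
  invisible(path)
}

#' Read a FASTA file into named sequence strings
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  vapply(as.character(bin), function(x) toupper(paste(x, collapse = "")),
         character(1))
}

#' Write a base-count table to TSV
#'
#' Columns: `scaffold`, `pos` (1-based), `individual`, `nA`, `nC`, `nG`,
#' `nT` -- the interchange format between the simulator and the callers.
#'
#' @param tab Tibble from [base_counts_table()].
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_base_counts <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a base-count TSV into per-scaffold count matrices
#'
#' @param path TSV written by [write_base_counts()].
#' @param individual Individual to extract (default: the only one present).
#' @return Named list: scaffold -> `L x 4` integer count matrix (positions
#'   1..max(pos); absent positions get zero counts).
#' @export
read_base_counts <- function(path, individual = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(individual)) {
    ids <- unique(tab$individual)
    if (length(ids) != 1) {
      stop("multiple individuals in file; pass `individual`", call. = FALSE)
    }
    individual <- ids
  }
  tab <- tab[tab$individual == individual, , drop = FALSE]
  out <- list()
  for (sc in unique(tab$scaffold)) {
    sub <- tab[tab$scaffold == sc, , drop = FALSE]
    L <- max(sub$pos)
    m <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, PQ_BASES))
    m[sub$pos, ] <- as.matrix(sub[, c("nA", "nC", "nG", "nT")])
    out[[sc]] <- m
  }
  out
}

#' Write window trees to a `.trees` newick file
#'
#' @param records Window-record tibble from [window_trees()].
#' @param path Output file; one newick string per line (unresolvable
#'   windows are skipped).
#' @return The path, invisibly.
#' @export
write_window_trees <- function(records, path) {
  writeLines(records$newick[!is.na(records$newick)], path)
  invisible(path)
}

#' Read a `.trees` newick file
#'
#' @param path File with one newick per line.
#' @return List of [ape::as.phylo] trees.
#' @export
read_window_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees
}
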