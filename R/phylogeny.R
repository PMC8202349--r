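# Jukes-Cantor distances, neighbor-joining trees, bootstrap support.
#
# Alignments are tibbles with columns `taxon` and `seq` (equal-length gapped
# sequences over {A,C,G,T,-,N}); multiple sequence alignment itself is out of
# scope and is expected to come from an external aligner.

#' Slice an alignment window
#'
#' Selects `width` consecutive columns starting at 1-based column `start`,
#' e.g. the fixed 440-column section used for tree building.
#'
#' @param aln Alignment tibble (`taxon`, `seq`).
#' @param start First column (1-based).
#' @param width Number of columns (default 440).
#' @return Alignment tibble restricted to the window.
#' @export
select_window <- function(aln, start, width = 440L) {
  stopifnot(start >= 1L, width >= 1L)
  len <- unique(nchar(aln$seq))
  if (length(len) != 1L) abort("alignment rows differ in length")
  if (start + width - 1L > len) abort("window extends past the alignment")
  dplyr::mutate(aln, seq = substr(.data$seq, start, start + width - 1L))
}

#' Jukes-Cantor distance matrix
#'
#' For each pair, the mismatch proportion p is computed over columns where
#' both sequences have an unambiguous base (pairwise deletion of gaps and N),
#' and corrected as d = -(3/4) ln(1 - 4p/3), assuming equal substitution
#' rates. Pairs with p >= 0.75 (correction undefined) raise an error naming
#' the pair.
#'
#' @param aln Alignment tibble (`taxon`, `seq`) with at least two rows.
#' @return A [stats::dist] object labeled by taxon.
#' @export
jc_distance <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) abort("need at least two taxa")
  if (length(unique(nchar(aln$seq))) != 1L) abort("alignment rows differ in length")
  ints <- lapply(aln$seq, utf8ToInt)
  acgt <- utf8ToInt("ACGT")
  good <- lapply(ints, function(x) x %in% acgt)
  D <- matrix(0, n, n, dimnames = list(aln$taxon, aln$taxon))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- good[[i]] & good[[j]]
      m <- sum(both)
      if (m == 0L) {
        abort(paste0("no comparable columns between '", aln$taxon[i],
                     "' and '", aln$taxon[j], "'"))
      }
      p <- sum(ints[[i]][both] != ints[[j]][both]) / m
      if (p >= 0.75) {
        abort(paste0("Jukes-Cantor correction undefined (p = ", signif(p, 3),
                     ") for pair '", aln$taxon[i], "' / '", aln$taxon[j], "'"))
      }
      D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  stats::as.dist(D)
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration on a distance matrix; negative
#' branch lengths (a known artifact of the two-point length formulas) are
#' clamped to zero with a warning.
#'
#' @param D A [stats::dist] object or symmetric matrix over at least three
#'   taxa.
#' @return An unrooted `ape::phylo` tree with branch lengths in
#'   substitutions per site.
#' @export
nj_tree <- function(D) {
  D <- stats::as.dist(D)
  if (attr(D, "Size") < 3L) abort("neighbor joining needs at least three taxa")
  tree <- ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warn("negative neighbor-joining branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the Jukes-Cantor +
#' neighbor-joining tree for each replicate, and annotates each internal
#' bipartition of the full-alignment tree with the percentage of replicates
#' containing it (stored in `node.label`).
#'
#' @param aln Alignment tibble (`taxon`, `seq`).
#' @param replicates Number of bootstrap replicates (default 500).
#' @param seed Optional integer seed.
#' @return An `ape::phylo` tree whose internal `node.label`s are support
#'   percentages in \[0, 100\].
#' @export
bootstrap_support <- function(aln, replicates = 500L, seed = NULL) {
  stopifnot(replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  base_tree <- nj_tree(jc_distance(aln))
  len <- nchar(aln$seq[1])
  chars <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  boot_trees <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(len, len, replace = TRUE)
    rep_aln <- tibble(
      taxon = aln$taxon,
      seq = apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    )
    boot_trees[[b]] <- nj_tree(jc_distance(rep_aln))
  }
  counts <- ape::prop.clades(base_tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base_tree$node.label <- round(100 * counts / replicates, 1)
  base_tree
}

#' Read an aligned FASTA into an alignment tibble
#'
#' @param path FASTA file of equal-length (gapped) sequences.
#' @return Alignment tibble (`taxon`, `seq`).
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(taxon = names(x), seq = toupper(as.character(x)))
}
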