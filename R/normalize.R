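# Community-matrix normalization and univariate comparisons.
#
# Community tables are tibbles with a `sample` identifier column followed by
# one non-negative numeric column per OTU.

# Extract the numeric part of a community tibble as a matrix with sample
# rownames, preserving column order.
cm_matrix <- function(comm, check_negative = TRUE) {
  stopifnot("sample" %in% names(comm))
  m <- as.matrix(comm[, setdiff(names(comm), "sample"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- comm$sample
  if (check_negative && any(m < 0)) {
    abort("community matrix has negative entries")
  }
  m
}

cm_rebuild <- function(m, comm) {
  dplyr::bind_cols(tibble(sample = comm$sample), as_tibble(m))
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total. All-zero samples stay zero.
#'
#' @param comm Community tibble (`sample` column + numeric OTU columns).
#' @return Community tibble of row-wise proportions.
#' @export
relative_abundance <- function(comm) {
  m <- cm_matrix(comm)
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  cm_rebuild(m / tot, comm)
}

#' Zero out relative abundances below a detection threshold
#'
#' An OTU is treated as absent from a sample when its relative abundance is
#' strictly below `threshold`; such entries are set to 0. No renormalization
#' is applied, and OTU columns that become all-zero are retained.
#'
#' @param comm Community tibble in relative-abundance form.
#' @param threshold Strict lower detection limit (default 0.001).
#' @return Thresholded community tibble; the names of all-zero OTU columns
#'   are attached as attribute `"empty_otus"`.
#' @export
threshold_relative_abundance <- function(comm, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1)
  m <- cm_matrix(comm)
  m[m < threshold] <- 0
  out <- cm_rebuild(m, comm)
  attr(out, "empty_otus") <- colnames(m)[colSums(m) == 0]
  out
}

#' Log-normalize a community matrix
#'
#' The transformation x -> log_b(x) + 1 for x > 0 (0 stays 0), standard for
#' community abundance data. If any entry is non-integer the whole matrix is
#' first divided by its smallest positive entry so that the smallest observed
#' abundance maps to 1 and all transformed values stay non-negative.
#'
#' @param comm Community tibble (counts or relative abundances).
#' @param base Logarithm base (default 2).
#' @return Log-normalized community tibble.
#' @export
log_normalize <- function(comm, base = 2) {
  stopifnot(base > 1)
  m <- cm_matrix(comm)
  pos <- m[m > 0]
  if (length(pos) > 0 && any(abs(m - round(m)) > 1e-8)) {
    m <- m / min(pos)
  }
  m[m > 0] <- log(m[m > 0], base = base) + 1
  cm_rebuild(m, comm)
}

#' Kruskal-Wallis rank-sum comparison
#'
#' Tie-corrected rank-based H statistic against a chi-squared reference with
#' (groups - 1) degrees of freedom.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (at least two groups).
#' @return Tibble `statistic` (H), `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) abort("need at least two groups")
  if (length(unique(values)) == 1L) {
    # every observation tied: no rank information, H = 0 by convention
    return(tibble(statistic = 0, df = nlevels(droplevels(groups)) - 1,
                  p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}
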