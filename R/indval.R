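# IndVal indicator-species (bioindicator) analysis.

#' Indicator value analysis with permutation test
#'
#' For OTU j and group k, specificity `A = mean(x_j in k) / sum_k'
#' mean(x_j in k')` and fidelity `B = (# samples in k with x_j > 0) /
#' (# samples in k)`; the indicator value is `A * B` and the OTU statistic
#' is its maximum over groups. Significance is assessed by randomly
#' relabeling samples: the p-value is the add-one-corrected probability of a
#' strictly higher indicator value, `(1 + #(IV* > IV)) / (1 + m)`, so ties
#' favor non-significance. OTUs whose permuted statistic is constant and
#' equal to the observed one (e.g. all-zero OTUs) get p = 1.
#'
#' @param comm Community tibble (`sample` column + numeric OTU columns),
#'   typically in relative-abundance form.
#' @param groups Group label vector aligned with the rows of `comm` (at
#'   least two groups, each non-empty).
#' @param permutations Number of random relabelings m (default 10000).
#' @param alpha Bioindicator significance cutoff on the raw permutation
#'   p-value (default 0.001; no multiple-testing correction by default).
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @param seed Optional integer seed for the permutation stream.
#' @return A `peatmob_indval` tibble: `otu`, `group` (the maximizing group),
#'   `A`, `B`, `indval`, `p_value`, `bioindicator`.
#' @export
indval <- function(comm, groups, permutations = 10000, alpha = 0.001,
                   p_adjust = "none", seed = NULL) {
  if (permutations < 1L) abort("permutations must be >= 1")
  g <- as.factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2L) abort("need at least two groups")
  if (any(table(g) == 0L)) abort("every group needs at least one sample")
  X <- cm_matrix(comm)
  if (length(g) != nrow(X)) abort("groups must match community rows")
  if (!is.null(seed)) set.seed(seed)

  stat_all <- function(gg) {
    # k x p matrices of group means and occurrence frequencies
    M <- rowsum(X, gg) / as.vector(table(gg))
    colsum <- colSums(M)
    colsum[colsum == 0] <- 1
    A <- sweep(M, 2, colsum, `/`)
    B <- rowsum((X > 0) + 0, gg) / as.vector(table(gg))
    IV <- A * B
    list(stat = apply(IV, 2, max),
         group = rownames(IV)[apply(IV, 2, which.max)],
         A = A, B = B, IV = IV)
  }

  obs <- stat_all(g)
  p_otus <- ncol(X)
  exceed <- numeric(p_otus)
  all_equal <- rep(TRUE, p_otus)
  for (i in seq_len(permutations)) {
    st <- stat_all(g[sample.int(length(g))])$stat
    exceed <- exceed + (st > obs$stat)
    all_equal <- all_equal & (st == obs$stat)
  }
  p <- unname((1 + exceed) / (1 + permutations))
  p[all_equal] <- 1
  p <- stats::p.adjust(p, method = p_adjust)

  idx <- cbind(match(obs$group, rownames(obs$A)), seq_len(p_otus))
  out <- tibble(
    otu = colnames(X),
    group = obs$group,
    A = obs$A[idx],
    B = obs$B[idx],
    indval = unname(obs$stat),
    p_value = p,
    bioindicator = p < alpha
  )
  class(out) <- c("peatmob_indval", class(out))
  attr(out, "permutations") <- permutations
  attr(out, "alpha") <- alpha
  out
}

#' Indicator-value overview plot
#'
#' Indicator value against permutation p-value (log scale), bioindicators
#' highlighted and colored by their favored group.
#'
#' @param object A `peatmob_indval` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peatmob_indval <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.001
  ggplot2::ggplot(object, ggplot2::aes(.data$indval, .data$p_value)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group,
                                     shape = .data$bioindicator), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 17)) +
    ggplot2::labs(x = "indicator value (A × B)",
                  y = "permutation p-value") +
    ggplot2::theme_minimal()
}
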