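# Partial redundancy analysis with permutation tests.

#' Site-conditioned partial redundancy analysis
#'
#' Centers the community matrix, residualizes both the community and the
#' constraining design on the conditioning variables, fits the residualized
#' community on the residualized design by least squares, and extracts
#' constrained axes from the singular decomposition of the fitted values.
#' The inertia decomposition (conditioned + constrained + unconstrained =
#' total, on the variance scale SS/(n-1)) is exact.
#'
#' @param comm Community tibble (`sample` column + numeric OTU columns),
#'   typically thresholded and log-normalized.
#' @param metadata Tibble with a `sample` column and the variables named in
#'   `formula` and `condition`.
#' @param formula Right-hand-side formula for the constraints, e.g.
#'   `~ treatment * date + ch4_rate`.
#' @param condition Right-hand-side formula for the conditioning
#'   (partialled-out) variables, e.g. `~ site`, or `NULL`.
#' @return A `peatmob_rda` object with inertias, eigenvalues, sample and OTU
#'   scores, and per-term sequential sums of squares. Supports [tidy()],
#'   [glance()], [autoplot()] and [rda_permutation_test()].
#' @export
partial_rda <- function(comm, metadata, formula, condition = NULL) {
  md <- dplyr::left_join(comm["sample"], metadata, by = "sample")
  Y <- cm_matrix(comm, check_negative = FALSE)  # transformed data may be signed
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)

  Zmm <- if (is.null(condition)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(condition, md)
  }
  qz <- qr(Zmm)
  Xmm <- model.matrix(formula, md)
  assign <- attr(Xmm, "assign")
  keep <- assign != 0L
  Xmm <- Xmm[, keep, drop = FALSE]
  assign <- assign[keep]
  term_labels <- attr(stats::terms(formula), "term.labels")
  if (ncol(Xmm) == 0L) abort("constraint formula has no terms")
  if (n <= qz$rank + qr(Xmm)$rank + 1L) {
    abort("too few samples for the requested design")
  }

  Xz <- qr.resid(qz, Xmm)
  # constraint columns absorbed by the condition (or constant) carry no
  # information: drop them rather than flag them as aliased
  null_cols <- colSums(Xz^2) < 1e-10 * max(1, sum(Xz^2))
  Xz <- Xz[, !null_cols, drop = FALSE]
  assign <- assign[!null_cols]
  qx <- qr(Xz)
  if (qx$rank < ncol(Xz)) {
    aliased <- colnames(Xz)[qx$pivot[(qx$rank + 1L):ncol(Xz)]]
    abort(paste0("aliased term(s) in design: ", paste(aliased, collapse = ", ")))
  }
  Yz <- qr.resid(qz, Yc)
  fitted <- if (ncol(Xz) > 0L) qr.fitted(qx, Yz) else Yz * 0
  resid <- Yz - fitted

  ss_total <- sum(Yc^2)
  ss_yz <- sum(Yz^2)
  ss_fit <- sum(fitted^2)
  ss_res <- sum(resid^2)
  nm1 <- n - 1

  sv <- svd(fitted)
  pos <- sv$d^2 > max(sv$d^2, 0) * 1e-12 & sv$d > 0
  d <- sv$d[pos]
  eig <- d^2 / nm1
  k <- length(eig)
  axes <- if (k > 0) paste0("RDA", seq_len(k)) else character(0)
  sample_scores <- sweep(sv$u[, pos, drop = FALSE], 2, d / sqrt(nm1), `*`)
  species_scores <- sv$v[seq_len(ncol(Y)), pos, drop = FALSE]
  dimnames(sample_scores) <- list(NULL, axes)
  dimnames(species_scores) <- list(NULL, axes)

  # sequential (formula-order) term sums of squares
  terms_present <- sort(unique(assign))
  cum_q <- vector("list", length(terms_present))
  ss_cum <- numeric(length(terms_present))
  df_cum <- integer(length(terms_present))
  for (t in seq_along(terms_present)) {
    cols <- assign <= terms_present[t]
    qt <- qr(Xz[, cols, drop = FALSE])
    Qt <- qr.Q(qt)[, seq_len(qt$rank), drop = FALSE]
    cum_q[[t]] <- Qt
    ss_cum[t] <- sum(crossprod(Qt, Yz)^2)
    df_cum[t] <- qt$rank
  }
  ss_terms <- diff(c(0, ss_cum))
  df_terms <- diff(c(0L, df_cum))
  df_resid <- n - qz$rank - qx$rank

  structure(list(
    inertia = list(
      total = ss_total / nm1,
      conditioned = (ss_total - ss_yz) / nm1,
      constrained = ss_fit / nm1,
      unconstrained = ss_res / nm1
    ),
    eigenvalues = setNames(eig, axes),
    sample_scores = dplyr::bind_cols(tibble(sample = comm$sample),
                                     as_tibble(sample_scores)),
    species_scores = dplyr::bind_cols(tibble(otu = colnames(Y)),
                                      as_tibble(species_scores)),
    terms = tibble(
      term = term_labels[terms_present], df = df_terms,
      ss = ss_terms, variance = ss_terms / nm1
    ),
    df_resid = df_resid,
    n = n,
    internals = list(
      Yz = Yz, Xz = Xz, assign = assign, qz = qz, qx = qx,
      cum_q = cum_q, terms_present = terms_present,
      ss_res = ss_res, nm1 = nm1
    )
  ), class = "peatmob_rda")
}

#' @export
print.peatmob_rda <- function(x, ...) {
  cat("Partial redundancy analysis (", x$n, " samples)\n", sep = "")
  inr <- x$inertia
  cat(sprintf("  Inertia: total %.4f = conditioned %.4f + constrained %.4f + unconstrained %.4f\n",
              inr$total, inr$conditioned, inr$constrained, inr$unconstrained))
  cat("  Constrained eigenvalues:\n")
  print(round(x$eigenvalues, 4))
  invisible(x)
}

#' Permutation tests for a partial RDA
#'
#' Pseudo-F statistics from inertia ratios, tested against a null built by
#' permuting rows of the reduced-model residuals (conditioning effects
#' preserved and re-residualized each draw). Terms are tested sequentially
#' in formula order: the reduced model for term i contains the condition and
#' all preceding terms. `scope = "model"` tests all constraints jointly;
#' `scope = "axis"` tests each constrained axis eigenvalue against the
#' condition-only null.
#'
#' @param object A `peatmob_rda` fit.
#' @param permutations Number of permutations m (>= 1); p-values are
#'   `(1 + #(F* >= F)) / (1 + m)`.
#' @param scope `"terms"`, `"axis"`, or `"model"`.
#' @param seed Optional integer seed for the permutation stream.
#' @return Tibble with one row per term/axis/model: `df`, `variance`,
#'   `statistic` (pseudo-F) and `p_value`.
#' @export
rda_permutation_test <- function(object, permutations = 999,
                                 scope = c("terms", "axis", "model"),
                                 seed = NULL) {
  stopifnot(inherits(object, "peatmob_rda"))
  scope <- match.arg(scope)
  if (permutations < 1L) abort("permutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  it <- object$internals
  n <- object$n
  qz <- it$qz
  Qfull <- qr.Q(it$qx)[, seq_len(it$qx$rank), drop = FALSE]
  df_res <- object$df_resid
  ms_res <- it$ss_res / df_res

  fit_ss <- function(Q, Y) if (is.null(Q)) 0 else sum(crossprod(Q, Y)^2)

  if (scope == "terms") {
    tp <- it$terms_present
    nt <- length(tp)
    Fobs <- (object$terms$ss / object$terms$df) / ms_res
    exceed <- integer(nt)
    for (t in seq_len(nt)) {
      Qred <- if (t == 1L) NULL else it$cum_q[[t - 1L]]
      fit_r <- if (is.null(Qred)) 0 * it$Yz else Qred %*% crossprod(Qred, it$Yz)
      E <- it$Yz - fit_r
      Qcum <- it$cum_q[[t]]
      df_t <- object$terms$df[t]
      for (p in seq_len(permutations)) {
        Ys <- qr.resid(qz, fit_r + E[sample.int(n), , drop = FALSE])
        ss_t <- fit_ss(Qcum, Ys) - fit_ss(Qred, Ys)
        ss_r <- sum(Ys^2) - fit_ss(Qfull, Ys)
        Fs <- (ss_t / df_t) / (ss_r / df_res)
        if (Fs >= Fobs[t]) exceed[t] <- exceed[t] + 1L
      }
    }
    return(tibble(
      term = object$terms$term, df = object$terms$df,
      variance = object$terms$variance, statistic = Fobs,
      p_value = (1 + exceed) / (1 + permutations)
    ))
  }

  if (scope == "model") {
    df_x <- it$qx$rank
    ss_fit <- sum(object$terms$ss)
    Fobs <- (ss_fit / df_x) / ms_res
    exceed <- 0L
    for (p in seq_len(permutations)) {
      Ys <- qr.resid(qz, it$Yz[sample.int(n), , drop = FALSE])
      ss_f <- fit_ss(Qfull, Ys)
      ss_r <- sum(Ys^2) - ss_f
      if ((ss_f / df_x) / (ss_r / df_res) >= Fobs) exceed <- exceed + 1L
    }
    return(tibble(
      term = "model", df = df_x, variance = ss_fit / it$nm1,
      statistic = Fobs, p_value = (1 + exceed) / (1 + permutations)
    ))
  }

  # axis scope
  eig <- object$eigenvalues
  k <- length(eig)
  Fobs <- eig / (object$inertia$unconstrained / df_res)
  exceed <- integer(k)
  for (p in seq_len(permutations)) {
    Ys <- qr.resid(qz, it$Yz[sample.int(n), , drop = FALSE])
    fit_s <- Qfull %*% crossprod(Qfull, Ys)
    d2 <- svd(fit_s, nu = 0, nv = 0)$d^2
    eig_s <- c(d2, numeric(k))[seq_len(k)] / it$nm1
    ss_r <- sum(Ys^2) - sum(d2)
    Fs <- eig_s / (ss_r / it$nm1 / df_res)
    exceed <- exceed + (Fs >= Fobs)
  }
  tibble(
    term = names(eig), df = 1L, variance = unname(eig),
    statistic = unname(Fobs), p_value = unname((1 + exceed) / (1 + permutations))
  )
}

#' @rdname partial_rda
#' @param x A `peatmob_rda` object.
#' @param ... Unused.
#' @export
tidy.peatmob_rda <- function(x, ...) {
  tibble(
    axis = names(x$eigenvalues),
    eigenvalue = unname(x$eigenvalues),
    proportion = unname(x$eigenvalues) / x$inertia$total
  )
}

#' @rdname partial_rda
#' @export
glance.peatmob_rda <- function(x, ...) {
  tibble(
    inertia_total = x$inertia$total,
    inertia_conditioned = x$inertia$conditioned,
    inertia_constrained = x$inertia$constrained,
    inertia_unconstrained = x$inertia$unconstrained,
    n_axes = length(x$eigenvalues),
    n_samples = x$n,
    df_residual = x$df_resid
  )
}

#' Ordination biplot of a partial RDA
#'
#' Sample scores on the first two constrained axes, optionally colored by a
#' metadata variable, with OTU scores drawn as labeled points.
#'
#' @param object A `peatmob_rda` fit.
#' @param metadata Optional tibble with a `sample` column to join for
#'   aesthetics.
#' @param colour Optional bare column name in `metadata` used for point
#'   color.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peatmob_rda <- function(object, metadata = NULL, colour = NULL, ...) {
  if (length(object$eigenvalues) < 2L) {
    abort("need at least two constrained axes to draw a biplot")
  }
  ss <- object$sample_scores
  if (!is.null(metadata)) ss <- dplyr::left_join(ss, metadata, by = "sample")
  prop <- object$eigenvalues / object$inertia$total * 100
  p <- ggplot2::ggplot(ss, ggplot2::aes(.data$RDA1, .data$RDA2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = {{ colour }}), size = 2) +
    ggplot2::geom_point(
      data = object$species_scores,
      mapping = ggplot2::aes(.data$RDA1, .data$RDA2),
      shape = 3, colour = "grey30", inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = sprintf("RDA1 (%.1f%%)", prop[1]),
      y = sprintf("RDA2 (%.1f%%)", prop[2])
    ) +
    ggplot2::theme_minimal()
  p
}
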