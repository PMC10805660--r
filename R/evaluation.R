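#' Cronbach's alpha for an indicator block
#'
#' Internal-consistency reliability computed from the block correlation
#' matrix: the sum of off-diagonal correlations divided by the variance of
#' the indicator sum (\eqn{p} plus the off-diagonal sum), times
#' \eqn{p/(p-1)}.  A single-indicator block returns 1 by convention (the
#' coefficient is undefined at \eqn{p = 1}); such blocks are excluded from
#' reliability pass/fail flags.
#'
#' @param x either a block correlation matrix or a units x indicators data
#'   matrix for one block.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  is_cor <- nrow(x) == ncol(x) && all(abs(diag(x) - 1) < 1e-8) &&
    isTRUE(all.equal(x, t(x), tolerance = 1e-8))
  R <- if (is_cor) x else stats::cor(x)
  p <- ncol(R)
  if (p == 1L) return(1)
  off <- sum(R) - p
  (off / (p + off)) * p / (p - 1)
}

#' Average variance extracted
#'
#' @param loadings vector of standardized outer loadings of one reflective
#'   block.
#' @param error_var per-indicator measurement-error variances; defaults to
#'   \code{1 - loadings^2}, the value implied by standardized indicators.
#' @return scalar in \[0, 1\]: \eqn{\sum\lambda^2 / (\sum\lambda^2 +
#'   \sum\mathrm{var}(\epsilon))}.
#' @export
ave <- function(loadings, error_var = 1 - loadings^2) {
  if (!length(loadings)) stop("empty block: no loadings")
  s2 <- sum(loadings^2)
  if (s2 + sum(error_var) == 0) return(0)
  s2 / (s2 + sum(error_var))
}

#' Composite reliability
#'
#' @inheritParams ave
#' @return scalar in \[0, 1\]: \eqn{(\sum\lambda)^2 / ((\sum\lambda)^2 +
#'   \sum\mathrm{var}(\epsilon))}.
#' @export
composite_reliability <- function(loadings, error_var = 1 - loadings^2) {
  if (!length(loadings)) stop("empty block: no loadings")
  s <- sum(loadings)^2
  if (s + sum(error_var) == 0) return(0)
  s / (s + sum(error_var))
}

#' Variance inflation factors
#'
#' For each predictor column, one over one minus the R-squared of its
#' regression on the remaining predictors.  Perfectly collinear predictors
#' are reported as \code{Inf} with a warning.
#'
#' @param x units x predictors numeric matrix, at least two columns.
#' @return named vector of VIFs (all \eqn{\ge 1}).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("VIF needs at least two predictor columns")
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(out)))
    warning("perfect collinearity: VIF reported as Inf")
  stats::setNames(out, colnames(x))
}

#' Q-squared predictive relevance
#'
#' One minus the product of \eqn{(1 - R^2_j)} over the endogenous
#' equations.  Greater than zero indicates the exogenous side of the model
#' has predictive relevance for the endogenous side.
#'
#' @param r2 vector of per-equation R-squared values, each in \[0, 1\].
#' @return scalar Q-squared.
#' @examples
#' q_squared(c(0.148, 0.686, 0.078))  # 0.753
#' @export
q_squared <- function(r2) {
  r2 <- as.numeric(r2)
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1))
    stop("every R-squared must lie in [0, 1]")
  1 - prod(1 - r2)
}

#' Goodness-of-fit index
#'
#' Geometric mean of average communality and average structural R-squared.
#' \code{type = "average"} averages communalities within each block first
#' and then across blocks; \code{type = "pooled"} pools all indicators
#' (each indicator's squared correlation with its own latent score divided
#' by the total indicator count), the form used inside the REBUS closeness
#' machinery.  The two coincide when all blocks have the same size.
#'
#' @param fit a [pls_path()] fit.
#' @param type \code{"average"} or \code{"pooled"}.
#' @return scalar GoF in \[0, 1\].
#' @export
gof <- function(fit, type = c("average", "pooled")) {
  stopifnot(inherits(fit, "plspath"))
  type <- match.arg(type)
  m <- fit$model
  mean_com <- if (type == "pooled") mean(fit$communalities)
  else mean(vapply(m$latents, function(l)
    mean(fit$communalities[m$blocks[[l]]]), numeric(1)))
  sqrt(mean_com * mean(fit$r_squared))
}

#' Cohen's f-squared effect size for a structural path
#'
#' The change in the dependent equation's R-squared when the predictor is
#' dropped, scaled by one minus the full R-squared.  Both regressions are
#' run on the fitted latent scores, so a predictor whose coefficient is
#' zero has exactly zero effect size and a single-predictor equation
#' reduces to \eqn{R^2/(1-R^2)}.
#'
#' @param fit a [pls_path()] fit.
#' @param from,to latent names of the structural edge.
#' @return scalar f-squared; \code{Inf} with a warning when the full
#'   equation is saturated (\eqn{R^2 = 1}).
#' @export
f_squared <- function(fit, from, to) {
  stopifnot(inherits(fit, "plspath"))
  m <- fit$model
  if (!(to %in% m$latents) || !(from %in% m$latents) ||
      m$inner[to, from] != 1)
    stop("no structural path ", .edge_label(from, to), " in the model")
  r2_full <- fit$r_squared[[to]]
  others <- setdiff(m$latents[m$inner[to, ] == 1], from)
  r2_red <- if (!length(others)) 0 else {
    y <- fit$scores[, to]
    Yp <- fit$scores[, others, drop = FALSE]
    res <- stats::lm.fit(Yp, y)$residuals
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  if (r2_full > 1 - 1e-12) {
    warning("saturated equation (R-squared = 1): f-squared is infinite")
    return(Inf)
  }
  (r2_full - r2_red) / (1 - r2_full)
}

#' Cross-loadings
#'
#' Correlation of every indicator with every latent score; an indicator
#' should correlate most strongly with its own latent.
#'
#' @param fit a [pls_path()] fit.
#' @return indicators x latents correlation matrix.
#' @export
cross_loadings <- function(fit) {
  stopifnot(inherits(fit, "plspath"))
  stats::cor(fit$data_std, fit$scores)
}

#' Full model-quality report
#'
#' Assembles the measurement-model indices (loading, communality, AVE,
#' Cronbach's alpha, composite reliability per block), the structural
#' indices (R-squared and f-squared per path, VIF where an equation has
#' two or more predictors), Q-squared and the GoF index.  Conventional
#' cut-offs (loading > 0.5, alpha > 0.7, composite reliability > 0.6,
#' AVE > 0.5, VIF < 10, GoF > 0.36) are reported as flags, never enforced.
#'
#' @param fit a [pls_path()] fit.
#' @return object of class \code{pls_evaluation} with components
#'   \code{outer} (per-indicator table), \code{blocks} (per-latent table),
#'   \code{inner} (per-path table), \code{vif}, \code{q_squared},
#'   \code{gof}, \code{cross_loadings}.
#' @export
evaluate <- function(fit) {
  stopifnot(inherits(fit, "plspath"))
  m <- fit$model
  block_of <- stats::setNames(rep(m$latents, lengths(m$blocks)),
                              unlist(m$blocks))
  ind <- names(fit$loadings)
  outer <- data.frame(
    latent = block_of[ind], indicator = ind,
    loading = as.numeric(fit$loadings),
    communality = as.numeric(fit$communalities),
    valid = as.numeric(fit$loadings) > 0.5,
    row.names = NULL, stringsAsFactors = FALSE)

  blocks <- do.call(rbind, lapply(m$latents, function(l) {
    q <- m$blocks[[l]]
    lam <- fit$loadings[q]
    a <- if (length(q) == 1L) 1 else
      cronbach_alpha(fit$data_std[, q, drop = FALSE])
    data.frame(latent = l, n_indicators = length(q),
               ave = ave(lam), cronbach_alpha = a,
               composite_reliability = composite_reliability(lam),
               single_indicator = length(q) == 1L,
               stringsAsFactors = FALSE)
  }))
  blocks$reliable <- (blocks$composite_reliability > 0.6 &
                        (blocks$single_indicator | blocks$cronbach_alpha > 0.7))

  e <- model_edges(m)
  inner <- data.frame(
    path = .edge_label(e$from, e$to),
    coefficient = fit$path_coefficients[cbind(e$to, e$from)],
    r_squared = fit$r_squared[e$to],
    f_squared = mapply(function(f, t) f_squared(fit, f, t), e$from, e$to),
    row.names = NULL, stringsAsFactors = FALSE)

  vifs <- list()
  for (j in m$endogenous) {
    P <- m$latents[m$inner[j, ] == 1]
    if (length(P) >= 2L)
      vifs[[j]] <- vif(fit$scores[, P, drop = FALSE])
  }

  structure(list(
    outer = outer, blocks = blocks, inner = inner, vif = vifs,
    q_squared = q_squared(fit$r_squared),
    gof = gof(fit), gof_pooled = gof(fit, "pooled"),
    cross_loadings = cross_loadings(fit)), class = "pls_evaluation")
}

#' @export
print.pls_evaluation <- function(x, digits = 3, ...) {
  cat("Measurement model:\n")
  print(cbind(x$outer[, c("latent", "indicator")],
              round(x$outer[, c("loading", "communality")], digits),
              valid = x$outer$valid), row.names = FALSE)
  cat("\nBlock reliability:\n")
  print(cbind(x$blocks[, c("latent", "n_indicators")],
              round(x$blocks[, c("ave", "cronbach_alpha",
                                 "composite_reliability")], digits),
              reliable = x$blocks$reliable), row.names = FALSE)
  cat("\nStructural model:\n")
  print(cbind(x$inner[, "path", drop = FALSE],
              round(x$inner[, c("coefficient", "r_squared", "f_squared")],
                    digits)), row.names = FALSE)
  cat(sprintf("\nQ-squared = %.*f;  GoF = %.*f (%s 0.36 cut-off)\n",
              digits, x$q_squared, digits, x$gof,
              if (x$gof > 0.36) "above" else "below"))
  invisible(x)
}
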