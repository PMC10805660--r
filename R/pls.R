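#' Fit a PLS path model
#'
#' Estimates a partial least squares path model by the classic three-stage
#' alternating algorithm: (1) iterate outer weights and inner proxies until
#' the outer weights stabilise, (2) estimate the structural (inner) path
#' coefficients by ordinary least squares of each endogenous latent score on
#' its predecessors' scores, (3) recover location parameters (latent means
#' and structural intercepts) on the original measurement scale.
#'
#' Outer weights start at one within each block and are rescaled after every
#' update so that each latent score has unit sample variance.  Reflective
#' (Mode A) blocks update weights proportionally to the covariance between
#' each indicator and the block's inner proxy; formative (Mode B) blocks use
#' the multiple-regression coefficients of the proxy on the block.  The
#' textbook Mode A expression divides by a term written as the variance of
#' the squared latent; it is computed here as the variance of the latent
#' itself, the standard Mode A estimator (on unit-variance proxies the two
#' normalisations coincide up to the final rescaling).
#'
#' Sign indeterminacy is resolved per block: weights are flipped so that the
#' sum of correlations between the block's indicators and its score is
#' non-negative.
#'
#' @param data data frame or matrix containing all indicator columns of
#'   \code{model} (extra columns are ignored).
#' @param model a [path_model()].
#' @param scheme inner weighting scheme; defaults to the model's.
#' @param tol convergence tolerance: the iteration stops when the largest
#'   absolute change in any (unit-variance-normalised) outer weight falls
#'   below \code{tol}.
#' @param max_iter maximum number of weight iterations.
#' @param standardize when \code{TRUE} (default) indicators are centred and
#'   scaled to unit sample variance before fitting.  \code{FALSE} is used
#'   internally by REBUS, where segment-local models must be expressed on
#'   the globally standardized scale: the input is used as-is and scores
#'   are not re-centred.
#' @return an object of class \code{plspath} with components
#'   \describe{
#'     \item{weights}{named outer-weight vector (unit-variance score scale)}
#'     \item{loadings}{named vector, correlation of each indicator with its
#'       block's score}
#'     \item{communalities}{squared loadings}
#'     \item{scores}{units x latents score matrix, each column standardized}
#'     \item{path_coefficients}{latents x latents matrix, entry (j, i) is
#'       the coefficient of latent i in the equation of latent j}
#'     \item{r_squared}{per-endogenous coefficient of determination}
#'     \item{inner_residuals}{units x endogenous residual matrix}
#'     \item{outer_residuals}{units x indicators residual matrix}
#'     \item{means, inner_intercepts}{location parameters on the original
#'       scale}
#'     \item{n_iterations, converged}{iteration diagnostics}
#'   }
#' @examples
#' sim <- simulate_pls_data(nutrition_model(), n = 216,
#'                          segments = nutrition_global_spec(), seed = 1)
#' fit <- pls_path(sim$data, nutrition_model())
#' fit
#' coef(fit)
#' @export
pls_path <- function(data, model, scheme = model$scheme, tol = 1e-6,
                     max_iter = 300, standardize = TRUE) {
  stopifnot(inherits(model, "path_model"))
  scheme <- match.arg(scheme, c("centroid", "factor", "path"))
  X0 <- .as_indicator_matrix(data, model)
  n <- nrow(X0)
  if (n < 3L) stop("need at least 3 units to fit a PLS path model")
  lat <- model$latents
  J <- length(lat)

  if (standardize) {
    z <- .zscore(X0)
    X <- z$values
    center <- z$center
    scl <- z$scale
  } else {
    X <- X0
    center <- stats::setNames(rep(0, ncol(X0)), colnames(X0))
    scl <- stats::setNames(rep(1, ncol(X0)), colnames(X0))
  }

  bidx <- lapply(model$blocks, function(ind) match(ind, colnames(X)))
  block_of <- stats::setNames(rep(lat, lengths(model$blocks)),
                              unlist(model$blocks))

  normalize_w <- function(v, Xb, block) {
    s <- as.vector(Xb %*% v)
    ssd <- stats::sd(s)
    if (!is.finite(ssd) || ssd < 1e-12)
      stop("degenerate latent score for block '", block,
           "': outer weights collapsed to zero")
    v / ssd
  }
  w <- lapply(lat, function(l)
    normalize_w(rep(1, length(bidx[[l]])), X[, bidx[[l]], drop = FALSE], l))
  names(w) <- lat
  scores_of <- function(w) {
    Y <- vapply(lat, function(l) as.vector(X[, bidx[[l]], drop = FALSE] %*% w[[l]]),
                numeric(n))
    colnames(Y) <- lat
    Y
  }
  Y <- scores_of(w)

  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    E <- inner_weights(Y, model, scheme)
    Z <- Y %*% t(E)
    w_new <- vector("list", J)
    names(w_new) <- lat
    for (l in lat) {
      Xb <- X[, bidx[[l]], drop = FALSE]
      zsd <- stats::sd(Z[, l])
      if (!is.finite(zsd) || zsd < 1e-12)
        stop("degenerate inner proxy for latent '", l,
             "' (is the latent connected in the structural model?)")
      zl <- Z[, l] / zsd
      v <- if (model$modes[[l]] == "reflective")
        outer_weights_mode_a(Xb, zl, normalize = FALSE)
      else
        outer_weights_mode_b(Xb, zl, normalize = FALSE)
      w_new[[l]] <- normalize_w(v, Xb, l)
    }
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    Y <- scores_of(w)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  # sign policy: sum of indicator-score correlations non-negative per block
  for (l in lat) {
    sgn <- sum(stats::cor(X[, bidx[[l]], drop = FALSE], Y[, l]))
    if (is.finite(sgn) && sgn < 0) {
      w[[l]] <- -w[[l]]
      Y[, l] <- -Y[, l]
    }
  }

  indicators <- unlist(model$blocks, use.names = FALSE)
  loadings <- vapply(indicators, function(q)
    stats::cor(X[, q], Y[, block_of[[q]]]), numeric(1))
  communalities <- loadings^2

  # structural coefficients: per-equation OLS on the latent scores
  B <- matrix(0, J, J, dimnames = list(lat, lat))
  endo <- model$endogenous
  for (j in endo) {
    P <- lat[model$inner[j, ] == 1]
    Yp <- Y[, P, drop = FALSE]
    cf <- tryCatch(solve(crossprod(Yp), crossprod(Yp, Y[, j])),
                   error = function(e)
                     stop("singular inner regression for equation '", j,
                          "': collinear predecessor scores", call. = FALSE))
    B[j, P] <- as.vector(cf)
  }

  inner_res <- vapply(endo, function(j)
    Y[, j] - as.vector(Y %*% B[j, ]), numeric(n))
  inner_res <- matrix(inner_res, nrow = n, dimnames = list(rownames(X0), endo))
  r2 <- vapply(endo, function(j) {
    y <- Y[, j]
    1 - sum(inner_res[, j]^2) / sum((y - mean(y))^2)
  }, numeric(1))

  outer_res <- X
  for (q in indicators)
    outer_res[, q] <- X[, q] - loadings[[q]] * Y[, block_of[[q]]]

  # location parameters on the original scale: block weights normalised to
  # sum one applied to the indicator means, then the structural identity at
  # the means for the intercepts
  means <- vapply(lat, function(l) {
    v <- w[[l]]
    s <- sum(v)
    if (abs(s) < 1e-12) return(NA_real_)
    sum((v / s) * center[bidx[[l]]])
  }, numeric(1))
  intercepts <- vapply(endo, function(j)
    means[[j]] - sum(B[j, ] * means), numeric(1))

  structure(list(
    model = model, scheme = scheme,
    weights = stats::setNames(unlist(w, use.names = FALSE), indicators),
    loadings = loadings, communalities = communalities,
    scores = Y, path_coefficients = B, r_squared = r2,
    inner_residuals = inner_res, outer_residuals = outer_res,
    means = means, inner_intercepts = intercepts,
    n_iterations = iter, converged = converged,
    data_std = X, center = center, scale = scl,
    n = n, standardized_input = !standardize), class = "plspath")
}

#' Inner weighting matrix
#'
#' Computes the latent-by-latent inner weights used to form each latent's
#' inner proxy.  Non-adjacent pairs always get weight zero.  Under the
#' centroid scheme adjacent weights are the sign of the score correlation;
#' under the factor scheme the correlation itself; under the path scheme
#' predecessors enter with their multiple-regression coefficients and
#' successors with correlations.
#'
#' @param scores units x latents score matrix (columns named by latent).
#' @param model a [path_model()].
#' @param scheme weighting scheme.
#' @return latents x latents matrix \code{E}; the proxy of latent \code{j}
#'   is \code{scores \%*\% E[j, ]}.
#' @export
inner_weights <- function(scores, model, scheme = model$scheme) {
  scheme <- match.arg(scheme, c("centroid", "factor", "path"))
  lat <- model$latents
  A <- (model$inner + t(model$inner)) > 0
  C <- suppressWarnings(stats::cor(scores[, lat, drop = FALSE]))
  C[!is.finite(C)] <- 0
  E <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  if (scheme == "centroid") {
    E[A] <- sign(C[A])
  } else {
    E[A] <- C[A]
    if (scheme == "path") {
      for (j in lat) {
        P <- which(model$inner[j, ] == 1)
        if (length(P))
          E[j, P] <- as.vector(solve(C[P, P, drop = FALSE], C[P, j]))
      }
    }
  }
  E
}

#' Outer weights for a reflective (Mode A) block
#'
#' Mode A weights are proportional to the covariance of each indicator with
#' the block's inner proxy.
#'
#' @param x_block units x indicators matrix of one block.
#' @param proxy inner-proxy vector for the block's latent.
#' @param normalize rescale the weights so the resulting score has unit
#'   sample variance (default).
#' @return weight vector, one entry per indicator column.
#' @export
outer_weights_mode_a <- function(x_block, proxy, normalize = TRUE) {
  x_block <- as.matrix(x_block)
  if (stats::sd(proxy) < 1e-12) stop("zero-variance inner proxy")
  v <- as.vector(stats::cov(x_block, proxy))
  if (all(abs(v) < 1e-12))
    stop("proxy is uncorrelated with every indicator in the block: ",
         "degenerate (all-zero) outer weights")
  if (normalize) v <- v / stats::sd(as.vector(x_block %*% v))
  stats::setNames(v, colnames(x_block))
}

#' Outer weights for a formative (Mode B) block
#'
#' Mode B weights are the multiple-regression coefficients of the inner
#' proxy on the block's indicators.
#'
#' @inheritParams outer_weights_mode_a
#' @return weight vector, one entry per indicator column.
#' @export
outer_weights_mode_b <- function(x_block, proxy, normalize = TRUE) {
  x_block <- as.matrix(x_block)
  if (stats::sd(proxy) < 1e-12) stop("zero-variance inner proxy")
  S <- stats::cov(x_block)
  v <- tryCatch(as.vector(solve(S, stats::cov(x_block, proxy))),
                error = function(e)
                  stop("singular block covariance: formative weights are ",
                       "not identified", call. = FALSE))
  if (all(abs(v) < 1e-12))
    stop("proxy is uncorrelated with every indicator in the block: ",
         "degenerate (all-zero) outer weights")
  if (normalize) v <- v / stats::sd(as.vector(x_block %*% v))
  stats::setNames(v, colnames(x_block))
}

#' Location parameters of a fitted model
#'
#' Latent means are the block outer weights, normalised to sum to one,
#' applied to the indicator means on the original scale; structural
#' intercepts follow from evaluating each inner equation at the latent
#' means.  A single-indicator latent therefore has mean equal to its
#' indicator's sample mean.
#'
#' @param fit a [pls_path()] fit.
#' @return list with components \code{means} (per latent) and
#'   \code{intercepts} (per endogenous latent).
#' @export
location_parameters <- function(fit) {
  stopifnot(inherits(fit, "plspath"))
  list(means = fit$means, intercepts = fit$inner_intercepts)
}

#' @export
print.plspath <- function(x, digits = 3, ...) {
  cat(sprintf(
    "PLS path model fit: %d units, %d latents, %d indicators (%s scheme)\n",
    x$n, length(x$model$latents), length(x$loadings), x$scheme))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  e <- model_edges(x$model)
  cat("Path coefficients:\n")
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s: %.*f\n", .edge_label(e$from[i], e$to[i]), digits,
                x$path_coefficients[e$to[i], e$from[i]]))
  cat("R-squared:",
      paste(sprintf("%s = %.*f", names(x$r_squared), digits, x$r_squared),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.plspath <- function(object, ...) {
  e <- model_edges(object$model)
  stats::setNames(object$path_coefficients[cbind(e$to, e$from)],
                  .edge_label(e$from, e$to))
}

#' @param type \code{"inner"} for structural residuals (units x endogenous)
#'   or \code{"outer"} for measurement residuals (units x indicators).
#' @rdname pls_path
#' @export
residuals.plspath <- function(object, type = c("inner", "outer"), ...) {
  type <- match.arg(type)
  if (type == "inner") object$inner_residuals else object$outer_residuals
}

#' @export
fitted.plspath <- function(object, ...) {
  endo <- object$model$endogenous
  object$scores[, endo, drop = FALSE] - object$inner_residuals
}

#' Predict latent scores for new units
#'
#' Applies the fitted outer weights (after the training-sample centring and
#' scaling) to new indicator data, and propagates the structural equations
#' to give model-implied predictions of each endogenous score.
#'
#' @param object a [pls_path()] fit.
#' @param newdata data frame with the model's indicator columns; defaults
#'   to the training data.
#' @param ... unused.
#' @return list with \code{scores} (weighted composite scores) and
#'   \code{predicted} (structural predictions for endogenous latents).
#' @export
predict.plspath <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data_std
  else {
    x0 <- .as_indicator_matrix(newdata, object$model)
    sweep(sweep(x0, 2L, object$center[colnames(x0)], "-"), 2L,
          object$scale[colnames(x0)], "/")
  }
  lat <- object$model$latents
  W <- matrix(0, ncol(X), length(lat),
              dimnames = list(colnames(X), lat))
  for (l in lat)
    W[object$model$blocks[[l]], l] <- object$weights[object$model$blocks[[l]]]
  S <- X %*% W
  endo <- object$model$endogenous
  pred <- S %*% t(object$path_coefficients)[, endo, drop = FALSE]
  list(scores = S, predicted = pred)
}

#' @export
plot.plspath <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$loadings, las = 2, main = "Outer loadings",
                    ylab = "loading", ylim = c(min(0, x$loadings), 1))
  graphics::abline(h = 0.5, lty = 2)
  cf <- coef(x)
  graphics::barplot(cf, las = 2, main = "Path coefficients",
                    ylab = "coefficient")
  invisible(x)
}

#' @export
summary.plspath <- function(object, ...) {
  ev <- evaluate(object)
  structure(list(fit = object, evaluation = ev), class = "summary.plspath")
}

#' @export
print.summary.plspath <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$evaluation)
  invisible(x)
}
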