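#' Bootstrap inference for loadings and path coefficients
#'
#' Resamples units with replacement, refits the PLS path model on each
#' resample, and summarises the replicate distributions of the outer
#' loadings and inner path coefficients.  Each replicate is sign-aligned to
#' the original fit (any block whose replicate score correlates negatively
#' with the original score on the resampled units is flipped, together with
#' the path coefficients touching it) so that the indeterminate sign of PLS
#' scores cannot inflate the standard errors.  The t statistic is the
#' original estimate divided by the bootstrap standard error, referred to a
#' t distribution with \eqn{n - 1} degrees of freedom.
#'
#' @param data indicator data (data frame or matrix).
#' @param model a [path_model()].
#' @param B number of bootstrap resamples (default 500).
#' @param seed integer seed; the triple (data, model, B, seed) fully
#'   determines the result.
#' @param ... further arguments to [pls_path()].
#' @return object of class \code{pls_boot}: \code{original}, \code{mean},
#'   \code{standard_error}, \code{t_statistic}, \code{p_value} (named
#'   per-parameter vectors), \code{replicates} (B x parameters matrix),
#'   \code{n_failed}, \code{df}, \code{seed}.
#' @export
bootstrap_pls <- function(data, model, B = 500, seed = NULL, ...) {
  if (B < 2) stop("B must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  fit0 <- pls_path(data, model, ...)
  n <- fit0$n
  orig <- .param_vector(fit0)
  lat <- model$latents
  e <- model_edges(model)
  X <- as.data.frame(data)

  reps <- matrix(NA_real_, B, length(orig),
                 dimnames = list(NULL, names(orig)))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_b <- tryCatch(pls_path(X[idx, , drop = FALSE], model, ...),
                      error = function(e) NULL)
    if (is.null(fit_b) || !fit_b$converged) { failed <- failed + 1L; next }
    # sign alignment against the original scores of the resampled units
    s <- vapply(lat, function(l) {
      r <- suppressWarnings(stats::cor(fit_b$scores[, l],
                                       fit0$scores[idx, l]))
      if (!is.finite(r) || r >= 0) 1 else -1
    }, numeric(1))
    lam <- fit_b$loadings * s[.block_of(model)[names(fit_b$loadings)]]
    pc <- fit_b$path_coefficients[cbind(e$to, e$from)] * s[e$to] * s[e$from]
    reps[b, ] <- c(lam, pc)
  }
  if (failed > 0.2 * B)
    stop(sprintf(
      "bootstrap failed: %d of %d replicates did not converge", failed, B))
  ok <- stats::complete.cases(reps)
  reps <- reps[ok, , drop = FALSE]
  se <- apply(reps, 2L, stats::sd)
  tstat <- ifelse(se > 0, orig / se, ifelse(abs(orig) > 0, Inf, 0))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  structure(list(
    original = orig, mean = colMeans(reps), standard_error = se,
    t_statistic = tstat, p_value = pval, replicates = reps,
    n_replicates = B, n_failed = failed, df = n - 1, seed = seed,
    model = model), class = "pls_boot")
}

.block_of <- function(model) {
  stats::setNames(rep(model$latents, lengths(model$blocks)),
                  unlist(model$blocks))
}

# loadings then path coefficients, stable naming
.param_vector <- function(fit) {
  e <- model_edges(fit$model)
  c(stats::setNames(as.numeric(fit$loadings),
                    paste0("loading: ", names(fit$loadings))),
    stats::setNames(fit$path_coefficients[cbind(e$to, e$from)],
                    paste0("path: ", .edge_label(e$from, e$to))))
}

#' Bootstrap significance table
#'
#' One row per parameter: original estimate, replicate mean, bootstrap
#' standard error, |t|, two-sided p-value, and the test decision at level
#' \code{alpha}.  The null is rejected only when |t| strictly exceeds the
#' critical value \eqn{t_{\alpha/2, n-1}}; a zero standard error with a
#' non-zero estimate is flagged \code{"degenerate, reject"}.
#'
#' @param boot a [bootstrap_pls()] result.
#' @param alpha significance level (default 0.05).
#' @return data frame mirroring the conventional PLS reporting layout
#'   (Original Sample, Sample Mean, STDEV, T Statistics, P Values,
#'   decision).
#' @export
hypothesis_table <- function(boot, alpha = 0.05) {
  stopifnot(inherits(boot, "pls_boot"))
  tcrit <- stats::qt(1 - alpha / 2, df = boot$df)
  degenerate <- boot$standard_error == 0 & abs(boot$original) > 0
  reject <- abs(boot$t_statistic) > tcrit
  decision <- ifelse(degenerate, "degenerate, reject",
                     ifelse(reject, "reject", "retain"))
  data.frame(
    parameter = names(boot$original),
    original = as.numeric(boot$original),
    mean = as.numeric(boot$mean),
    std_error = as.numeric(boot$standard_error),
    t_statistic = abs(as.numeric(boot$t_statistic)),
    p_value = as.numeric(boot$p_value),
    decision = decision,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pls_boot <- function(x, digits = 3, ...) {
  cat(sprintf(
    "PLS bootstrap: %d replicates (%d failed), t reference df = %d\n",
    x$n_replicates, x$n_failed, x$df))
  tab <- hypothesis_table(x)
  tab[, 2:6] <- round(tab[, 2:6], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
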