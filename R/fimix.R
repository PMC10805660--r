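#' FIMIX-PLS: finite mixture of inner-model regressions
#'
#' Fits a K-component Gaussian mixture over the structural (inner) model,
#' taking the latent scores of a converged global PLS fit as given.  Each
#' endogenous equation is a regression of its latent score on its
#' predecessors' scores; within component k the equations have their own
#' coefficients and their own diagonal error variances.  Estimation is by
#' the EM algorithm: the E-step computes posterior membership
#' probabilities proportional to the mixing proportion times the component
#' density of the unit's endogenous scores, the M-step updates mixing
#' proportions, weighted-least-squares coefficients and error variances.
#' The best of \code{n_restarts} random initialisations (by final
#' log-likelihood) is kept; an optional hard partition (e.g. from REBUS or
#' Ward) supplies one extra initialisation.
#'
#' Mixing proportions are floored at \code{1e-4} during EM to prevent
#' degenerate collapse (a component still at the floor on convergence is
#' flagged); a component error variance collapsing below \code{1e-8}
#' aborts that restart.  Components are canonicalised by descending mixing
#' proportion, and the hard assignment is the posterior argmax with ties
#' broken toward the larger-proportion component.
#'
#' @param x a [pls_path()] fit, or a units x latents score matrix with
#'   columns named by the model's latents.
#' @param model a [path_model()] (defines the inner equations).
#' @param K number of components (\eqn{\ge 1}).
#' @param seed integer seed; fully determines the fit together with the
#'   scores, K and the restart count.
#' @param n_restarts random initialisations (default 10).
#' @param tol EM stops when the log-likelihood improves by less than
#'   \code{tol} (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param init_assignment optional integer vector of segment labels used
#'   as one additional (soft) initialisation.
#' @return object of class \code{fimix}: \code{mixing_proportions},
#'   \code{coefficients} (list of per-component path matrices),
#'   \code{residual_variances} (components x equations),
#'   \code{posteriors}, \code{assignment}, \code{log_likelihood},
#'   \code{em_trace}, \code{n_parameters}, \code{aic}, \code{bic},
#'   \code{caic}, \code{entropy}, \code{K}, \code{seed},
#'   \code{floored_component}.
#' @export
fimix <- function(x, model, K, seed = NULL, n_restarts = 10, tol = 1e-6,
                  max_iter = 500, init_assignment = NULL) {
  if (K < 1) stop("K must be at least 1")
  S <- if (inherits(x, "plspath")) x$scores else as.matrix(x)
  lat <- model$latents
  if (!all(lat %in% colnames(S)))
    stop("score matrix lacks latent column(s): ",
         paste(setdiff(lat, colnames(S)), collapse = ", "))
  S <- S[, lat, drop = FALSE]
  n <- nrow(S)
  endo <- model$endogenous
  eqs <- lapply(endo, function(j) lat[model$inner[j, ] == 1])
  names(eqs) <- endo
  R <- sum(lengths(eqs))  # predictors across the inner equations
  if (K > floor(n / 2)) stop("K too large for ", n, " units")
  if (!is.null(seed)) set.seed(seed)

  rho_floor <- 1e-4
  psi_floor <- 1e-8

  run_em <- function(P) {
    trace <- numeric(0)
    ll_prev <- -Inf
    beta <- psi <- NULL
    for (it in seq_len(max_iter)) {
      # M-step
      rho <- pmax(colMeans(P), rho_floor)
      rho <- rho / sum(rho)
      beta <- vector("list", K)
      psi <- matrix(NA_real_, K, length(endo),
                    dimnames = list(NULL, endo))
      for (k in seq_len(K)) {
        bk <- matrix(0, length(lat), length(lat),
                     dimnames = list(lat, lat))
        wk <- P[, k]
        for (j in endo) {
          Xj <- S[, eqs[[j]], drop = FALSE]
          y <- S[, j]
          XtW <- t(Xj * wk)
          cf <- tryCatch(solve(XtW %*% Xj, XtW %*% y),
                         error = function(e) NULL)
          if (is.null(cf)) return(NULL)
          bk[j, eqs[[j]]] <- as.vector(cf)
          res <- y - as.vector(Xj %*% cf)
          v <- sum(wk * res^2) / sum(wk)
          if (!is.finite(v) || v < psi_floor) return(NULL)
          psi[k, j] <- v
        }
        beta[[k]] <- bk
      }
      # E-step
      logf <- matrix(0, n, K)
      for (k in seq_len(K)) for (j in endo) {
        mu <- as.vector(S %*% beta[[k]][j, ])
        logf[, k] <- logf[, k] +
          stats::dnorm(S[, j], mu, sqrt(psi[k, j]), log = TRUE)
      }
      lp <- sweep(logf, 2L, log(rho), "+")
      mx <- apply(lp, 1L, max)
      lse <- mx + log(rowSums(exp(lp - mx)))
      ll <- sum(lse)
      P <- exp(lp - lse)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
      ll_prev <- ll
    }
    list(ll = ll, P = P, rho = rho, beta = beta, psi = psi, trace = trace)
  }

  inits <- lapply(seq_len(max(1L, n_restarts)), function(r) {
    P <- matrix(stats::rexp(n * K), n, K)
    P / rowSums(P)
  })
  if (!is.null(init_assignment)) {
    stopifnot(length(init_assignment) == n)
    P <- matrix(if (K > 1) 0.1 / (K - 1) else 1, n, K)
    P[cbind(seq_len(n), pmin(as.integer(init_assignment), K))] <-
      if (K > 1) 0.9 else 1
    inits <- c(inits, list(P))
  }
  if (K == 1L) inits <- inits[1]  # deterministic collapse

  best <- NULL
  for (P0 in inits) {
    out <- run_em(P0)
    if (is.null(out)) next
    if (is.null(best) || out$ll > best$ll) best <- out
  }
  if (is.null(best))
    stop("all EM restarts collapsed (variance below 1e-8); ",
         "reduce K or supply more data")

  # canonical order: descending mixing proportion
  ord <- order(best$rho, decreasing = TRUE)
  rho <- best$rho[ord]
  beta <- best$beta[ord]
  psi <- best$psi[ord, , drop = FALSE]
  P <- best$P[, ord, drop = FALSE]
  colnames(P) <- paste0("segment", seq_len(K))

  n_par <- fimix_n_parameters(K, R)
  crit <- information_criteria(best$ll, n_par, n)
  structure(list(
    K = K, mixing_proportions = rho, coefficients = beta,
    residual_variances = psi, posteriors = P,
    assignment = max.col(P, ties.method = "first"),
    log_likelihood = best$ll, em_trace = best$trace,
    n_parameters = n_par, aic = crit[["AIC"]], bic = crit[["BIC"]],
    caic = crit[["CAIC"]],
    entropy = if (K > 1) entropy_criterion(P) else NA_real_,
    floored_component = any(rho <= rho_floor * K),
    n = n, model = model, seed = seed,
    n_restarts = length(inits)), class = "fimix")
}

#' Number of free FIMIX parameters
#'
#' \eqn{N_K = (K - 1) + K R}: the free mixing proportions plus the
#' per-component inner-model regression coefficients.  \code{R} counts the
#' predictor variables across the inner equations; set
#' \code{count_variances = TRUE} to also count each component's
#' per-equation error variances.
#'
#' @param K number of components (\eqn{\ge 1}).
#' @param R number of predictor variables in the inner model.
#' @param n_equations number of endogenous equations (needed only when
#'   \code{count_variances} is \code{TRUE}).
#' @param count_variances include error-variance parameters (default
#'   \code{FALSE}, the literal predictor count).
#' @return integer parameter count.
#' @export
fimix_n_parameters <- function(K, R, n_equations = 0,
                               count_variances = FALSE) {
  if (K < 1) stop("K must be at least 1")
  if (R < 0) stop("R must be non-negative")
  extra <- if (count_variances) K * n_equations else 0
  (K - 1) + K * R + extra
}

#' Information criteria for mixture-order selection
#'
#' \code{AIC = -2 lnL + 2 N}, \code{BIC = -2 lnL + ln(I) N},
#' \code{CAIC = -2 lnL + (ln(I) + 1) N}, where \code{N} is the free
#' parameter count and \code{I} the number of observations (so
#' \code{CAIC - BIC = N} identically).
#'
#' @param lnL maximised log-likelihood.
#' @param n_parameters free parameter count (e.g.
#'   [fimix_n_parameters()]).
#' @param I number of observations (\eqn{\ge 1}).
#' @return named vector \code{c(AIC, BIC, CAIC)}.
#' @export
information_criteria <- function(lnL, n_parameters, I) {
  if (I < 1) stop("I must be at least 1")
  c(AIC = -2 * lnL + 2 * n_parameters,
    BIC = -2 * lnL + log(I) * n_parameters,
    CAIC = -2 * lnL + (log(I) + 1) * n_parameters)
}

#' Normed entropy criterion (EN)
#'
#' \eqn{EN = 1 - \sum_i \sum_k -P_{ik} \ln P_{ik} / (I \ln K)}, with
#' \eqn{0 \ln 0 := 0}.  EN is 1 for perfectly crisp (0/1) posteriors and 0
#' for uniform ones; values near 1 indicate a well-separated segmentation.
#'
#' @param posteriors units x K matrix of membership probabilities, rows
#'   summing to one, \eqn{K \ge 2}.
#' @return scalar in \[0, 1\], or \code{NA} for \eqn{K = 1} (undefined).
#' @export
entropy_criterion <- function(posteriors) {
  P <- as.matrix(posteriors)
  K <- ncol(P)
  if (K < 2L) return(NA_real_)
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6))
    stop("posteriors must be a row-stochastic matrix")
  P <- pmin(pmax(P, 0), 1)
  h <- -P * log(P)
  h[P == 0] <- 0
  1 - sum(h) / (nrow(P) * log(K))
}

#' Choose the number of FIMIX components
#'
#' Fits [fimix()] for each K in \code{K_range} (a K = 1 baseline row is
#' always included) and tabulates log-likelihood, AIC, BIC, CAIC and EN.
#' The recommendation is the K with maximal normed entropy, the rule that
#' favours the crispest segmentation; the likelihood criteria are reported
#' alongside.
#'
#' @param x a [pls_path()] fit or score matrix (see [fimix()]).
#' @param model a [path_model()].
#' @param K_range candidate component counts (default \code{2:5}).
#' @param seed integer seed; each K uses a sub-seed derived from it.
#' @param ... forwarded to [fimix()].
#' @return object of class \code{fimix_selection}: \code{criteria} (one
#'   row per K), \code{recommended_K}, \code{fits}.
#' @export
fimix_select <- function(x, model, K_range = 2:5, seed = NULL, ...) {
  K_all <- sort(unique(c(1L, as.integer(K_range))))
  fits <- lapply(K_all, function(K)
    fimix(x, model, K,
          seed = if (is.null(seed)) NULL else seed + K, ...))
  criteria <- do.call(rbind, lapply(fits, function(f)
    data.frame(K = f$K, logLik = f$log_likelihood, AIC = f$aic,
               BIC = f$bic, CAIC = f$caic, EN = f$entropy)))
  cand <- criteria[criteria$K %in% K_range & !is.na(criteria$EN), ]
  rec <- if (nrow(cand)) cand$K[which.max(cand$EN)] else NA_integer_
  structure(list(criteria = criteria, recommended_K = rec, fits = fits),
            class = "fimix_selection")
}

#' @export
print.fimix_selection <- function(x, digits = 3, ...) {
  cat("FIMIX component-count selection (argmax EN):\n")
  tab <- x$criteria
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat("recommended K =", x$recommended_K, "\n")
  invisible(x)
}

#' @export
print.fimix <- function(x, digits = 3, ...) {
  cat(sprintf(
    "FIMIX-PLS: K = %d, lnL = %.*f, AIC = %.*f, BIC = %.*f, EN = %s\n",
    x$K, digits, x$log_likelihood, digits, x$aic, digits, x$bic,
    if (is.na(x$entropy)) "NA" else sprintf("%.*f", digits, x$entropy)))
  cat("mixing proportions:",
      paste(round(x$mixing_proportions, digits), collapse = ", "), "\n")
  e <- model_edges(x$model)
  tab <- data.frame(path = .edge_label(e$from, e$to))
  for (k in seq_len(x$K))
    tab[[paste0("segment", k)]] <-
      round(x$coefficients[[k]][cbind(e$to, e$from)], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
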