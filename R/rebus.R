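#' Ward agglomerative clustering
#'
#' Agglomerative hierarchical clustering under Ward's criterion: at each
#' step the two groups whose merger least increases the total within-group
#' sum of squared errors (SSE) are joined.  The merge topology is computed
#' by \code{stats::hclust(method = "ward.D2")} (exact Ward on Euclidean
#' distances); merge heights are reported as SSE increments
#' (\code{hclust} height squared over two, so two singletons \eqn{x, y}
#' merge at \eqn{\|x-y\|^2/2}).
#'
#' @param x units x features numeric matrix with at least two rows.
#' @return object of class \code{ward_tree}: \code{merge} and \code{order}
#'   as in [stats::hclust()], \code{height} (SSE increment per merge,
#'   nondecreasing), and the underlying \code{hclust} object.
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows to cluster")
  if (!all(is.finite(x))) stop("non-finite values in clustering features")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height^2 / 2,
                 order = hc$order, hclust = hc), class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat("Ward agglomerative tree over", nrow(x$merge) + 1L, "units;",
      "SSE merge increments range",
      sprintf("[%.4g, %.4g]\n", min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a Ward tree into G groups
#'
#' @param tree a [ward_cluster()] result.
#' @param G number of groups.
#' @return integer vector of group labels.
#' @export
cut_ward <- function(tree, G) {
  stopifnot(inherits(tree, "ward_tree"))
  unname(stats::cutree(tree$hclust, k = G))
}

# Feature matrix for the initial Ward partition: the global model's outer
# (communality) and inner (structural) residual columns, augmented with
# one gradient column per structural edge (predecessor score times the
# equation's residual — the unit's contribution to the normal equations).
# Raw residuals have segment-specific means when segments differ in level;
# the gradient columns additionally have segment-specific means when
# segments differ only in their path coefficients, where raw residuals are
# mean-zero in every segment and carry no location signal for Ward.  All
# columns are standardized so that blocks with many indicators cannot
# dominate the metric.
.residual_features <- function(fit) {
  e <- model_edges(fit$model)
  grad <- sign(fit$scores[, e$from, drop = FALSE]) *
    fit$inner_residuals[, e$to, drop = FALSE]
  colnames(grad) <- .edge_label(e$from, e$to)
  std <- function(f) {
    sds <- .col_sds(f)
    sds[sds < 1e-12] <- 1
    sweep(sweep(f, 2L, colMeans(f), "-"), 2L, sds, "/") / sqrt(ncol(f))
  }
  cbind(std(fit$outer_residuals), std(fit$inner_residuals),
        2 * std(grad))
}

#' Initial REBUS partition from the global model's residuals
#'
#' Ward-clusters the global fit's residual features (outer and inner
#' residual columns plus one slope-signature column per structural edge,
#' all standardized; see the methods vignette for why the raw residuals
#' alone cannot see slope heterogeneity) and cuts the tree into G groups.
#'
#' @param fit the global [pls_path()] fit.
#' @param G number of groups (\code{G = 1} puts every unit in one group,
#'   \code{G = n} gives every unit its own).
#' @return integer vector of group labels, one per unit.
#' @export
initial_partition <- function(fit, G) {
  stopifnot(inherits(fit, "plspath"))
  if (G > fit$n) stop("more groups than units (G = ", G, ", n = ",
                      fit$n, ")")
  if (G == 1) return(rep(1L, fit$n))
  cut_ward(ward_cluster(.residual_features(fit)), G)
}

#' Closeness-measure (CM) matrix
#'
#' For every unit and every candidate segment, the CM index is the product
#' of two normalised residual ratios computed under the segment's local
#' model: the unit's communality-weighted squared measurement residuals
#' over their segment average (with an \eqn{n_g - m_g - 1} degrees-of-
#' freedom correction), times the analogous R-squared-weighted squared
#' structural residual ratio.  Units fit a segment's model well when their
#' CM is small; REBUS reassigns each unit to its row-minimum segment.
#'
#' Residuals are evaluated against the globally standardized data for all
#' units under each local model, keeping CM values comparable across
#' segments.
#'
#' @param X globally standardized units x indicators matrix (model column
#'   order).
#' @param model a [path_model()].
#' @param local_fits list of per-segment [pls_path()] fits (fitted on the
#'   rows of \code{X} belonging to each segment, \code{standardize =
#'   FALSE}).
#' @param assignment integer segment label per unit (defines \eqn{n_g}).
#' @param mg how \eqn{m_g} is counted: \code{"parameters"} (paths plus
#'   loadings, default) or \code{"latents"} (number of latent variables).
#' @param scope denominator summation: \code{"segment"} (over units
#'   currently in the class, default) or \code{"all"} (over all units).
#' @return units x segments matrix of non-negative CM values.
#' @export
closeness_measure <- function(X, model, local_fits, assignment,
                              mg = c("parameters", "latents"),
                              scope = c("segment", "all")) {
  mg <- match.arg(mg)
  scope <- match.arg(scope)
  X <- as.matrix(X)
  n <- nrow(X)
  G <- length(local_fits)
  stopifnot(length(assignment) == n)
  indicators <- unlist(model$blocks, use.names = FALSE)
  block_of <- .block_of(model)
  endo <- model$endogenous
  m_g <- if (mg == "parameters") .n_model_parameters(model)
  else length(model$latents)

  CM <- matrix(NA_real_, n, G)
  for (g in seq_len(G)) {
    fit <- local_fits[[g]]
    n_g <- sum(assignment == g)
    dfc <- n_g - m_g - 1
    if (dfc <= 0)
      stop("segment ", g, " too small for the closeness-measure ",
           "correction (n_g - m_g - 1 <= 0; n_g = ", n_g, ", m_g = ",
           m_g, ")")
    # score every unit under segment g's outer weights
    W <- matrix(0, ncol(X), length(model$latents),
                dimnames = list(colnames(X), model$latents))
    for (l in model$latents)
      W[model$blocks[[l]], l] <- fit$weights[model$blocks[[l]]]
    S <- X %*% W
    com <- pmax(fit$communalities[indicators], 1e-12)
    E2 <- (X[, indicators, drop = FALSE] -
             S[, block_of[indicators], drop = FALSE] *
             rep(fit$loadings[indicators], each = n))^2
    num_out <- as.vector(E2 %*% (1 / com))
    B <- fit$path_coefficients
    Fres <- vapply(endo, function(j) S[, j] - as.vector(S %*% B[j, ]),
                   numeric(n))
    Fres <- matrix(Fres, nrow = n)
    r2 <- pmax(fit$r_squared[endo], 1e-12)
    num_in <- as.vector(Fres^2 %*% (1 / r2))
    idx <- if (scope == "segment") assignment == g else rep(TRUE, n)
    den_out <- sum(num_out[idx]) / dfc
    den_in <- sum(num_in[idx]) / dfc
    CM[, g] <- (num_out / den_out) * (num_in / den_in)
  }
  dimnames(CM) <- list(rownames(X), paste0("segment", seq_len(G)))
  CM
}

#' REBUS-PLS segmentation
#'
#' Response-based unit segmentation: starting from a Ward clustering of the
#' global model's standardized measurement and structural residuals, the
#' algorithm alternates between fitting a local PLS model in each segment
#' and reassigning every unit to the segment whose local model gives it the
#' smallest closeness measure ([closeness_measure()]).  Iteration stops
#' when the fraction of units changing segment falls below
#' \code{stop_fraction} (default 0.05\% of units, so effectively zero
#' changes at moderate n) or after \code{max_iter} passes.
#'
#' Ties in the row-minimum CM keep the unit in its current segment, which
#' promotes convergence of the composition-change criterion.  A segment
#' falling below the minimum estimable size aborts with an error naming
#' the iteration.
#'
#' @param data indicator data.
#' @param model a [path_model()].
#' @param G number of segments (\code{G = 1} reproduces the global fit).
#' @param scheme,tol passed to [pls_path()].
#' @param max_iter maximum reassignment passes (default 50).
#' @param stop_fraction composition-change stop rule (default 5e-4, i.e.
#'   0.05\%).
#' @param mg,scope forwarded to [closeness_measure()].
#' @param min_size minimum units per segment; defaults to
#'   \code{max(10, number of model parameters + 2)}.
#' @param on_small what to do when a reassignment pass would push a
#'   segment below \code{min_size}: \code{"shrink"} (default) keeps the
#'   segment at \code{min_size} by retaining the units with the smallest
#'   closeness measure for it, so a poor initial partition cannot collapse
#'   the iteration; \code{"fail"} aborts with an error naming the
#'   iteration.
#' @return object of class \code{rebus}: \code{assignment},
#'   \code{local_fits}, \code{cm_matrix}, \code{iteration_trace} (fraction
#'   reassigned per pass), \code{n_iterations}, \code{converged},
#'   \code{global_fit}, \code{gqi}, \code{n_segments}.
#' @export
rebus <- function(data, model, G, scheme = model$scheme, tol = 1e-6,
                  max_iter = 50, stop_fraction = 5e-4,
                  mg = "parameters", scope = "segment", min_size = NULL,
                  on_small = c("shrink", "fail")) {
  if (G < 1) stop("G must be at least 1")
  on_small <- match.arg(on_small)
  global <- pls_path(data, model, scheme = scheme, tol = tol)
  X <- global$data_std
  n <- nrow(X)
  min_size <- min_size %||% max(10, .n_model_parameters(model) + 2)
  if (G > n) stop("more segments than units (G = ", G, ", n = ", n, ")")

  fit_locals <- function(assignment) {
    lapply(seq_len(G), function(g)
      pls_path(X[assignment == g, , drop = FALSE], model, scheme = scheme,
               tol = tol, standardize = FALSE))
  }
  check_sizes <- function(assignment, iteration) {
    sizes <- tabulate(assignment, nbins = G)
    if (any(sizes < min_size))
      stop("segment ", which.min(sizes), " fell below the minimum size (",
           min_size, ") at iteration ", iteration,
           "; reduce G or relax min_size")
  }
  # keep every segment at min_size by retaining the units that fit it best
  enforce_sizes <- function(proposal, cm) {
    repeat {
      sizes <- tabulate(proposal, nbins = G)
      g <- which(sizes < min_size)[1]
      if (is.na(g)) return(proposal)
      movable <- which(proposal != g &
                       tabulate(proposal, nbins = G)[proposal] > min_size)
      need <- min_size - sizes[g]
      if (length(movable) < need)
        stop("cannot maintain minimum segment size ", min_size,
             " with G = ", G, " and n = ", length(proposal))
      take <- movable[order(cm[movable, g])][seq_len(need)]
      proposal[take] <- g
    }
  }

  if (G == 1L) {
    assignment <- rep(1L, n)
    local_fits <- list(global)
    cm <- closeness_measure(X, model, local_fits, assignment,
                            mg = mg, scope = scope)
    res <- structure(list(
      n_segments = 1L, assignment = assignment, local_fits = local_fits,
      cm_matrix = cm, iteration_trace = 0, n_iterations = 1L,
      converged = TRUE, global_fit = global, tree = NULL,
      min_size = min_size), class = "rebus")
    res$gqi <- group_quality_index(res)
    return(res)
  }

  tree <- ward_cluster(.residual_features(global))
  assignment <- cut_ward(tree, G)
  if (on_small == "fail") {
    check_sizes(assignment, 0L)
  } else {
    # top up deficient initial segments from the largest ones; the first
    # reassignment pass will redistribute these units anyway
    repeat {
      sizes <- tabulate(assignment, nbins = G)
      g <- which(sizes < min_size)[1]
      if (is.na(g)) break
      donors <- which(assignment == which.max(sizes))
      need <- min_size - sizes[g]
      if (length(donors) - need < min_size)
        stop("cannot maintain minimum segment size ", min_size,
             " with G = ", G, " and n = ", n)
      assignment[donors[seq_len(need)]] <- g
    }
  }

  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  local_fits <- NULL
  cm <- NULL
  repeat {
    iter <- iter + 1L
    local_fits <- fit_locals(assignment)
    cm <- closeness_measure(X, model, local_fits, assignment,
                            mg = mg, scope = scope)
    current <- cm[cbind(seq_len(n), assignment)]
    best <- do.call(pmin, lapply(seq_len(G), function(g) cm[, g]))
    proposal <- max.col(-cm, ties.method = "first")
    new_assignment <- ifelse(current <= best + 1e-12, assignment, proposal)
    if (on_small == "shrink")
      new_assignment <- enforce_sizes(new_assignment, cm)
    changed <- mean(new_assignment != assignment)
    trace <- c(trace, changed)
    if (changed < stop_fraction) { converged <- TRUE; break }
    if (on_small == "fail") check_sizes(new_assignment, iter)
    assignment <- new_assignment
    if (iter >= max_iter) break
  }

  res <- structure(list(
    n_segments = G, assignment = assignment, local_fits = local_fits,
    cm_matrix = cm, iteration_trace = trace, n_iterations = iter,
    converged = converged, global_fit = global, tree = tree,
    min_size = min_size), class = "rebus")
  res$gqi <- group_quality_index(res)
  res
}

#' Group quality index (GQI)
#'
#' Segment-size-weighted quality of a REBUS partition, in the same
#' geometric-mean pattern as the GoF index: the outer component is the
#' square root of the size-weighted mean pooled communality of the local
#' models, the inner component the square root of the size-weighted mean
#' structural R-squared, and the overall GQI is their product.  With a
#' single segment the GQI collapses to the global pooled GoF.
#'
#' @param result a [rebus()] result.
#' @return named vector \code{c(overall, outer, inner)}.
#' @export
group_quality_index <- function(result) {
  stopifnot(inherits(result, "rebus"))
  G <- result$n_segments
  sizes <- tabulate(result$assignment, nbins = G)
  wts <- sizes / sum(sizes)
  com_g <- vapply(result$local_fits, function(f)
    mean(f$communalities), numeric(1))
  r2_g <- vapply(result$local_fits, function(f)
    mean(f$r_squared), numeric(1))
  outer <- sqrt(sum(wts * com_g))
  inner <- sqrt(sum(wts * r2_g))
  c(overall = outer * inner, outer = outer, inner = inner)
}

#' Choose the number of REBUS segments
#'
#' Runs [rebus()] for each candidate G and tabulates the overall, outer
#' and inner group quality indices alongside the (G-independent) global
#' GoF.  The recommended G maximises the overall GQI among the candidates
#' whose reassignment iteration actually reached composition stability —
#' a partition that keeps oscillating is not a valid segmentation, and
#' with more segments than the data supports the iteration typically
#' fails to settle.  When no candidate converges the argmax over all
#' candidates is returned; failed runs are reported as \code{NA}.
#'
#' @param data indicator data.
#' @param model a [path_model()].
#' @param G_range candidate segment counts (default \code{2:4}).
#' @param ... forwarded to [rebus()].
#' @return object of class \code{rebus_selection}: \code{criteria} (one
#'   row per G), \code{recommended_G}, \code{fits} (list of rebus results).
#' @export
rebus_select <- function(data, model, G_range = 2:4, ...) {
  fits <- lapply(G_range, function(G)
    tryCatch(rebus(data, model, G, ...), error = function(e) e))
  rows <- lapply(seq_along(G_range), function(i) {
    f <- fits[[i]]
    if (inherits(f, "error"))
      return(data.frame(G = G_range[i], gqi = NA_real_,
                        gqi_outer = NA_real_, gqi_inner = NA_real_,
                        gof = NA_real_, converged = NA))
    data.frame(G = G_range[i], gqi = f$gqi[["overall"]],
               gqi_outer = f$gqi[["outer"]], gqi_inner = f$gqi[["inner"]],
               gof = gof(f$global_fit, "pooled"), converged = f$converged)
  })
  criteria <- do.call(rbind, rows)
  ok <- !is.na(criteria$gqi) & criteria$converged %in% TRUE
  rec <- if (any(ok)) criteria$G[ok][which.max(criteria$gqi[ok])]
  else if (all(is.na(criteria$gqi))) NA_integer_
  else G_range[which.max(criteria$gqi)]
  structure(list(criteria = criteria, recommended_G = rec, fits = fits),
            class = "rebus_selection")
}

#' @export
print.rebus_selection <- function(x, digits = 3, ...) {
  cat("REBUS segment-count selection (argmax overall GQI):\n")
  tab <- x$criteria
  tab[, 2:5] <- round(tab[, 2:5], digits)
  print(tab, row.names = FALSE)
  cat("recommended G =", x$recommended_G, "\n")
  invisible(x)
}

#' @export
print.rebus <- function(x, digits = 3, ...) {
  sizes <- tabulate(x$assignment, nbins = x$n_segments)
  cat(sprintf(
    "REBUS-PLS: %d segments (sizes %s), %d iterations, %s\n",
    x$n_segments, paste(sizes, collapse = "/"), x$n_iterations,
    if (x$converged) "composition stable" else "max_iter reached"))
  cat(sprintf("GQI = %.*f (outer %.*f, inner %.*f)\n",
              digits, x$gqi[["overall"]], digits, x$gqi[["outer"]],
              digits, x$gqi[["inner"]]))
  e <- model_edges(x$global_fit$model)
  tab <- data.frame(path = .edge_label(e$from, e$to),
                    global = x$global_fit$path_coefficients[cbind(e$to, e$from)])
  for (g in seq_len(x$n_segments))
    tab[[paste0("segment", g)]] <-
      x$local_fits[[g]]$path_coefficients[cbind(e$to, e$from)]
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rebus <- function(object, ...) {
  print(object, ...)
  invisible(object)
}
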