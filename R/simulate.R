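#' Declare the ground truth for one latent segment
#'
#' @param proportion segment mixing proportion in (0, 1].
#' @param path_coefficients named vector of structural coefficients, names
#'   as \code{"A -> B"} edge labels.
#' @param loadings named per-indicator loadings in (0, 1]; measurement
#'   error variance is \code{1 - loading^2}.
#' @param inner_sd optional named per-endogenous structural noise standard
#'   deviations.  When omitted the noise is chosen so every latent score
#'   has unit variance (requiring the coefficients to imply a positive
#'   residual variance).
#' @param r_squared optional named per-endogenous target R-squared values;
#'   an alternative to \code{inner_sd} (noise is scaled to hit the
#'   target).
#' @param exo_shift optional named mean shifts (in score standard
#'   deviations) for the exogenous latents; shifts are propagated through
#'   the segment's structural equations, so segments can differ in level
#'   as real sub-populations do while each segment's inner regressions
#'   remain intercept-free.
#' @return object of class \code{segment_spec}.
#' @export
segment_spec <- function(proportion, path_coefficients, loadings = NULL,
                         inner_sd = NULL, r_squared = NULL,
                         exo_shift = NULL) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]")
  if (!is.null(loadings) && (any(loadings <= 0) || any(loadings > 1)))
    stop("loadings must lie in (0, 1] (error variance 1 - loading^2)")
  if (!is.null(inner_sd) && !is.null(r_squared))
    stop("give inner_sd or r_squared, not both")
  structure(list(proportion = proportion,
                 path_coefficients = path_coefficients,
                 loadings = loadings, inner_sd = inner_sd,
                 r_squared = r_squared, exo_shift = exo_shift),
            class = "segment_spec")
}

# propagate exogenous mean shifts through the standardized-scale system:
# shift of an endogenous latent is the standardized-coefficient-weighted
# sum of its predecessors' shifts
.score_shifts <- function(model, spec, sys) {
  lat <- model$latents
  shift <- stats::setNames(rep(0, length(lat)), lat)
  if (is.null(spec$exo_shift)) return(shift)
  for (l in names(spec$exo_shift)) {
    if (!l %in% model$exogenous)
      stop("exo_shift names a non-exogenous latent: ", l)
    shift[[l]] <- spec$exo_shift[[l]]
  }
  sd_all <- sqrt(diag(sys$Sigma))
  for (j in .topo_order(model$inner)) {
    P <- lat[model$inner[j, ] == 1]
    if (!length(P)) next
    b_std <- sys$coef(j) * sd_all[P] / sd_all[[j]]
    shift[[j]] <- sum(b_std * shift[P])
  }
  shift
}

# coefficient vector of the equation for latent j, from a named edge map
.eq_coef <- function(model, coefs, j) {
  P <- model$latents[model$inner[j, ] == 1]
  vapply(P, function(p) {
    v <- unname(coefs[.edge_label(p, j)])
    if (is.na(v)) stop("segment spec lacks path coefficient for ",
                       .edge_label(p, j))
    v
  }, numeric(1))
}

# asymptotic squared correlation between a block's Mode A composite and
# its latent: weights are proportional to the loadings in the population,
# so rel = (sum lambda^2)^2 / ((sum lambda^2)^2 + sum lambda^2 (1-lambda^2))
.block_reliability <- function(model, loadings) {
  vapply(model$latents, function(l) {
    lam2 <- loadings[model$blocks[[l]]]^2
    s <- sum(lam2)
    err <- sum(lam2 * (1 - lam2))
    if (s + 0 == 0) return(0)
    s^2 / (s^2 + err)
  }, numeric(1))
}

# latent covariance + per-equation noise sd implied by a segment spec;
# exogenous scores are standard normal, the chain is propagated in
# topological order.  target = "composite" treats the stated coefficients
# as composite-level (estimable) quantities and backs out the latent-level
# system through the block reliabilities; target = "latent" takes them at
# face value.
.latent_system <- function(model, spec, target = "composite") {
  lat <- model$latents
  topo <- .topo_order(model$inner)
  coefs <- spec$path_coefficients

  if (target == "composite" && is.null(spec$inner_sd) &&
      is.null(spec$r_squared)) {
    # composite covariance implied by the stated coefficients with unit
    # score variances
    Sstar <- .propagate_unit(model, coefs)
    rel <- .block_reliability(model, spec$loadings)
    D <- sqrt(rel[lat])
    Sig <- Sstar / tcrossprod(D)
    diag(Sig) <- 1
    sds <- stats::setNames(rep(NA_real_, length(lat)), lat)
    bmap <- list()
    for (j in topo) {
      P <- lat[model$inner[j, ] == 1]
      if (!length(P)) next
      b <- as.vector(solve(Sig[P, P, drop = FALSE], Sig[P, j]))
      v <- 1 - as.numeric(t(b) %*% Sig[P, P, drop = FALSE] %*% b)
      if (v <= 0)
        stop("composite-level coefficients into '", j, "' are not ",
             "attainable with these loadings (implied latent noise ",
             "variance <= 0); lower the coefficients or raise the ",
             "loadings")
      sds[[j]] <- sqrt(v)
      bmap[[j]] <- stats::setNames(b, P)
    }
    return(list(Sigma = Sig, sds = sds, coef = function(j) bmap[[j]]))
  }

  Sig <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  sds <- stats::setNames(rep(NA_real_, length(lat)), lat)
  for (j in topo) {
    P <- lat[model$inner[j, ] == 1]
    if (!length(P)) { Sig[j, j] <- 1; next }
    b <- .eq_coef(model, coefs, j)
    predvar <- as.numeric(t(b) %*% Sig[P, P, drop = FALSE] %*% b)
    sd_j <- if (!is.null(spec$inner_sd)) {
      v <- unname(spec$inner_sd[j])
      if (is.na(v)) stop("inner_sd lacks entry for ", j)
      v
    } else if (!is.null(spec$r_squared)) {
      r2 <- unname(spec$r_squared[j])
      if (is.na(r2)) stop("r_squared lacks entry for ", j)
      if (r2 <= 0 || r2 >= 1) stop("target R-squared must be in (0, 1)")
      sqrt(predvar * (1 - r2) / r2)
    } else {
      v <- 1 - predvar
      if (v < 0)
        stop("path coefficients into '", j, "' imply negative noise ",
             "variance under unit score variance; give inner_sd")
      sqrt(v)
    }
    sds[[j]] <- sd_j
    Sig[j, j] <- predvar + sd_j^2
    done <- setdiff(topo[seq_len(match(j, topo) - 1L)], j)
    for (i in done)
      Sig[j, i] <- Sig[i, j] <- sum(b * Sig[P, i])
  }
  list(Sigma = Sig, sds = sds,
       coef = function(j) .eq_coef(model, coefs, j))
}

# unit-variance covariance propagation of an edge-coefficient map
.propagate_unit <- function(model, coefs) {
  lat <- model$latents
  topo <- .topo_order(model$inner)
  Sig <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  for (j in topo) {
    P <- lat[model$inner[j, ] == 1]
    if (!length(P)) { Sig[j, j] <- 1; next }
    b <- .eq_coef(model, coefs, j)
    predvar <- as.numeric(t(b) %*% Sig[P, P, drop = FALSE] %*% b)
    if (predvar >= 1)
      stop("stated coefficients into '", j,
           "' imply explained variance >= 1")
    Sig[j, j] <- 1
    done <- setdiff(topo[seq_len(match(j, topo) - 1L)], j)
    for (i in done)
      Sig[j, i] <- Sig[i, j] <- sum(b * Sig[P, i])
  }
  Sig
}

#' Simulate segment-structured indicator data
#'
#' Draws each unit's segment label from the spec proportions, propagates
#' standard-normal exogenous scores through the structural chain with the
#' segment's path coefficients and Gaussian inner noise, standardises each
#' latent score to its theoretical unit variance, and emits indicators as
#' loading times score plus Gaussian measurement error of variance one
#' minus the squared loading.  Pooled indicator columns are finally
#' rescaled to mean zero and unit variance (\code{rescale = TRUE}), which
#' is the scale the estimator consumes.
#'
#' All randomness flows from \code{seed} through R's generator in a fixed
#' draw order (labels, then scores and errors segment by segment), so a
#' fixed seed reproduces the table byte for byte.
#'
#' Because composite scores built from error-laden indicators have
#' reliability below one, a PLS refit of latent-level coefficients is
#' attenuated.  The default \code{target = "composite"} therefore treats
#' the stated path coefficients as the composite-level estimands (the
#' scale on which PLS results are reported) and backs out the latent-level
#' generating system through the block reliabilities, so that the fitted
#' coefficients converge to the stated values as n grows.
#' \code{target = "latent"} takes the coefficients at face value; it is
#' also used automatically whenever \code{inner_sd} or \code{r_squared}
#' is given in a spec.
#'
#' @param model a [path_model()].
#' @param n number of units.
#' @param segments a [segment_spec()] or list of them; proportions must
#'   sum to one.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param rescale rescale pooled indicator columns to mean 0, sd 1.
#' @param target scale of the stated path coefficients:
#'   \code{"composite"} (default) or \code{"latent"}.
#' @return object of class \code{pls_sim}: \code{data} (data frame with
#'   \code{unit} row names), \code{true_labels}, \code{true_scores},
#'   \code{segments}, \code{model}, \code{seed}.
#' @export
simulate_pls_data <- function(model, n = 216, segments, seed = NULL,
                              rescale = TRUE,
                              target = c("composite", "latent")) {
  target <- match.arg(target)
  if (n < 1) stop("n must be positive")
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  props <- vapply(segments, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-6)
    stop("segment proportions must sum to 1")
  lat <- model$latents
  topo <- .topo_order(model$inner)
  indicators <- unlist(model$blocks, use.names = FALSE)
  block_of <- .block_of(model)
  systems <- lapply(segments, function(s) {
    miss <- setdiff(indicators, names(s$loadings))
    if (length(miss))
      stop("segment spec lacks loading(s) for: ",
           paste(miss, collapse = ", "))
    .latent_system(model, s, target = target)
  })
  if (!is.null(seed)) set.seed(seed)

  labels <- sample.int(length(segments), n, replace = TRUE, prob = props)
  scores <- matrix(NA_real_, n, length(lat), dimnames = list(NULL, lat))
  X <- matrix(NA_real_, n, length(indicators),
              dimnames = list(NULL, indicators))
  for (g in seq_along(segments)) {
    idx <- which(labels == g)
    if (!length(idx)) next
    sys <- systems[[g]]
    spec <- segments[[g]]
    Sg <- matrix(NA_real_, length(idx), length(lat),
                 dimnames = list(NULL, lat))
    for (j in topo) {
      P <- lat[model$inner[j, ] == 1]
      if (!length(P)) {
        Sg[, j] <- stats::rnorm(length(idx))
      } else {
        b <- sys$coef(j)
        noise <- if (sys$sds[[j]] > 0)
          stats::rnorm(length(idx), sd = sys$sds[[j]]) else 0
        Sg[, j] <- as.vector(Sg[, P, drop = FALSE] %*% b) + noise
      }
    }
    # theoretical standardization so the declared loadings apply
    Sg_std <- sweep(Sg, 2L, sqrt(diag(sys$Sigma)), "/")
    Sg_std <- sweep(Sg_std, 2L, .score_shifts(model, spec, sys), "+")
    for (q in indicators) {
      lam <- spec$loadings[[q]]
      ev <- 1 - lam^2
      err <- if (ev > 0) stats::rnorm(length(idx), sd = sqrt(ev)) else 0
      X[idx, q] <- lam * Sg_std[, block_of[[q]]] + err
    }
    scores[idx, ] <- Sg_std
  }
  if (rescale) X <- .zscore(X)$values
  d <- as.data.frame(X)
  rownames(d) <- sprintf("u%03d", seq_len(n))
  structure(list(data = d, true_labels = labels, true_scores = scores,
                 segments = segments, model = model, seed = seed),
            class = "pls_sim")
}

#' @export
print.pls_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic PLS sample: %d units x %d indicators, %d segment(s) (sizes %s)\n",
    nrow(x$data), ncol(x$data), length(x$segments),
    paste(tabulate(x$true_labels, length(x$segments)), collapse = "/")))
  invisible(x)
}

#' Ground-truth specs for the toddler-nutrition model
#'
#' \code{nutrition_global_spec()} is the single-population truth: chain
#' coefficients 0.390, 0.829, 0.287 with the reported global loadings.
#' \code{nutrition_segments()} is the two-segment truth with proportions
#' 75/216 and 141/216 and the segment-wise chain coefficients and loadings
#' of the study's response-based segmentation.
#'
#' @return a [segment_spec()] (global) or list of two (segments).
#' @export
nutrition_global_spec <- function() {
  segment_spec(
    proportion = 1,
    path_coefficients = c("X -> Y1" = 0.390, "Y1 -> Y2" = 0.829,
                          "Y2 -> Y3" = 0.287),
    loadings = c(X1.1 = 1, Y1.1 = 0.992, Y1.2 = 0.992,
                 Y2.1 = 0.727, Y2.2 = 0.752, Y2.3 = 0.579, Y2.4 = 0.884,
                 Y3.1 = 0.919, Y3.2 = 0.913, Y3.3 = 0.958))
}

#' @rdname nutrition_global_spec
#' @export
nutrition_segments <- function() {
  list(
    segment_spec(
      proportion = 75 / 216,
      path_coefficients = c("X -> Y1" = 0.540, "Y1 -> Y2" = 0.797,
                            "Y2 -> Y3" = 0.404),
      loadings = c(X1.1 = 1, Y1.1 = 0.991, Y1.2 = 0.992,
                   Y2.1 = 0.692, Y2.2 = 0.633, Y2.3 = 0.590, Y2.4 = 0.894,
                   Y3.1 = 0.891, Y3.2 = 0.940, Y3.3 = 0.891)),
    segment_spec(
      proportion = 141 / 216,
      path_coefficients = c("X -> Y1" = 0.504, "Y1 -> Y2" = 0.843,
                            "Y2 -> Y3" = 0.701),
      loadings = c(X1.1 = 1, Y1.1 = 0.985, Y1.2 = 0.983,
                   Y2.1 = 0.722, Y2.2 = 0.758, Y2.3 = 0.543, Y2.4 = 0.786,
                   Y3.1 = 0.921, Y3.2 = 0.911, Y3.3 = 0.969)))
}

#' Strongly separated two-segment truth
#'
#' Two segments (35\%/65\%) whose chain coefficients are +0.8 in the first
#' segment and -0.8 in the second on every edge (gap 1.6 per path), with
#' near-noiseless structural equations (inner noise sd 0.02),
#' near-noiseless measurement (all loadings 0.995), and segment-distinct
#' exogenous means (+1.5 vs -0.8 score standard deviations, propagated
#' down the chain).  These idealised conditions are deliberate: under pure
#' slope heterogeneity the membership of low-score units is not
#' identifiable by any rule, and the residuals feeding the Ward
#' initialisation carry no location signal at all, so a fixture meant to
#' certify recovery must also separate segments in level — as real
#' sub-populations (and the study's two segments) do.  With this design
#' recovery failures are attributable to the segmentation method, not the
#' data.
#'
#' @return list of two [segment_spec()]s.
#' @export
separated_segments <- function() {
  inds <- c("X1.1", "Y1.1", "Y1.2", "Y2.1", "Y2.2", "Y2.3", "Y2.4",
            "Y3.1", "Y3.2", "Y3.3")
  loads <- stats::setNames(c(1, rep(0.995, 9)), inds)
  sds <- c(Y1 = 0.02, Y2 = 0.02, Y3 = 0.02)
  list(
    segment_spec(0.35,
                 c("X -> Y1" = 0.8, "Y1 -> Y2" = 0.8, "Y2 -> Y3" = 0.8),
                 loads, inner_sd = sds),
    segment_spec(0.65,
                 c("X -> Y1" = -0.8, "Y1 -> Y2" = -0.8, "Y2 -> Y3" = -0.8),
                 loads, inner_sd = sds))
}

#' Simulate score-level mixture-of-regressions data
#'
#' Generates latent scores directly (no measurement layer) from a
#' segment-structured recursive system: exogenous scores are standard
#' normal and each endogenous score is its predecessors' scores times the
#' segment's path coefficients plus Gaussian noise, left on the raw
#' regression scale (no per-segment standardization).  This is the classic
#' mixture-of-regressions benchmark: the stated slopes are exactly the
#' within-segment regression coefficients of the emitted scores.
#'
#' @param model a [path_model()] (only the structural part is used).
#' @param n number of units.
#' @param segments list of [segment_spec()]s; \code{loadings} are ignored
#'   and \code{inner_sd} defaults to 0.05 per equation.
#' @param seed integer seed.
#' @return list with \code{scores} (units x latents matrix),
#'   \code{true_labels} and \code{segments}.
#' @export
simulate_mixture_scores <- function(model, n = 400, segments, seed = NULL) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  props <- vapply(segments, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-6)
    stop("segment proportions must sum to 1")
  lat <- model$latents
  topo <- .topo_order(model$inner)
  if (!is.null(seed)) set.seed(seed)
  labels <- sample.int(length(segments), n, replace = TRUE, prob = props)
  S <- matrix(NA_real_, n, length(lat), dimnames = list(NULL, lat))
  for (g in seq_along(segments)) {
    idx <- which(labels == g)
    if (!length(idx)) next
    spec <- segments[[g]]
    for (j in topo) {
      P <- lat[model$inner[j, ] == 1]
      if (!length(P)) {
        S[idx, j] <- stats::rnorm(length(idx))
      } else {
        b <- .eq_coef(model, spec$path_coefficients, j)
        sd_j <- if (is.null(spec$inner_sd)) 0.05 else {
          v <- unname(spec$inner_sd[j])
          if (is.na(v)) 0.05 else v
        }
        S[idx, j] <- as.vector(S[idx, P, drop = FALSE] %*% b) +
          stats::rnorm(length(idx), sd = sd_j)
      }
    }
  }
  list(scores = S, true_labels = labels, segments = segments)
}

#' Standard synthetic test fixtures
#'
#' A named collection of simulated samples covering the regimes the
#' estimator and the two segmentation methods must handle:
#' \describe{
#'   \item{noiseless_chain}{one segment, all loadings 1, zero inner noise:
#'     indicators are exact transforms of the latent chain, so a PLS fit
#'     recovers the structure exactly.}
#'   \item{one_segment}{the homogeneous nutrition truth, n = 216.}
#'   \item{two_segment_separated}{[separated_segments()], n = 216.}
#'   \item{two_segment_overlapping}{[nutrition_segments()] (segment path
#'     coefficients differ only moderately), n = 216.}
#'   \item{degenerate_constant_column}{the one-segment table with its
#'     first indicator replaced by a constant — must be rejected by
#'     validation.}
#' }
#'
#' @param seed integer seed driving the whole suite.
#' @return named list; all entries but the last are \code{pls_sim}
#'   objects, the last is a plain data frame.
#' @export
fixture_suite <- function(seed = 1) {
  set.seed(seed)
  m <- nutrition_model()
  noiseless <- simulate_pls_data(
    m, n = 100,
    segments = segment_spec(
      1,
      c("X -> Y1" = 0.390, "Y1 -> Y2" = 0.829, "Y2 -> Y3" = 0.287),
      stats::setNames(rep(1, 10), unlist(m$blocks)),
      inner_sd = c(Y1 = 0, Y2 = 0, Y3 = 0)))
  one <- simulate_pls_data(m, n = 216, segments = nutrition_global_spec())
  sep <- simulate_pls_data(m, n = 216, segments = separated_segments())
  ovl <- simulate_pls_data(m, n = 216, segments = nutrition_segments())
  degenerate <- one$data
  degenerate[[1]] <- 5
  list(noiseless_chain = noiseless, one_segment = one,
       two_segment_separated = sep, two_segment_overlapping = ovl,
       degenerate_constant_column = degenerate)
}
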