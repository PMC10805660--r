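library(mclust)  # adjustedRandIndex: independent agreement oracle

ari <- mclust::adjustedRandIndex

# simple two-latent toy model used across files
toy_model <- function() {
  path_model(blocks = list(A = c("a1", "a2"), B = c("b1", "b2")),
             paths = "A -> B")
}

toy_data <- function(n = 50, slope = 0.7, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  b <- slope * a + rnorm(n, sd = sqrt(1 - slope^2))
  data.frame(a1 = 0.9 * a + rnorm(n, sd = sqrt(1 - 0.81)),
             a2 = 0.8 * a + rnorm(n, sd = 0.6),
             b1 = 0.9 * b + rnorm(n, sd = sqrt(1 - 0.81)),
             b2 = 0.8 * b + rnorm(n, sd = 0.6))
}

# exhaustive-search Ward: at each step merge the pair of groups whose
# union minimises the increase in within-group SSE
brute_ward <- function(x) {
  x <- as.matrix(x)
  groups <- lapply(seq_len(nrow(x)), identity)
  sse <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  members <- list()
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        d <- sse(c(groups[[i]], groups[[j]])) - sse(groups[[i]]) -
          sse(groups[[j]])
        if (d < bestd - 1e-12) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    members[[length(members) + 1]] <- merged
    heights <- c(heights, bestd)
    groups[[best[1]]] <- merged
    groups[best[2]] <- NULL
  }
  list(members = members, heights = heights)
}

# member sets of each merge step from an hclust-style merge matrix
merge_members <- function(merge) {
  out <- list()
  for (k in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else out[[v]]
    out[[k]] <- sort(c(grab(merge[k, 1]), grab(merge[k, 2])))
  }
  out
}

# direct loop-wise evaluation of the closeness-measure formula, kept
# deliberately naive and independent of the vectorised implementation
brute_cm <- function(X, model, local_fits, assignment, m_g) {
  n <- nrow(X)
  G <- length(local_fits)
  lat <- model$latents
  endo <- model$endogenous
  CM <- matrix(NA_real_, n, G)
  for (g in seq_len(G)) {
    fit <- local_fits[[g]]
    S <- matrix(0, n, length(lat), dimnames = list(NULL, lat))
    for (l in lat)
      for (q in model$blocks[[l]])
        S[, l] <- S[, l] + fit$weights[[q]] * X[, q]
    num_out <- num_in <- numeric(n)
    for (i in seq_len(n)) {
      for (l in lat) for (q in model$blocks[[l]]) {
        e <- X[i, q] - fit$loadings[[q]] * S[i, l]
        num_out[i] <- num_out[i] + e^2 / fit$communalities[[q]]
      }
      for (j in endo) {
        pred <- sum(fit$path_coefficients[j, ] * S[i, ])
        f <- S[i, j] - pred
        num_in[i] <- num_in[i] + f^2 / fit$r_squared[[j]]
      }
    }
    n_g <- sum(assignment == g)
    den_out <- sum(num_out[assignment == g]) / (n_g - m_g - 1)
    den_in <- sum(num_in[assignment == g]) / (n_g - m_g - 1)
    CM[, g] <- (num_out / den_out) * (num_in / den_in)
  }
  CM
}
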