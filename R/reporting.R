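# Report-writing commands behind the shell entry point (inst/cli/plsseg).
# Each command writes machine-readable CSV/JSON reports plus a manifest
# (inputs, options, seed, package version) so a run can be reproduced
# exactly.

.write_manifest <- function(out_dir, command, options) {
  manifest <- list(
    command = command, options = options,
    package = "plsseg",
    version = as.character(utils::packageVersion("plsseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.resolve_inputs <- function(data, model) {
  if (is.character(data)) data <- read_indicator_data(data)
  if (is.character(model)) model <- read_path_model(model)
  list(data = data, model = model)
}

#' Fit a model and write the full report set
#'
#' Writes the measurement-model table (loadings, AVE, alpha, composite
#' reliability), the structural table (R-squared, f-squared), the
#' bootstrap significance table, Q-squared/GoF, the latent scores and a
#' run manifest into \code{out_dir}.
#'
#' @param data indicator data or path to a CSV file.
#' @param model a [path_model()] or path to a YAML model file.
#' @param out_dir output directory (created if needed).
#' @param scheme inner weighting scheme.
#' @param B bootstrap replicates; \code{B = 0} skips the bootstrap.
#' @param seed integer seed for the bootstrap.
#' @param ... forwarded to [pls_path()].
#' @return invisibly, a list with the fit, evaluation, bootstrap (or
#'   \code{NULL}) and the written file paths.
#' @export
cmd_fit <- function(data, model, out_dir, scheme = NULL, B = 500,
                    seed = 1, ...) {
  inp <- .resolve_inputs(data, model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- scheme %||% inp$model$scheme
  fit <- pls_path(inp$data, inp$model, scheme = scheme, ...)
  ev <- evaluate(fit)
  boot <- if (B > 0) bootstrap_pls(inp$data, inp$model, B = B, seed = seed,
                                   scheme = scheme, ...) else NULL

  outer <- merge(ev$outer, ev$blocks, by = "latent", sort = FALSE)
  files <- c(
    measurement = file.path(out_dir, "measurement_model.csv"),
    structural = file.path(out_dir, "structural_model.csv"),
    scores = file.path(out_dir, "scores.csv"),
    fit = file.path(out_dir, "fit.json"))
  utils::write.csv(outer, files[["measurement"]], row.names = FALSE)
  utils::write.csv(ev$inner, files[["structural"]], row.names = FALSE)
  utils::write.csv(data.frame(unit = rownames(fit$scores) %||%
                                seq_len(fit$n), fit$scores),
                   files[["scores"]], row.names = FALSE)
  if (!is.null(boot)) {
    files[["bootstrap"]] <- file.path(out_dir, "bootstrap.csv")
    utils::write.csv(hypothesis_table(boot), files[["bootstrap"]],
                     row.names = FALSE)
  }
  jsonlite::write_json(list(
    converged = fit$converged, n_iterations = fit$n_iterations,
    weights = as.list(fit$weights), loadings = as.list(fit$loadings),
    path_coefficients = as.list(coef(fit)),
    r_squared = as.list(fit$r_squared),
    q_squared = ev$q_squared, gof = ev$gof,
    means = as.list(fit$means),
    inner_intercepts = as.list(fit$inner_intercepts)),
    files[["fit"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "fit",
                  list(scheme = scheme, B = B, seed = seed))
  invisible(list(fit = fit, evaluation = ev, bootstrap = boot,
                 files = files))
}

# Tables 8-10-shaped comparison of global vs per-segment local models
.comparison_tables <- function(global_fit, local_fits, label) {
  e <- model_edges(global_fit$model)
  paths <- data.frame(path = .edge_label(e$from, e$to),
                      global = global_fit$path_coefficients[cbind(e$to, e$from)])
  loads <- data.frame(indicator = names(global_fit$loadings),
                      global = as.numeric(global_fit$loadings))
  r2 <- data.frame(equation = names(global_fit$r_squared),
                   global = as.numeric(global_fit$r_squared))
  q2 <- data.frame(model = "global",
                   q_squared = q_squared(global_fit$r_squared))
  for (g in seq_along(local_fits)) {
    f <- local_fits[[g]]
    nm <- paste0(label, "_seg", g)
    paths[[nm]] <- f$path_coefficients[cbind(e$to, e$from)]
    loads[[nm]] <- as.numeric(f$loadings[names(global_fit$loadings)])
    r2[[nm]] <- as.numeric(f$r_squared[names(global_fit$r_squared)])
    q2 <- rbind(q2, data.frame(model = nm,
                               q_squared = q_squared(f$r_squared)))
  }
  list(paths = paths, loadings = loads, r_squared = r2, q_squared = q2)
}

#' Segment a dataset and write criteria, assignments and comparisons
#'
#' Runs REBUS-PLS and/or FIMIX-PLS, writes the segment-count criteria
#' table (GQI/GoF for REBUS; lnL, AIC, BIC, CAIC, EN for FIMIX), the unit
#' assignments, and global-versus-local comparison tables of path
#' coefficients, loadings, R-squared and Q-squared.
#'
#' @inheritParams cmd_fit
#' @param method \code{"rebus"}, \code{"fimix"} or \code{"both"}.
#' @param G number of REBUS segments to fit (chosen by GQI over
#'   \code{G_range} when \code{NULL}).
#' @param K number of FIMIX components (chosen by EN over \code{K_range}
#'   when \code{NULL}).
#' @param G_range,K_range candidate ranges for the selection tables.
#' @return invisibly, a list with the fitted segmentations and file paths.
#' @export
cmd_segment <- function(data, model, out_dir,
                        method = c("both", "rebus", "fimix"),
                        G = 2, K = 2, G_range = 2:4, K_range = 2:5,
                        seed = 1, ...) {
  method <- match.arg(method)
  inp <- .resolve_inputs(data, model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  global <- pls_path(inp$data, inp$model, ...)
  out <- list(files = character(0))
  units <- rownames(global$scores) %||% seq_len(global$n)

  if (method %in% c("both", "rebus")) {
    sel <- rebus_select(inp$data, inp$model, G_range = G_range, ...)
    G_use <- G %||% sel$recommended_G
    rb <- rebus(inp$data, inp$model, G = G_use, ...)
    f_crit <- file.path(out_dir, "rebus_criteria.csv")
    f_asg <- file.path(out_dir, "rebus_assignment.csv")
    utils::write.csv(sel$criteria, f_crit, row.names = FALSE)
    utils::write.csv(data.frame(unit = units, segment = rb$assignment),
                     f_asg, row.names = FALSE)
    cmp <- .comparison_tables(rb$global_fit, rb$local_fits, "rebus")
    for (nm in names(cmp)) {
      f <- file.path(out_dir, paste0("rebus_comparison_", nm, ".csv"))
      utils::write.csv(cmp[[nm]], f, row.names = FALSE)
      out$files <- c(out$files, f)
    }
    out$rebus <- rb
    out$rebus_selection <- sel
    out$files <- c(out$files, f_crit, f_asg)
  }
  if (method %in% c("both", "fimix")) {
    sel <- fimix_select(global, inp$model, K_range = K_range, seed = seed,
                        ...)
    K_use <- K %||% sel$recommended_K
    fm <- fimix(global, inp$model, K = K_use, seed = seed, ...)
    f_crit <- file.path(out_dir, "fimix_criteria.csv")
    f_asg <- file.path(out_dir, "fimix_assignment.csv")
    f_post <- file.path(out_dir, "fimix_posteriors.csv")
    utils::write.csv(sel$criteria, f_crit, row.names = FALSE)
    utils::write.csv(data.frame(unit = units, segment = fm$assignment),
                     f_asg, row.names = FALSE)
    utils::write.csv(data.frame(unit = units, fm$posteriors), f_post,
                     row.names = FALSE)
    # local refits per hard-assigned FIMIX segment for the comparison
    keep <- tabulate(fm$assignment, fm$K) >= max(10, 2)
    local <- lapply(which(keep), function(k)
      pls_path(inp$data[fm$assignment == k, , drop = FALSE], inp$model,
               ...))
    cmp <- .comparison_tables(global, local, "fimix")
    for (nm in names(cmp)) {
      f <- file.path(out_dir, paste0("fimix_comparison_", nm, ".csv"))
      utils::write.csv(cmp[[nm]], f, row.names = FALSE)
      out$files <- c(out$files, f)
    }
    out$fimix <- fm
    out$fimix_selection <- sel
    out$files <- c(out$files, f_crit, f_asg, f_post)
  }
  .write_manifest(out_dir, "segment",
                  list(method = method, G = G, K = K, seed = seed,
                       G_range = G_range, K_range = K_range))
  invisible(out)
}

#' Simulate a dataset and write it with its truth sidecar
#'
#' @param out_dir output directory.
#' @param n number of units.
#' @param segments truth specification (default: the two-segment
#'   nutrition truth); also accepts \code{"global"}, \code{"nutrition"}
#'   or \code{"separated"} as shorthand.
#' @param seed integer seed.
#' @param model a [path_model()] (default [nutrition_model()]).
#' @return invisibly, the simulated \code{pls_sim} object and file paths.
#' @export
cmd_simulate <- function(out_dir, n = 216, segments = "nutrition",
                         seed = 1, model = nutrition_model()) {
  if (is.character(segments))
    segments <- switch(segments,
                       global = nutrition_global_spec(),
                       nutrition = nutrition_segments(),
                       separated = separated_segments(),
                       stop("unknown segment shorthand: ", segments))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_pls_data(model, n = n, segments = segments, seed = seed)
  f_data <- file.path(out_dir, "dataset.csv")
  f_truth <- file.path(out_dir, "truth.json")
  utils::write.csv(cbind(unit = rownames(sim$data), sim$data), f_data,
                   row.names = FALSE)
  specs <- lapply(sim$segments, function(s)
    list(proportion = s$proportion,
         path_coefficients = as.list(s$path_coefficients),
         loadings = as.list(s$loadings)))
  jsonlite::write_json(list(seed = seed, n = n,
                            true_labels = sim$true_labels,
                            segments = specs),
                       f_truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  .write_manifest(out_dir, "simulate", list(n = n, seed = seed))
  invisible(list(sim = sim, files = c(data = f_data, truth = f_truth)))
}
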