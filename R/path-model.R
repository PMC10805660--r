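#' Declare a PLS path model
#'
#' A path model names the latent variables, assigns every manifest indicator
#' to exactly one latent block, fixes the measurement mode of each block
#' (reflective/Mode A or formative/Mode B), and lists the directed structural
#' paths among the latents.  The structural graph must be acyclic; a latent
#' with no incoming path is exogenous, all others are endogenous.
#'
#' @param blocks named list; one entry per latent variable, each a character
#'   vector of the indicator (column) names belonging to that block.  Block
#'   order and within-block indicator order are preserved everywhere.
#' @param paths directed structural paths, either a character vector of
#'   declarations such as \code{"Practice -> Food"} or a two-column
#'   (from, to) matrix.
#' @param modes measurement mode per latent: \code{"reflective"} or
#'   \code{"formative"}, a single value recycled to all blocks or a named
#'   vector.
#' @param scheme inner weighting scheme used when fitting:
#'   \code{"centroid"} (default), \code{"factor"} or \code{"path"}.
#' @return an object of class \code{path_model} with components
#'   \code{latents}, \code{blocks}, \code{modes}, \code{inner} (binary
#'   matrix, \code{inner[j, i] == 1} iff \code{i} is a direct predictor of
#'   \code{j}), \code{scheme}, \code{endogenous} and \code{exogenous}.
#' @examples
#' m <- path_model(
#'   blocks = list(X = "x1", Y = c("y1", "y2")),
#'   paths  = "X -> Y")
#' m
#' @seealso [nutrition_model()] for the bundled four-latent chain model,
#'   [read_path_model()] to load a model from a YAML file.
#' @export
path_model <- function(blocks, paths, modes = "reflective",
                       scheme = c("centroid", "factor", "path")) {
  scheme <- match.arg(scheme)
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("'blocks' must be a named list of indicator vectors")
  latents <- names(blocks)
  if (anyDuplicated(latents))
    stop("duplicated latent name: ", latents[duplicated(latents)][1])
  blocks <- lapply(blocks, as.character)
  if (any(lengths(blocks) == 0L))
    stop("latent '", latents[lengths(blocks) == 0L][1],
         "' owns no indicator")
  indicators <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("indicator assigned to more than one block: ",
         indicators[duplicated(indicators)][1])

  if (length(modes) == 1L && is.null(names(modes)))
    modes <- stats::setNames(rep(modes, length(latents)), latents)
  if (is.null(names(modes)) && length(modes) == length(latents))
    names(modes) <- latents
  modes <- modes[latents]
  names(modes) <- latents
  if (anyNA(modes) || !all(modes %in% c("reflective", "formative")))
    stop("'modes' must be \"reflective\" or \"formative\" for every latent")

  edges <- .parse_edges(paths)
  unknown <- setdiff(unique(c(edges$from, edges$to)), latents)
  if (length(unknown))
    stop("path references unknown latent: ", unknown[1])
  inner <- matrix(0, length(latents), length(latents),
                  dimnames = list(latents, latents))
  inner[cbind(edges$to, edges$from)] <- 1
  if (any(diag(inner) != 0)) stop("self-loop in structural paths")
  if (is.null(.topo_order(inner)))
    stop("structural paths contain a cycle")

  endogenous <- latents[rowSums(inner) > 0]
  structure(list(latents = latents, blocks = blocks, modes = modes,
                 inner = inner, scheme = scheme,
                 endogenous = endogenous,
                 exogenous = setdiff(latents, endogenous)),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("PLS path model:", length(x$latents), "latent variables,",
      length(unlist(x$blocks)), "indicators,", sum(x$inner), "paths\n")
  for (l in x$latents) {
    cat(sprintf("  %s (%s%s): %s\n", l, x$modes[[l]],
                if (l %in% x$exogenous) ", exogenous" else "",
                paste(x$blocks[[l]], collapse = ", ")))
  }
  e <- which(x$inner == 1, arr.ind = TRUE)
  if (nrow(e))
    cat("  paths:", paste(.edge_label(x$latents[e[, 2]], x$latents[e[, 1]]),
                          collapse = ", "), "\n")
  cat("  inner weighting scheme:", x$scheme, "\n")
  invisible(x)
}

#' Structural edges of a path model
#'
#' @param model a [path_model()].
#' @return data frame with columns \code{from} and \code{to}, one row per
#'   directed structural path, in latent order of the dependent equation.
#' @export
model_edges <- function(model) {
  out <- do.call(rbind, lapply(model$latents, function(j) {
    preds <- model$latents[model$inner[j, ] == 1]
    if (!length(preds)) return(NULL)
    data.frame(from = preds, to = j, stringsAsFactors = FALSE)
  }))
  out %||% data.frame(from = character(0), to = character(0))
}

# paths + loadings: free parameters of a fitted model, used by the
# closeness-measure degrees-of-freedom correction
.n_model_parameters <- function(model) {
  sum(model$inner) + length(unlist(model$blocks))
}

#' Read or write a path-model specification file
#'
#' The on-disk format is YAML with keys \code{blocks} (map latent ->
#' indicator list), \code{paths} (list of \code{"A -> B"} strings),
#' \code{modes} (map latent -> mode; optional, default reflective) and
#' \code{scheme} (optional, default centroid).
#'
#' @param path file path.
#' @return \code{read_path_model} returns a validated [path_model()];
#'   \code{write_path_model} invisibly returns \code{path}.
#' @export
read_path_model <- function(path) {
  if (!file.exists(path)) stop("model specification file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$blocks)) stop("model specification lacks a 'blocks' key: ", path)
  if (is.null(y$paths)) stop("model specification lacks a 'paths' key: ", path)
  modes <- if (is.null(y$modes)) "reflective" else unlist(y$modes)
  scheme <- y$scheme %||% "centroid"
  if (!scheme %in% c("centroid", "factor", "path"))
    stop("unknown inner weighting scheme: ", scheme)
  path_model(blocks = lapply(y$blocks, unlist),
             paths = unlist(y$paths), modes = modes, scheme = scheme)
}

#' @param model a [path_model()] to serialize.
#' @rdname read_path_model
#' @export
write_path_model <- function(model, path) {
  e <- model_edges(model)
  yaml::write_yaml(list(
    blocks = model$blocks,
    modes = as.list(model$modes),
    paths = as.list(.edge_label(e$from, e$to)),
    scheme = model$scheme), path)
  invisible(path)
}

#' The toddler-nutrition path model
#'
#' The bundled default model: a four-latent recursive chain
#' Practice -> Food -> Service -> Nutrition, measured reflectively by
#' 1/2/4/3 indicators.  Practice is the community health-post (posyandu)
#' count; Food the two iron-supplement (Fe1/Fe3) coverage indicators;
#' Service the four antenatal/neonatal care indicators; Nutrition the
#' stunting, underweight and wasting case counts.
#'
#' @param scheme inner weighting scheme, default \code{"centroid"}.
#' @return a [path_model()] with latents \code{X}, \code{Y1}, \code{Y2},
#'   \code{Y3} and indicators \code{X1.1}, \code{Y1.1}, ..., \code{Y3.3}.
#' @export
nutrition_model <- function(scheme = "centroid") {
  path_model(
    blocks = list(
      X  = "X1.1",
      Y1 = c("Y1.1", "Y1.2"),
      Y2 = c("Y2.1", "Y2.2", "Y2.3", "Y2.4"),
      Y3 = c("Y3.1", "Y3.2", "Y3.3")),
    paths = c("X -> Y1", "Y1 -> Y2", "Y2 -> Y3"),
    modes = "reflective",
    scheme = scheme)
}
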