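# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse path declarations of the form "A -> B" (whitespace optional)
.parse_edges <- function(paths) {
  if (is.matrix(paths) || is.data.frame(paths)) {
    m <- as.matrix(paths)
    if (ncol(m) != 2L) stop("a path matrix must have two columns (from, to)")
    return(data.frame(from = as.character(m[, 1]), to = as.character(m[, 2]),
                      stringsAsFactors = FALSE))
  }
  paths <- as.character(paths)
  parts <- strsplit(paths, "->", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed path declaration: ", paths[bad][1],
                     " (expected \"A -> B\")")
  data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
             to   = trimws(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

.edge_label <- function(from, to) paste(from, "->", to)

# topological order of a binary predecessor matrix inner[to, from];
# returns NULL when the graph has a cycle
.topo_order <- function(inner) {
  remaining <- rownames(inner)
  out <- character(0)
  while (length(remaining)) {
    free <- remaining[rowSums(inner[remaining, remaining, drop = FALSE]) == 0]
    if (!length(free)) return(NULL)
    out <- c(out, free)
    remaining <- setdiff(remaining, free)
  }
  out
}

.col_sds <- function(x) apply(x, 2L, stats::sd)

# column z-scores with the sample (n-1) standard deviation
.zscore <- function(x) {
  ctr <- colMeans(x)
  scl <- .col_sds(x)
  list(values = sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/"),
       center = ctr, scale = scl)
}
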