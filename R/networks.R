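#' Construct a network layer
#'
#' A layer is an undirected, unweighted graph on nodes `1..n` without
#' self-loops or multi-edges, stored as an edge list. Layers are the
#' building blocks of the two-layer multiplex connectivity the multiplex
#' Kuramoto model runs on.
#'
#' @param n node count (positive integer).
#' @param edges two-column integer matrix of node pairs (1-based), one row
#'   per undirected edge; a zero-row matrix gives an empty graph.
#' @return an object of class `mkm_layer` with elements `n`, `edges`
#'   (canonicalized: smaller id first, rows sorted, duplicates an error) and
#'   `mean_degree`.
#' @seealso [er_layer()], [as_adjacency()], [giant_component_fraction()]
#' @export
layer <- function(n, edges) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_param("`n` must be a positive integer, got %s", format(n))
  n <- as.integer(n)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), 0L, 2L)
  if (ncol(edges) != 2L)
    stop_param("`edges` must have two columns")
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n))
      stop_param("edge endpoints must be node ids in 1..%d", n)
    if (any(edges[, 1L] == edges[, 2L]))
      stop_param("self-loops are not allowed")
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (anyDuplicated(edges))
      stop_param("duplicate edges are not allowed")
  }
  dimnames(edges) <- NULL
  structure(
    list(n = n, edges = edges, mean_degree = 2 * nrow(edges) / n),
    class = "mkm_layer"
  )
}

#' Generate an Erdős–Rényi G(n, p) layer
#'
#' Each of the `choose(n, 2)` unordered node pairs is included
#' independently with probability `p`. Generation is delegated to
#' [igraph::sample_gnp()] under a fixed seed, so a given `(n, p, seed)`
#' triple is bit-reproducible.
#'
#' @param n node count.
#' @param p edge probability in `[0, 1]`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return an [layer()] object.
#' @examples
#' l <- er_layer(100, 0.1, seed = 1)
#' l$mean_degree
#' @export
er_layer <- function(n, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_param("`p` must be a probability in [0, 1]")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_param("`n` must be a positive integer")
  g <- with_seed_if(seed, igraph::sample_gnp(n, p))
  edges <- igraph::as_edgelist(g, names = FALSE)
  layer(n, edges)
}

#' Dense adjacency matrix of a layer
#'
#' @param x an [layer()] object.
#' @return symmetric `n x n` 0/1 matrix with zero diagonal.
#' @export
as_adjacency <- function(x) {
  stopifnot(inherits(x, "mkm_layer"))
  a <- matrix(0, x$n, x$n)
  if (nrow(x$edges)) {
    a[x$edges] <- 1
    a[x$edges[, 2:1, drop = FALSE]] <- 1
  }
  a
}

#' Fraction of nodes in the largest connected component
#'
#' The multiplex Kuramoto phenomenology is insensitive to the link density
#' as long as the layers sit above the percolation threshold
#' `p > 1/(n-1)`; this helper measures where a layer stands.
#'
#' @param x an [layer()] object.
#' @return fraction in `[0, 1]`; an empty graph gives `1/n` (singletons).
#' @export
giant_component_fraction <- function(x) {
  stopifnot(inherits(x, "mkm_layer"))
  g <- igraph::graph_from_edgelist(x$edges, directed = FALSE)
  g <- igraph::add_vertices(g, x$n - igraph::vcount(g))
  max(igraph::components(g)$csize) / x$n
}

#' Bundle two layers into a multiplex network
#'
#' The model couples one set of cortical regions through two independent
#' layers on the same node set: an excitatory-excitatory (EE) layer and an
#' excitatory-inhibitory (EI) layer. Interaction sums are normalized by the
#' layer mean degrees, so a layer without edges leaves the normalization
#' undefined: such a multiplex is constructed with a warning and refuses to
#' be integrated.
#'
#' @param layer_ee,layer_ei [layer()] objects with identical node counts.
#' @return an object of class `mkm_multiplex` with elements `n`,
#'   `layer_ee`, `layer_ei`, `mean_degree_ee`, `mean_degree_ei`.
#' @examples
#' mx <- multiplex(er_layer(50, 0.2, seed = 1), er_layer(50, 0.2, seed = 2))
#' c(mx$mean_degree_ee, mx$mean_degree_ei)
#' @export
multiplex <- function(layer_ee, layer_ei) {
  stopifnot(inherits(layer_ee, "mkm_layer"), inherits(layer_ei, "mkm_layer"))
  if (layer_ee$n != layer_ei$n)
    stop("layers must share the node count (got ", layer_ee$n, " and ",
         layer_ei$n, ")", call. = FALSE)
  if (layer_ee$mean_degree == 0 || layer_ei$mean_degree == 0)
    warning("a layer has no edges; degree normalization is undefined and ",
            "integration will fail", call. = FALSE)
  structure(
    list(n = layer_ee$n, layer_ee = layer_ee, layer_ei = layer_ei,
         mean_degree_ee = layer_ee$mean_degree,
         mean_degree_ei = layer_ei$mean_degree),
    class = "mkm_multiplex"
  )
}

#' Erdős–Rényi multiplex in one call
#'
#' Convenience wrapper drawing two independent G(n, p) layers. Defaults
#' (`n = 100`, `p = 0.1`, mean degree about 10) sit safely above the
#' percolation threshold.
#'
#' @param n node count.
#' @param p_ee,p_ei edge probabilities of the EE and EI layers.
#' @param seed optional integer seed (the two layers use `seed` and
#'   `seed + 1` sub-streams via [derive_seeds()]).
#' @return an `mkm_multiplex` object.
#' @export
er_multiplex <- function(n = 100, p_ee = 0.1, p_ei = p_ee, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    as.list(derive_seeds(seed, 2L))
  multiplex(er_layer(n, p_ee, seeds[[1]]), er_layer(n, p_ei, seeds[[2]]))
}

#' @export
print.mkm_layer <- function(x, ...) {
  cat(sprintf("<mkm_layer> n = %d, edges = %d, mean degree = %.3f\n",
              x$n, nrow(x$edges), x$mean_degree))
  invisible(x)
}

#' @export
print.mkm_multiplex <- function(x, ...) {
  cat(sprintf(
    "<mkm_multiplex> n = %d | EE: %d edges (<k> = %.3f) | EI: %d edges (<k> = %.3f)\n",
    x$n, nrow(x$layer_ee$edges), x$mean_degree_ee,
    nrow(x$layer_ei$edges), x$mean_degree_ei))
  invisible(x)
}

#' Read / write a layer as a plain-text edge list
#'
#' The file format is one edge per line as two whitespace-separated
#' 0-based node ids; lines starting with `#` are comments. [write_edge_list()]
#' records the node count in a `# n=<count>` header so isolated trailing
#' nodes survive the round trip; [read_edge_list()] takes the count from
#' that header, from the `n` argument, or falls back to the largest id + 1.
#' Self-loops and ids at or beyond the node count are rejected.
#'
#' @param path file path.
#' @param n optional node count override.
#' @return [read_edge_list()] returns an [layer()] object;
#'   [write_edge_list()] invisibly returns `path`.
#' @export
read_edge_list <- function(path, n = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  hn <- regmatches(header, regexpr("(?<=n=)[0-9]+", header, perl = TRUE))
  hn <- unlist(hn)
  lines <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "[[:space:]]+")
    if (any(lengths(parts) != 2L))
      stop_param("each edge line must hold exactly two node ids")
    ids <- suppressWarnings(matrix(as.integer(unlist(parts)),
                                   ncol = 2L, byrow = TRUE))
    if (anyNA(ids)) stop_param("non-integer node id in edge list")
  } else {
    ids <- matrix(integer(), 0L, 2L)
  }
  if (is.null(n)) n <- if (length(hn)) as.integer(hn[[1]]) else
    if (nrow(ids)) max(ids) + 1L else
      stop_param("node count unknown: no header and no `n` given")
  if (nrow(ids) && any(ids >= n))
    stop_param("node id >= declared node count %d", n)
  if (any(ids[, 1L] == ids[, 2L]))
    stop_param("self-loop in edge list file")
  layer(n, ids + 1L)
}

#' @rdname read_edge_list
#' @param x an [layer()] object to write.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "mkm_layer"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", x$n), con)
  if (nrow(x$edges))
    writeLines(sprintf("%d %d", x$edges[, 1L] - 1L, x$edges[, 2L] - 1L), con)
  invisible(path)
}

#' Read / write a two-layer multiplex bundle
#'
#' A multiplex bundle on disk is a directory holding two edge-list files
#' plus a small JSON manifest (`<name>.json`) recording the node count and
#' the file names.
#'
#' @param x an `mkm_multiplex` object.
#' @param dir directory (created if missing).
#' @param name bundle base name.
#' @return [read_multiplex()] returns an `mkm_multiplex`;
#'   [write_multiplex()] invisibly returns the manifest path.
#' @export
write_multiplex <- function(x, dir, name = "multiplex") {
  stopifnot(inherits(x, "mkm_multiplex"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ee <- paste0(name, "_ee.edges")
  ei <- paste0(name, "_ei.edges")
  write_edge_list(x$layer_ee, file.path(dir, ee))
  write_edge_list(x$layer_ei, file.path(dir, ei))
  manifest <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(n = x$n, layer_ee = ee, layer_ei = ei),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_multiplex
#' @param manifest path to a bundle manifest written by [write_multiplex()].
#' @export
read_multiplex <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  multiplex(read_edge_list(file.path(dir, m$layer_ee), n = m$n),
            read_edge_list(file.path(dir, m$layer_ei), n = m$n))
}
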