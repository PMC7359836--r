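#' Landscape crossing-cost factors
#'
#' Multiplicative cost factors (>= 1) applied to the geographic length of
#' crossing a cell of each landscape class. Suitable habitat is the unit-cost
#' baseline and is fixed at 1. Defaults follow the cost ranges explored for a
#' large terrestrial herbivore crossing glacial landscapes: 1.25 for
#' unsuitable land and glacier, 1.25 for (frozen) sea; sea costs up to ~3
#' are plausible where open water is a strong barrier.
#'
#' @param unsuitable_land,glacier,sea cost factors, each >= 1.
#' @return object of class `cost_params`.
#' @export
cost_params <- function(unsuitable_land = 1.25, glacier = 1.25, sea = 1.25) {
  f <- c(SUITABLE = 1, UNSUITABLE_LAND = unsuitable_land,
         GLACIER = glacier, SEA = sea)
  if (any(f < 1)) stop("cost factors must be >= 1", call. = FALSE)
  structure(list(factors = f), class = "cost_params")
}

class_factors <- function(params, class_codes) {
  # class_codes are integers 0..3; factors indexed in CLASS_CODES order
  unname(params$factors[match(class_codes, CLASS_CODES)])
}

#' Build the classed cost graph over a landscape
#'
#' One node per grid cell; undirected edges between neighboring cells
#' (8-neighborhood by default). An edge's weight is the great-circle length
#' between the two cell centers multiplied by the arithmetic mean of the two
#' endpoint cost factors, giving a symmetric km-equivalent crossing cost.
#' All cells are nodes regardless of class: unsuitable terrain raises the
#' cost of a path, it is never an absolute barrier.
#'
#' @param suitability a suitability raster (used only for validation against
#'   `classes`; may be `NULL`).
#' @param classes a cost-class raster.
#' @param params a [cost_params()].
#' @param neighborhood 4 or 8 (default 8; diagonal moves use the true
#'   diagonal center-to-center great-circle length).
#' @return object of class `cost_graph` wrapping an [igraph::graph] whose
#'   vertex names are linear cell indices and whose `weight` attribute is the
#'   km-equivalent cost.
#' @export
build_cost_graph <- function(suitability, classes, params = cost_params(),
                             neighborhood = 8) {
  stopifnot(neighborhood %in% c(4, 8))
  if (!is.null(suitability) && !same_grid(suitability$grid, classes$grid))
    stop("suitability and cost-class rasters on different grids",
         call. = FALSE)
  grid <- classes$grid
  nr <- grid$n_rows; nc <- grid$n_cols
  fac <- class_factors(params, classes$values)

  # enumerate unique neighbor pairs: for every cell, the E, S, SE, SW moves
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    from <- c(from, cell_index(grid, row[ok], col[ok]))
    to <- c(to, cell_index(grid, r2[ok], c2[ok]))
  }
  len <- great_circle_km(cell_centers(grid, from), cell_centers(grid, to))
  w <- len * (fac[from] + fac[to]) / 2
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(nr * nc))
  g <- igraph::add_edges(g, rbind(from, to), weight = w)
  structure(list(graph = g, grid = grid, params = params,
                 neighborhood = neighborhood),
            class = "cost_graph")
}

#' @export
print.cost_graph <- function(x, ...) {
  cat(sprintf("cost_graph: %d nodes, %d edges, %d-neighborhood\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$neighborhood))
  invisible(x)
}

#' Least-cost-path distance matrix
#'
#' Exact shortest-path (Dijkstra) distances over the full cost graph between
#' the given cells. Paths may cross cells of any class; class factors only
#' scale the cost.
#'
#' @param graph a [build_cost_graph()] result.
#' @param cells integer vector of linear cell indices.
#' @return symmetric numeric matrix of km-equivalent least-cost distances,
#'   dimnames the cell indices.
#' @export
least_cost_matrix <- function(graph, cells) {
  if (length(cells) == 0) stop("empty cell list", call. = FALSE)
  cells <- as.integer(cells)
  v <- as.character(cells)
  d <- igraph::distances(graph$graph, v = v, to = v,
                         weights = igraph::E(graph$graph)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- list(cells, cells)
  d
}

#' Dispersal-thresholded connection graph
#'
#' Two occupied cells are connected when either one's per-step dispersal
#' reach exceeds (strictly) the least-cost path between them: edge (i, j)
#' iff `max(d_i, d_j) > costD[i, j]` under the default `"max"` rule
#' (one-way colonization suffices for genetic exchange); `"min"` requires
#' both. Connected components are labelled deterministically by the lowest
#' member cell index.
#'
#' @param costD least-cost distance matrix over the occupied cells
#'   (dimnames = cell indices).
#' @param dispersal_km named numeric vector, per-cell dispersal reach in km
#'   per step, covering all cells of `costD`.
#' @param rule `"max"` (default) or `"min"`.
#' @return object of class `connection_graph`: list with `cells`, `edges`
#'   (two-column matrix of cell indices) and `component` (named integer
#'   vector, component label = minimal member cell index).
#' @export
connection_edges <- function(costD, dispersal_km, rule = c("max", "min")) {
  rule <- match.arg(rule)
  cells <- as.integer(rownames(costD))
  d <- dispersal_km[as.character(cells)]
  if (anyNA(d)) stop("dispersal values must cover all cells", call. = FALSE)
  if (any(d < 0)) stop("negative dispersal", call. = FALSE)
  n <- length(cells)
  comb <- if (rule == "max") outer(d, d, pmax) else outer(d, d, pmin)
  adj <- comb > costD  # strict: equal reach does not connect
  adj[!upper.tri(adj)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- cbind(cells[idx[, 1]], cells[idx[, 2]])
  structure(list(cells = cells, edges = edges,
                 component = label_components(cells, edges)),
            class = "connection_graph")
}

#' Connected components of a connection graph
#'
#' @param graph a `connection_graph`.
#' @return named integer vector: for each cell, the lowest cell index in its
#'   connected component (a stable, deterministic component label).
#' @export
components_of <- function(graph) graph$component

label_components <- function(cells, edges) {
  n <- length(cells)
  pos <- stats::setNames(seq_len(n), cells)
  if (nrow(edges) > 0) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(pos[as.character(edges[, 1])],
                                    pos[as.character(edges[, 2])]))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(n)
  }
  # name each component by its minimal member cell index
  min_cell <- tapply(cells, memb, min)
  stats::setNames(as.integer(min_cell[as.character(memb)]), cells)
}

#' Write and read labelled square distance matrices (PHYLIP square dialect)
#'
#' First line the matrix order `n`, then one line per row: label followed by
#' the `n` distances.
#'
#' @param D symmetric matrix with dimnames.
#' @param path file path.
#' @return `read_phylip_matrix` returns the labelled matrix.
#' @export
write_phylip_matrix <- function(D, path) {
  labs <- rownames(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(labs[i], format(D[i, ], digits = 15,
                                       scientific = FALSE, trim = TRUE)),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[`, "", 1)
  D <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(D) <- list(labs, labs)
  D
}
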