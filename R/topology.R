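#' @useDynLib shgame, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

new_sh_graph <- function(n, adj, kind, radius = NA_integer_, shape = NULL) {
  structure(list(n = n, adj = adj, kind = kind,
                 radius = radius, shape = shape),
            class = "sh_graph")
}

#' Periodic-lattice neighborhood graph
#'
#' Builds the interaction graph of a `rows x cols` lattice with joint
#' (toroidal) boundaries. Under the Moore scheme the neighbors of a cell
#' are all cells within Chebyshev distance `radius`; under the von Neumann
#' scheme, within Manhattan distance `radius`. Cell `(row, col)` (0-based)
#' maps to player index `row*cols + col + 1` (row-major; player indices
#' are 1-based).
#'
#' @param rows,cols lattice dimensions; each must be at least
#'   `2 * radius + 1` so neighborhoods do not wrap onto themselves.
#' @param scheme `"moore"` or `"von_neumann"`.
#' @param radius neighborhood radius, integer >= 1.
#' @return An `sh_graph` object: fields `n`, `adj` (list of integer
#'   neighbor vectors), `kind`, `radius`, `shape`.
#' @examples
#' g <- lattice_neighbors(5, 5, "moore", 1)
#' lengths(g$adj)[1]  # 8
#' @export
lattice_neighbors <- function(rows, cols, scheme = c("moore", "von_neumann"),
                              radius = 1L) {
  scheme <- match.arg(scheme)
  rows <- as.integer(rows); cols <- as.integer(cols)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  if (rows < 2L * radius + 1L || cols < 2L * radius + 1L)
    stop("lattice too small for the requested radius", call. = FALSE)

  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  if (scheme == "von_neumann")
    off <- off[abs(off$dr) + abs(off$dc) <= radius, ]

  n <- rows * cols
  cell_r <- rep(0:(rows - 1L), each = cols)
  cell_c <- rep(0:(cols - 1L), times = rows)
  # n x k matrix of neighbor indices via toroidal wrap
  nb <- matrix(0L, nrow = n, ncol = nrow(off))
  for (k in seq_len(nrow(off))) {
    rr <- (cell_r + off$dr[k]) %% rows
    cc <- (cell_c + off$dc[k]) %% cols
    nb[, k] <- rr * cols + cc + 1L
  }
  adj <- lapply(seq_len(n), function(i) sort(nb[i, ]))
  new_sh_graph(n, adj, scheme, radius, c(rows, cols))
}

#' Well-mixed (complete) interaction graph
#'
#' Everybody is neighbor with everybody: the complete graph on `n`
#' players.
#'
#' @param n number of players, at least 2.
#' @return An `sh_graph` object of kind `"well_mixed"`.
#' @export
well_mixed_neighbors <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("well-mixed graph needs n >= 2", call. = FALSE)
  adj <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  new_sh_graph(n, adj, "well_mixed")
}

#' Scale-free interaction graph mapped onto the lattice
#'
#' Grows a preferential-attachment (power-law degree) graph on `n`
#' vertices, each newly added vertex attaching `m` edges to existing
#' vertices with probability proportional to degree (Barabasi-Albert
#' model, via \pkg{igraph}). Vertices are identified with lattice cells by
#' a seeded random permutation; the placement matters only for
#' visualization, not for the dynamics. The default `m = 4` gives a mean
#' degree near 8, matching the Moore radius-1 lattice so topology
#' comparisons are degree-fair.
#'
#' @param n number of vertices.
#' @param m edges attached by each new vertex; `1 <= m <= n - 2` so the
#'   growth process has at least one step.
#' @param seed integer seed making the graph and placement reproducible.
#' @param shape optional `c(rows, cols)` with `rows * cols == n`, recorded
#'   for rendering.
#' @return An `sh_graph` object of kind `"scale_free"`.
#' @export
scale_free_neighbors <- function(n, m = 4L, seed = 1L, shape = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L || m > n - 2L)
    stop("scale-free m must satisfy 1 <= m <= n - 2", call. = FALSE)
  if (!is.null(shape) && prod(shape) != n)
    stop("shape does not match n", call. = FALSE)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  ig <- igraph::sample_pa(n, m = m, directed = FALSE)
  perm <- sample.int(n)  # lattice placement of graph vertices
  el <- igraph::as_edgelist(ig, names = FALSE)
  el <- cbind(perm[el[, 1]], perm[el[, 2]])
  adj <- rep(list(integer(0)), n)
  ord <- split(c(el[, 2], el[, 1]), c(el[, 1], el[, 2]))
  adj[as.integer(names(ord))] <- lapply(ord, function(v) sort(unique(as.integer(v))))
  new_sh_graph(n, adj, "scale_free", shape = shape)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Number of edges of an interaction graph
#' @param graph an `sh_graph`.
#' @return Integer edge count.
#' @export
graph_edge_count <- function(graph) sum(lengths(graph$adj)) %/% 2L

# CSR (0-based) form consumed by the compiled engine
as_csr <- function(graph) {
  deg <- lengths(graph$adj)
  list(adj = as.integer(unlist(graph$adj, use.names = FALSE) - 1L),
       ptr = as.integer(c(0L, cumsum(deg))))
}

#' Write a graph as a tab-separated edge list
#'
#' Two integer columns (1-based player indices), one edge per line.
#'
#' @param graph an `sh_graph`.
#' @param path output file path.
#' @export
write_edge_list <- function(graph, path) {
  rows <- unlist(lapply(seq_len(graph$n), function(i) {
    js <- graph$adj[[i]]
    js <- js[js > i]
    if (length(js)) paste(i, js, sep = "\t") else character(0)
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.sh_graph <- function(x, ...) {
  cat("SH interaction graph:", x$kind, "- n =", x$n,
      "- edges =", graph_edge_count(x), "\n")
  invisible(x)
}
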