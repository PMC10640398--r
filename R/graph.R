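#' Spot neighbourhood graphs
#'
#' SRT platforms come in two spatial flavours: barcoded arrays (ST, Visium)
#' where spots sit on a regular grid addressed by integer `(row, col)` array
#' coordinates, and imaging platforms (osmFISH-like) where cells carry
#' Euclidean `(x, y)` positions. `build_grid_graph()` links array spots to
#' their immediate lattice neighbours; `build_knn_graph()` links each cell to
#' its `k` nearest Euclidean neighbours and symmetrises the relation by union.
#'
#' Grid adjacency conventions:
#' * `square` (ST): rook 4-neighbourhood, offsets `(±1, 0)` and `(0, ±1)`.
#' * `hex` (Visium array coordinates, column parity alternating by row): up to
#'   6 neighbours at offsets `(0, ±2)` and `(±1, ±1)`.
#'
#' Missing spots are simply absent: a spot keeps only the neighbours that are
#' present in `coords`.
#'
#' @param coords A data frame with one row per spot: column `spot_id` plus
#'   either integer `row`,`col` (grid) or numeric `x`,`y` (Euclidean).
#' @param k Number of nearest neighbours (default 15). Distance ties are
#'   broken towards the lower spot index for determinism.
#' @param layout `"square"` or `"hex"`.
#' @return A `spot_graph`: list with `n_spots`, `adjacency` (list of integer
#'   neighbour index vectors, 1-based, sorted), and `spot_ids`.
#' @examples
#' coords <- tibble::tibble(spot_id = c("a", "b", "c"), x = c(0, 1, 10), y = 0)
#' build_knn_graph(coords, k = 1)
#' @export
build_knn_graph <- function(coords, k = 15) {
  coords <- as_coords(coords, mode = "euclidean")
  n <- nrow(coords)
  if (k < 1 || k >= n) {
    abort(sprintf("k must satisfy 1 <= k < n_spots (got k = %s, n_spots = %d)", k, n),
          class = "spanr_invalid_parameter")
  }
  d <- as.matrix(dist(cbind(coords$x, coords$y)))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    # ties broken by lower spot index; exclude self
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    adj[[i]] <- ord[seq_len(k)]
  }
  # symmetrise by union
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (!(i %in% adj[[j]])) adj[[j]] <- c(adj[[j]], i)
    }
  }
  new_spot_graph(lapply(adj, function(x) sort(as.integer(x))), coords$spot_id)
}

#' @rdname build_knn_graph
#' @export
build_grid_graph <- function(coords, layout = c("square", "hex")) {
  layout <- match.arg(layout)
  coords <- as_coords(coords, mode = "grid")
  n <- nrow(coords)
  offs <- switch(layout,
    square = cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L)),
    hex = cbind(c(0L, 0L, -1L, -1L, 1L, 1L), c(-2L, 2L, -1L, 1L, -1L, 1L))
  )
  key <- paste(coords$row, coords$col, sep = "_")
  if (anyDuplicated(key)) {
    abort("duplicate (row, col) positions in grid coordinates",
          class = "spanr_invalid_parameter")
  }
  lookup <- setNames(seq_len(n), key)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb_key <- paste(coords$row[i] + offs[, 1L], coords$col[i] + offs[, 2L], sep = "_")
    hit <- lookup[nb_key]
    adj[[i]] <- sort(as.integer(hit[!is.na(hit)]))
  }
  new_spot_graph(adj, coords$spot_id)
}

#' Tabulate neighbour types
#'
#' Counts, for every spot, how many of its graph neighbours currently carry
#' each label: the sufficient statistic `u_i(l)` of the Markov random field
#' conditional.
#'
#' @param graph A `spot_graph`.
#' @param z Integer label vector in `1..K`, one per spot.
#' @param K Number of types.
#' @return An `n_spots` by `K` integer matrix; row `i` sums to `degree(i)`.
#' @export
neighbor_type_counts <- function(graph, z, K) {
  stopifnot(inherits(graph, "spot_graph"))
  z <- check_labels(z, graph$n_spots, K)
  u <- matrix(0L, graph$n_spots, K)
  for (i in seq_len(graph$n_spots)) {
    nb <- graph$adjacency[[i]]
    if (length(nb)) u[i, ] <- tabulate(z[nb], nbins = K)
  }
  u
}

new_spot_graph <- function(adjacency, spot_ids) {
  structure(
    list(n_spots = length(adjacency), adjacency = adjacency,
         spot_ids = as.character(spot_ids)),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf("<spot_graph> %d spots, %d edges, degree %d-%d (median %g)\n",
              x$n_spots, sum(deg) %/% 2L, min(deg), max(deg), median(deg)))
  invisible(x)
}

graph_degrees <- function(graph) lengths(graph$adjacency)

# edge list as a 2-column matrix with i < j (each undirected edge once)
graph_edges <- function(graph) {
  ii <- rep.int(seq_len(graph$n_spots), lengths(graph$adjacency))
  jj <- unlist(graph$adjacency, use.names = FALSE)
  keep <- ii < jj
  cbind(i = ii[keep], j = jj[keep])
}

as_coords <- function(coords, mode) {
  coords <- tibble::as_tibble(coords)
  if (!"spot_id" %in% names(coords)) {
    coords$spot_id <- as.character(seq_len(nrow(coords)))
  }
  if (mode == "euclidean") {
    if (!all(c("x", "y") %in% names(coords))) {
      abort("euclidean coordinates need columns x and y (got grid columns?)",
            class = "spanr_wrong_mode")
    }
    if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
      abort("coordinates must be finite", class = "spanr_invalid_parameter")
    }
  } else {
    if (!all(c("row", "col") %in% names(coords))) {
      abort("grid coordinates need columns row and col (use build_knn_graph for x/y)",
            class = "spanr_wrong_mode")
    }
    if (any(coords$row != round(coords$row)) || any(coords$col != round(coords$col))) {
      abort("grid coordinates must be integers", class = "spanr_invalid_parameter")
    }
  }
  coords
}

check_labels <- function(z, n, K) {
  if (is.factor(z)) z <- as.integer(z)
  z <- as.integer(z)
  if (length(z) != n) {
    abort(sprintf("label vector length %d does not match %d spots", length(z), n),
          class = "spanr_invalid_input")
  }
  if (anyNA(z) || any(z < 1L) || any(z > K)) {
    abort(sprintf("labels must lie in 1..%d", K), class = "spanr_invalid_label")
  }
  z
}
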