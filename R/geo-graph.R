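# Geography-only spatial graphs: great-circle distances, radius
# neighborhoods, Boolean-power reachability, connectivity repair and
# Gaussian edge weighting.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between coordinate pairs (haversine)
#'
#' Spherical distance on an Earth of radius 6371 km. Vectorized over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90 | abs(lat2) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(abs(lon1) > 180 | abs(lon2) > 180, na.rm = TRUE)) {
    stop("longitude out of range [-180, 180]")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  h <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Pairwise great-circle distance matrix
#'
#' @param latitude,longitude Coordinate vectors of equal length (degrees).
#' @return Symmetric n x n matrix of distances in km with zero diagonal.
#' @export
great_circle_matrix <- function(latitude, longitude) {
  n <- length(latitude)
  stopifnot(length(longitude) == n)
  D <- matrix(0, n, n)
  if (n > 1) {
    idx <- which(upper.tri(D), arr.ind = TRUE)
    d <- haversine_km(latitude[idx[, 1]], longitude[idx[, 1]],
                      latitude[idx[, 2]], longitude[idx[, 2]])
    D[idx] <- d
    D[idx[, c(2, 1), drop = FALSE]] <- d
  }
  D
}

#' Radius neighborhoods of monitoring sites
#'
#' For each site the neighbor set is every other site within `d` km
#' (boundary inclusive, self excluded); the neighbor count is the size of
#' that set.
#'
#' @param dist_km Symmetric distance matrix in km (see
#'   [great_circle_matrix()]).
#' @param d Radius in km (> 0).
#' @return List with `neighbors` (list of integer index vectors) and
#'   `counts` (integer vector).
#' @export
radius_neighbors <- function(dist_km, d) {
  stopifnot(is.matrix(dist_km), nrow(dist_km) == ncol(dist_km), d > 0)
  n <- nrow(dist_km)
  neighbors <- lapply(seq_len(n), function(i) {
    which(dist_km[i, ] <= d & seq_len(n) != i)
  })
  list(neighbors = neighbors, counts = lengths(neighbors))
}

#' Binary adjacency from radius neighborhoods
#'
#' `A[i, j] = 1` iff site j lies in the neighbor set of site i. The radius
#' rule is symmetric, so the result must be a symmetric 0/1 matrix with
#' zero diagonal; asymmetric input is an internal consistency error.
#'
#' @param neighbors Output of [radius_neighbors()] (or its `neighbors`
#'   element).
#' @return n x n binary adjacency matrix.
#' @export
build_radius_adjacency <- function(neighbors) {
  if (is.list(neighbors) && !is.null(neighbors$neighbors)) {
    neighbors <- neighbors$neighbors
  }
  n <- length(neighbors)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, neighbors[[i]]] <- 1
  if (any(diag(A) != 0) || !isTRUE(all.equal(A, t(A)))) {
    stop("internal consistency error: radius neighborhoods not symmetric")
  }
  A
}

check_adjacency <- function(A, allow_diag = FALSE) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!all(A %in% c(0, 1))) stop("adjacency must be a 0/1 matrix")
  if (!identical(unname(A), unname(t(A)))) stop("adjacency must be symmetric")
  if (!allow_diag && any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  A
}

#' Reachable matrix and connected components by Boolean powers
#'
#' Iterates `A_i = sgn((A + I)^i)` — the sign function applied elementwise
#' to successive powers of the self-looped adjacency — until two successive
#' iterates agree; the fixpoint is the reachable matrix `M_G` (the Boolean
#' transitive closure). The number of connected components equals the rank
#' of `M_G`, and the distinct rows of `M_G` (a maximum linearly independent
#' set) are the component indicator vectors.
#'
#' @param A Symmetric 0/1 adjacency matrix. A reflexive matrix (ones on the
#'   diagonal) is accepted: self-loops do not change reachability.
#' @return Object of class `reachability_result`: list with `m_g` (0/1
#'   matrix), `component_count`, `components` (list of integer node sets,
#'   ordered by smallest member), `membership` (integer vector) and
#'   `iterations` (the fixpoint index k).
#' @export
reachable_matrix <- function(A) {
  A <- check_adjacency(A, allow_diag = TRUE)
  n <- nrow(A)
  base <- (A + diag(n) > 0) * 1
  cur <- base
  k <- 1L
  repeat {
    nxt <- (cur %*% base > 0) * 1
    k <- k + 1L
    if (identical(nxt, cur)) break
    cur <- nxt
    if (k > n + 1L) stop("reachability iteration failed to reach a fixpoint")
  }
  keys <- apply(cur, 1, paste, collapse = "")
  membership <- match(keys, unique(keys))
  components <- split(seq_len(n), membership)
  names(components) <- NULL
  structure(
    list(m_g = cur, component_count = length(components),
         components = components, membership = membership, iterations = k),
    class = "reachability_result"
  )
}

#' @export
print.reachability_result <- function(x, ...) {
  cat("Reachability:", nrow(x$m_g), "nodes,", x$component_count,
      "connected component(s)\n")
  invisible(x)
}

#' Connect components by shortest cross-component edges
#'
#' Repeatedly adds the edge between the globally closest pair of nodes
#' lying in different current components (ties broken by the smallest
#' `(i, j)` index pair), merging components until the graph is connected.
#' Exactly `component_count - 1` edges are added.
#'
#' @param A Binary adjacency matrix (symmetric, zero diagonal).
#' @param dist_km Distance matrix aligned with `A`.
#' @param reach Optional precomputed [reachable_matrix()] result for `A`.
#' @return List with `adjacency` (repaired matrix) and `repair_edges`
#'   (data.frame with columns `i`, `j`, `distance_km`; zero rows if the
#'   input was already connected).
#' @export
connect_components <- function(A, dist_km, reach = NULL) {
  A <- check_adjacency(A)
  if (is.null(reach)) reach <- reachable_matrix(A)
  membership <- reach$membership
  n <- nrow(A)
  repairs <- list()
  while (length(unique(membership)) > 1) {
    cross <- outer(membership, membership, FUN = "!=")
    cand <- which(cross & upper.tri(cross), arr.ind = TRUE)
    dists <- dist_km[cand]
    best_d <- min(dists)
    at_min <- cand[dists == best_d, , drop = FALSE]
    ord <- order(at_min[, 1], at_min[, 2])
    i <- at_min[ord[1], 1]
    j <- at_min[ord[1], 2]
    A[i, j] <- A[j, i] <- 1
    repairs[[length(repairs) + 1L]] <- c(i, j, best_d)
    membership[membership == membership[j]] <- membership[i]
  }
  repair_edges <- if (length(repairs)) {
    df <- as.data.frame(do.call(rbind, repairs))
    names(df) <- c("i", "j", "distance_km")
    df$i <- as.integer(df$i); df$j <- as.integer(df$j)
    df
  } else {
    data.frame(i = integer(0), j = integer(0), distance_km = numeric(0))
  }
  list(adjacency = A, repair_edges = repair_edges)
}

#' Gaussian kernel edge weights
#'
#' `A_w[i, j] = exp(-d_ij^2 / (2 theta^2))` on edges of `A`, 0 elsewhere.
#' Edge weights that underflow to zero (edges far beyond the kernel width,
#' possible for repair edges) are floored at the smallest positive double
#' so that a positive weight corresponds exactly to an edge.
#'
#' @param A Binary adjacency (post-repair).
#' @param dist_km Distance matrix in km.
#' @param theta Kernel width in km (> 0); default 5.
#' @return Symmetric weighted adjacency with entries in (0, 1\] on edges.
#' @export
gaussian_weighted_adjacency <- function(A, dist_km, theta = 5) {
  A <- check_adjacency(A)
  stopifnot(theta > 0)
  W <- exp(-dist_km^2 / (2 * theta^2)) * A
  W[A == 1 & W == 0] <- .Machine$double.xmin
  W
}

edge_table <- function(A, dist_km, W, repair_edges) {
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  is_repair <- rep(FALSE, nrow(idx))
  if (nrow(repair_edges)) {
    key <- paste(idx[, 1], idx[, 2])
    rkey <- paste(pmin(repair_edges$i, repair_edges$j),
                  pmax(repair_edges$i, repair_edges$j))
    is_repair <- key %in% rkey
  }
  data.frame(
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    distance_km = dist_km[idx], weight = W[idx], is_repair_edge = is_repair
  )
}

new_soil_graph <- function(table, dist_km, adjacency, weights, repair_edges,
                           d, theta, masked = FALSE, labels = NULL) {
  structure(
    list(
      n = nrow(adjacency),
      node_ids = as.character(table$sample_id),
      latitude = table$latitude, longitude = table$longitude,
      dist_km = dist_km, adjacency = adjacency, weights = weights,
      edges = edge_table(adjacency, dist_km, weights, repair_edges),
      repair_edges = repair_edges,
      params = list(d = d, theta = theta, masked = masked),
      labels = labels
    ),
    class = "soil_graph"
  )
}

#' Build the fixed geography-only spatial graph
#'
#' Pipeline: great-circle distance matrix, radius adjacency at `d` km,
#' reachability check, shortest-distance connectivity repair, Gaussian
#' kernel weights with width `theta`. The result is always connected.
#'
#' @param table A validated `sample_table` (or any data.frame with
#'   `sample_id`, `latitude`, `longitude`).
#' @param d Neighborhood radius in km (default 10).
#' @param theta Gaussian kernel width in km (default 5).
#' @return Object of class `soil_graph`: node ids/coordinates, `dist_km`,
#'   binary `adjacency`, `weights`, an `edges` data.frame
#'   (i, j, distance_km, weight, is_repair_edge), `repair_edges` and the
#'   build `params`.
#' @export
build_fixed_graph <- function(table, d = 10, theta = 5) {
  if (nrow(table) < 2) stop("insufficient sites: need n >= 2")
  D <- great_circle_matrix(table$latitude, table$longitude)
  nb <- radius_neighbors(D, d)
  A0 <- build_radius_adjacency(nb)
  rep_out <- connect_components(A0, D)
  W <- gaussian_weighted_adjacency(rep_out$adjacency, D, theta)
  new_soil_graph(table, D, rep_out$adjacency, W, rep_out$repair_edges,
                 d = d, theta = theta, masked = FALSE)
}

#' A self-only graph for covariate-only baselines
#'
#' Returns a `soil_graph` with no edges: propagation operators reduce to
#' the identity and attention sees only the node itself, so a model trained
#' on it uses covariates alone. Used as the non-spatial baseline in
#' recovery experiments.
#'
#' @param table Sample table.
#' @return A `soil_graph` with empty edge set.
#' @export
identity_graph <- function(table) {
  n <- nrow(table)
  D <- great_circle_matrix(table$latitude, table$longitude)
  A <- matrix(0, n, n)
  empty <- data.frame(i = integer(0), j = integer(0), distance_km = numeric(0))
  g <- new_soil_graph(table, D, A, A, empty, d = 0, theta = 1, masked = FALSE)
  g$params$identity <- TRUE
  g
}

#' @export
print.soil_graph <- function(x, ...) {
  cat(sprintf(
    "Spatial graph: %d nodes, %d edges (%d repair), d=%g km, theta=%g km%s\n",
    x$n, nrow(x$edges), sum(x$edges$is_repair_edge),
    x$params$d, x$params$theta,
    if (isTRUE(x$params$masked)) ", environmental-type masked" else ""))
  invisible(x)
}

#' Export a graph edge list as CSV
#'
#' Columns: `i`, `j`, `distance_km`, `weight`, `is_repair_edge`.
#'
#' @param graph A `soil_graph`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_graph_edges_csv <- function(graph, path) {
  stopifnot(inherits(graph, "soil_graph"))
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export a graph as a JSON document
#'
#' Nodes with ids and coordinates, the edge list, and the build parameters
#' (`d`, `theta`, masking flag).
#'
#' @param graph A `soil_graph`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "soil_graph"))
  doc <- list(
    params = graph$params,
    nodes = data.frame(id = graph$node_ids, latitude = graph$latitude,
                       longitude = graph$longitude),
    edges = graph$edges
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
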