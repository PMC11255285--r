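# Parent-material zoning (density clustering), environmental-type
# classification, same-type adjacency masking and the dynamic adjacency
# sequence.

#' Density-based parent-material zoning of sampling sites
#'
#' DBSCAN-style clustering on great-circle distances: a core site has at
#' least `min_samples` sites (itself included) within `eps_km`; clusters
#' are the connected sets of core sites plus the border sites reachable
#' from them; remaining sites are noise. With `stratify_by_material` the
#' clustering runs separately within each `parent_material` class and the
#' (material, cluster) pairs are flattened to contiguous zone ids.
#'
#' @param table Sample table with `latitude`/`longitude` (and
#'   `parent_material` when stratifying).
#' @param eps_km Neighborhood radius in km (default 15).
#' @param min_samples Core-point threshold, self included (default 4).
#' @param stratify_by_material Cluster within parent-material classes.
#' @return Object of class `parent_zoning`: `labels` (integer zone ids,
#'   contiguous from 0; noise = -1), `is_noise`, `n_zones`, and the
#'   parameters used.
#' @export
dbscan_zones <- function(table, eps_km = 15, min_samples = 4,
                         stratify_by_material = FALSE) {
  stopifnot(eps_km > 0, min_samples >= 1)
  n <- nrow(table)
  if (stratify_by_material) {
    if (is.null(table$parent_material)) {
      stop("column 'parent_material' required when stratify_by_material = TRUE")
    }
    labels <- rep(-1L, n)
    next_id <- 0L
    for (mat in sort(unique(as.character(table$parent_material)))) {
      idx <- which(as.character(table$parent_material) == mat)
      sub <- dbscan_core(table$latitude[idx], table$longitude[idx],
                         eps_km, min_samples)
      pos <- sub >= 0
      labels[idx[pos]] <- sub[pos] + next_id
      if (any(pos)) next_id <- next_id + max(sub[pos]) + 1L
    }
  } else {
    labels <- dbscan_core(table$latitude, table$longitude, eps_km, min_samples)
  }
  structure(
    list(labels = labels, is_noise = labels == -1L,
         n_zones = length(unique(labels[labels >= 0])),
         eps_km = eps_km, min_samples = min_samples,
         stratify_by_material = stratify_by_material),
    class = "parent_zoning"
  )
}

# Classic DBSCAN expansion over a precomputed great-circle distance matrix.
dbscan_core <- function(latitude, longitude, eps_km, min_samples) {
  n <- length(latitude)
  D <- great_circle_matrix(latitude, longitude)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps_km))  # incl. self
  core <- lengths(nb) >= min_samples
  labels <- rep(-1L, n)
  visited <- rep(FALSE, n)
  cluster <- -1L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cluster <- cluster + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cluster
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == -1L) labels[q] <- cluster   # border or new core
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          labels[q] <- cluster
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' @export
print.parent_zoning <- function(x, ...) {
  cat("Parent-material zoning:", x$n_zones, "zone(s),",
      sum(x$is_noise), "noise site(s)\n")
  invisible(x)
}

#' Classify sites into organic-rich, mineral-rich or mixed types
#'
#' The organic index is the organic-matter content (g/kg); the mineral
#' index is the mean of the dataset-standardized free/amorphous Fe and Mn
#' fractions. A site is `ORGANIC_RICH` when only its organic index exceeds
#' its threshold, `MINERAL_RICH` when only the mineral index does, and
#' `MIXED` otherwise (both above or both below). Default thresholds are
#' the 60th percentile of each index over the table.
#'
#' @param table Sample table with `organic_matter`, `free_fe`,
#'   `amorphous_fe`, `free_mn`, `amorphous_mn`.
#' @param t_o,t_m Explicit thresholds for the organic and mineral indices;
#'   if `NULL` they are taken as the `quantile_prob` quantile.
#' @param quantile_prob Quantile used for default thresholds (0.6).
#' @return Object of class `env_type_assignment`: `labels` (character in
#'   ORGANIC_RICH / MINERAL_RICH / MIXED), the indices, the thresholds used
#'   and `m_eit`, the pairwise same-type 0/1 matrix.
#' @export
classify_env_types <- function(table, t_o = NULL, t_m = NULL,
                               quantile_prob = 0.6) {
  needed <- c("organic_matter", "free_fe", "amorphous_fe", "free_mn",
              "amorphous_mn")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in needed) {
    if (any(!is.finite(table[[col]]))) {
      stop("non-finite values in column '", col, "' at row(s) ",
           paste(which(!is.finite(table[[col]])), collapse = ", "))
    }
  }
  organic <- table$organic_matter
  minerals <- scale(as.matrix(table[, c("free_fe", "amorphous_fe",
                                        "free_mn", "amorphous_mn")]))
  minerals[is.nan(minerals)] <- 0  # constant column: no information
  mineral <- rowMeans(minerals)
  if (is.null(t_o)) t_o <- stats::quantile(organic, quantile_prob, names = FALSE)
  if (is.null(t_m)) t_m <- stats::quantile(mineral, quantile_prob, names = FALSE)
  labels <- ifelse(organic > t_o & mineral <= t_m, "ORGANIC_RICH",
            ifelse(mineral > t_m & organic <= t_o, "MINERAL_RICH", "MIXED"))
  structure(
    list(labels = labels, organic_index = organic, mineral_index = mineral,
         t_o = t_o, t_m = t_m, m_eit = env_type_matrix(labels)),
    class = "env_type_assignment"
  )
}

#' @export
print.env_type_assignment <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Pairwise same-type matrix
#'
#' `M[i, j] = 1` iff sites i and j carry the same environmental-type
#' label; reflexive and symmetric (an equivalence-relation matrix).
#'
#' @param labels One label per node (character/factor).
#' @return n x n 0/1 matrix.
#' @export
env_type_matrix <- function(labels) {
  labels <- as.character(labels)
  outer(labels, labels, FUN = "==") * 1
}

#' Mask an adjacency matrix by type agreement (Hadamard product)
#'
#' `A' = A * M` elementwise; masking never adds edges.
#'
#' @param A Binary adjacency.
#' @param m_eit Same-type matrix from [env_type_matrix()].
#' @return Masked binary adjacency.
#' @export
mask_adjacency <- function(A, m_eit) {
  if (!all(dim(A) == dim(m_eit))) stop("shape mismatch between A and M_eit")
  A * m_eit
}

#' Build the parent-material-aware spatial graph
#'
#' Same pipeline as [build_fixed_graph()] but the radius adjacency is first
#' masked by environmental-type agreement: neighbors of a different type
#' are removed before the reachability check, so connectivity repair edges
#' are the only cross-type edges. Weights are the Gaussian kernel
#' restricted to the repaired edge set.
#'
#' @param table Sample table.
#' @param d Radius in km (default 10).
#' @param theta Kernel width in km (default 5, as for the fixed graph).
#' @param labels Environmental-type label per site (e.g. from
#'   [classify_env_types()]), or an `env_type_assignment`.
#' @return A connected `soil_graph` with `params$masked = TRUE`.
#' @export
build_parent_material_graph <- function(table, d = 10, theta = 5, labels) {
  if (inherits(labels, "env_type_assignment")) labels <- labels$labels
  if (nrow(table) < 2) stop("insufficient sites: need n >= 2")
  if (length(labels) != nrow(table)) stop("labels must cover all sites")
  D <- great_circle_matrix(table$latitude, table$longitude)
  A0 <- build_radius_adjacency(radius_neighbors(D, d))
  A1 <- mask_adjacency(A0, env_type_matrix(labels))
  rep_out <- connect_components(A1, D)
  W <- gaussian_weighted_adjacency(rep_out$adjacency, D, theta)
  new_soil_graph(table, D, rep_out$adjacency, W, rep_out$repair_edges,
                 d = d, theta = theta, masked = TRUE, labels = labels)
}

#' Dynamic sequence of weighted adjacency matrices
#'
#' Applies [build_parent_material_graph()] independently to each snapshot
#' of site positions (e.g. externally predicted future positions) and
#' returns the weighted adjacency of each.
#'
#' @param positions List of data.frames, each with `latitude` and
#'   `longitude` for every site (same number of rows in every snapshot).
#' @param labels Environmental-type labels, either one vector shared by all
#'   snapshots or a list with one vector per snapshot.
#' @param d,theta Graph parameters as in [build_parent_material_graph()].
#' @return List of weighted adjacency matrices, one per snapshot.
#' @export
dynamic_adjacency_sequence <- function(positions, labels, d = 10, theta = 5) {
  stopifnot(is.list(positions), length(positions) >= 1)
  n <- nrow(positions[[1]])
  per_snapshot <- is.list(labels) && !is.data.frame(labels)
  lapply(seq_along(positions), function(t) {
    pos <- positions[[t]]
    if (nrow(pos) != n) stop("ragged snapshots: all must have ", n, " sites")
    lab <- if (per_snapshot) labels[[t]] else labels
    tab <- data.frame(sample_id = as.character(seq_len(n)),
                      latitude = pos$latitude, longitude = pos$longitude)
    build_parent_material_graph(tab, d = d, theta = theta, labels = lab)$weights
  })
}

#' Export zone and type assignments as CSV
#'
#' @param table Sample table (for ids).
#' @param zoning A `parent_zoning` (or `NULL`).
#' @param env_types An `env_type_assignment` (or `NULL`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_zone_assignments_csv <- function(table, zoning = NULL, env_types = NULL,
                                       path) {
  out <- data.frame(sample_id = as.character(table$sample_id))
  if (!is.null(zoning)) out$zone <- zoning$labels
  if (!is.null(env_types)) out$env_type <- env_types$labels
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
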