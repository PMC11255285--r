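# Fixtures built in code: small valid survey tables and toy graphs.

make_test_table <- function(n = 10, seed = 42, lat0 = 23.0, lon0 = 111.0,
                            spread = 0.05) {
  set.seed(seed)
  tex <- matrix(stats::runif(3 * n, 1, 4), n, 3)
  tex <- 100 * tex / rowSums(tex)
  data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    latitude = lat0 + stats::rnorm(n, sd = spread),
    longitude = lon0 + stats::rnorm(n, sd = spread),
    pollution_type = sample(c("background", "industrial"), n, replace = TRUE),
    crop = sample(c("rice", "maize"), n, replace = TRUE),
    organic_matter = stats::runif(n, 10, 50),
    doc = stats::runif(n, 50, 300),
    ph = stats::runif(n, 4.5, 8),
    free_fe = stats::runif(n, 5, 40),
    amorphous_fe = stats::runif(n, 0.5, 5),
    free_mn = stats::runif(n, 100, 800),
    amorphous_mn = stats::runif(n, 50, 400),
    cec = stats::runif(n, 5, 25),
    sand_pct = tex[, 1], clay_pct = tex[, 2], silt_pct = tex[, 3],
    parent_material = sample(c("limestone", "granite"), n, replace = TRUE),
    cd = stats::rlnorm(n, 0, 0.5),
    pb = stats::rlnorm(n, 4, 0.5),
    stringsAsFactors = FALSE
  )
}

# Table whose sites sit at given km offsets east of a base point (equator
# scale: 1 degree longitude = 111.195 km at latitude 0).
table_at_km <- function(km_east, lat = 0) {
  n <- length(km_east)
  tbl <- make_test_table(n, seed = 7)
  tbl$latitude <- rep(lat, n)
  tbl$longitude <- km_east / (111.19492664455873 * cos(lat * pi / 180))
  tbl
}

random_adjacency <- function(n, p = 0.2) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1
  A + t(A)
}

# Independent component labeling via igraph (BFS/union-find oracle).
igraph_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::components(g)
}

# Warshall transitive closure oracle over the reflexive relation.
warshall_closure <- function(A) {
  n <- nrow(A)
  R <- (A + diag(n)) > 0
  for (k in seq_len(n)) {
    R <- R | (outer(R[, k], R[k, ], FUN = "&"))
  }
  R * 1
}
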