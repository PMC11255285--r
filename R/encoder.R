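# Feature encoding: one-hot categories and train-only standardization.

#' Fit a feature encoder on training nodes
#'
#' Builds the design-matrix recipe for the 15 predictors: continuous
#' columns are standardized with mean/sd estimated on the training rows
#' only (no leakage); `pollution_type` and `crop` are one-hot encoded over
#' the category levels seen in training.
#'
#' @param table Sample table.
#' @param train_index Integer indices of the training rows (non-empty).
#' @return Object of class `feature_encoder` with the per-column centers
#'   and scales, the category level maps and the ordered output
#'   `feature_names`.
#' @export
fit_feature_encoder <- function(table, train_index) {
  if (length(train_index) == 0) stop("train_index must be non-empty")
  cont <- .continuous_predictors
  centers <- scales <- numeric(length(cont))
  names(centers) <- names(scales) <- cont
  for (col in cont) {
    v <- table[[col]][train_index]
    centers[col] <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-8) {
      warning("constant continuous column '", col, "': sd floored at 1e-8")
      s <- 1e-8
    }
    scales[col] <- s
  }
  levels_map <- lapply(.categorical_predictors, function(col) {
    sort(unique(as.character(table[[col]][train_index])))
  })
  names(levels_map) <- .categorical_predictors
  feature_names <- c(
    cont,
    unlist(lapply(.categorical_predictors, function(col) {
      paste0(col, "=", levels_map[[col]])
    }))
  )
  structure(
    list(centers = centers, scales = scales, levels = levels_map,
         feature_names = feature_names),
    class = "feature_encoder"
  )
}

#' Encode a table into the model design matrix
#'
#' @param encoder A fitted [fit_feature_encoder()].
#' @param table Sample table to transform (any rows).
#' @return Numeric matrix, one row per table row, columns in
#'   `encoder$feature_names` order. Unseen category levels map to an
#'   all-zero block with a warning.
#' @export
encode_features <- function(encoder, table) {
  stopifnot(inherits(encoder, "feature_encoder"))
  n <- nrow(table)
  blocks <- list()
  cont <- .continuous_predictors
  Xc <- sapply(cont, function(col) {
    (table[[col]] - encoder$centers[col]) / encoder$scales[col]
  })
  if (n == 1) Xc <- matrix(Xc, nrow = 1, dimnames = list(NULL, cont))
  blocks[["continuous"]] <- Xc
  for (col in .categorical_predictors) {
    lev <- encoder$levels[[col]]
    vals <- as.character(table[[col]])
    unseen <- setdiff(unique(vals), lev)
    if (length(unseen)) {
      warning("unseen ", col, " level(s) at transform time: ",
              paste(unseen, collapse = ", "), " (encoded as all-zero)")
    }
    B <- matrix(0, n, length(lev),
                dimnames = list(NULL, paste0(col, "=", lev)))
    hit <- match(vals, lev)
    ok <- !is.na(hit)
    B[cbind(which(ok), hit[ok])] <- 1
    blocks[[col]] <- B
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- encoder$feature_names
  X
}
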