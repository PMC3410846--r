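#' Principal components of the non-allometric shape residuals
#'
#' Eigendecomposition of the specimen-level covariance matrix of the shape
#' residuals. PCs are ordered by decreasing eigenvalue; for reproducibility
#' each loading vector is signed so that its largest-magnitude entry is
#' positive.
#'
#' @param residuals An [allometric_regression()] fit, or a plain numeric
#'   matrix of specimens x coordinates.
#' @param n_pc Number of PCs to retain in the scores (default all non-null).
#' @return Object of class `shape_space`: list with `mean_shape`, `loadings`
#'   (coordinates x PC), `eigenvalues`, `variance_fractions` (sum to 1),
#'   `scores` (tibble: specimen metadata + PC columns), `landmark_ids`.
#' @export
shape_pca <- function(residuals, n_pc = NULL) {
  samples <- NULL; lm_ids <- NULL; mean_shape <- NULL
  if (inherits(residuals, "allometry_fit")) {
    samples <- residuals$samples
    lm_ids <- residuals$landmark_ids
    mean_shape <- residuals$mean_shape
    residuals <- residuals$residuals
  }
  X <- as.matrix(residuals)
  n <- nrow(X)
  if (n < 2) abort("shape PCA needs at least 2 specimens")
  Xc <- sweep(X, 2, colMeans(X))
  if (is.null(mean_shape)) mean_shape <- colMeans(X)
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  vf <- if (sum(vals) > 0) vals / sum(vals) else vals
  keep <- if (is.null(n_pc)) min(n - 1, ncol(X)) else min(n_pc, ncol(X))
  sc <- Xc %*% vecs[, seq_len(keep), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(keep))
  scores <- if (!is.null(samples)) dplyr::bind_cols(samples, as_tibble(sc))
  else tibble(specimen_id = rownames(X) %||% as.character(seq_len(n))) %>%
    dplyr::bind_cols(as_tibble(sc))
  structure(list(mean_shape = mean_shape, loadings = vecs,
                 eigenvalues = vals, variance_fractions = vf,
                 scores = scores, landmark_ids = lm_ids),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  top <- head(x$variance_fractions, 4)
  cat("Shape space:", nrow(x$scores), "specimens;",
      "top PCs explain", paste0(sprintf("%.1f%%", 100 * top), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn shape_pca Per-PC eigenvalues and variance fractions
#' @param x A `shape_space`.
#' @param ... Unused.
#' @export
tidy.shape_space <- function(x, ...) {
  tibble(pc = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         variance_fraction = x$variance_fractions,
         cumulative = cumsum(x$variance_fractions))
}

#' @describeIn shape_pca Scree plot of the eigenvalue spectrum
#' @param object A `shape_space`.
#' @param n_pc Number of PCs to display.
#' @export
autoplot.shape_space <- function(object, n_pc = 10, ...) {
  d <- head(tidy(object), n_pc)
  ggplot(d, aes(x = .data$pc, y = 100 * .data$variance_fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = "Principal component", y = "% shape variance") +
    theme_minimal()
}

#' Morph landmark coordinates along a shape PC
#'
#' Returns `mean shape + c * loading vector`, reshaped to landmark
#' coordinates, i.e. the configuration a specimen scoring `c` on that PC (and
#' zero on all others) would have.
#'
#' @param space A `shape_space`.
#' @param pc PC index.
#' @param c Score along the PC.
#' @return Tibble with `landmark_id, x, y, z`.
#' @export
morph_along_pc <- function(space, pc = 1L, c = 0) {
  if (pc < 1 || pc > ncol(space$loadings)) abort("pc index out of range")
  v <- space$mean_shape + c * space$loadings[, pc]
  M <- matrix(v, ncol = 3, byrow = TRUE)
  ids <- space$landmark_ids %||% seq_len(nrow(M))
  tibble(landmark_id = as.integer(ids), x = M[, 1], y = M[, 2], z = M[, 3])
}

#' Breed-sex phenotype averages
#'
#' Collapses specimen-level PC scores (and the log size covariate) to one row
#' per (breed, sex): the arithmetic mean, with groups of size one passing the
#' single specimen's value through unchanged.
#'
#' @param scores The `scores` tibble of a `shape_space` (or any tibble with
#'   `breed`, `sex`, PC columns, and optionally a log size column).
#' @return Tibble keyed by `(breed, sex)` with averaged PC columns, the
#'   averaged log size covariate, and `n_specimens`.
#' @export
breed_sex_average <- function(scores) {
  if (inherits(scores, "shape_space")) scores <- scores$scores
  if (!all(c("breed", "sex") %in% names(scores))) {
    abort("scores must carry breed and sex metadata")
  }
  num_cols <- names(scores)[grepl("^PC\\d+$", names(scores))]
  size_cols <- intersect(c("log_neuro_centroid", "log_centroid"), names(scores))
  scores %>%
    group_by(.data$breed, .data$sex) %>%
    summarise(across(all_of(c(num_cols, size_cols)), mean),
              n_specimens = dplyr::n(), .groups = "drop") %>%
    arrange(.data$breed, .data$sex)
}
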