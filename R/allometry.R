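#' Pooled within-group allometric regression
#'
#' Regresses the superimposed shape coordinates on log centroid size with the
#' common slope estimated from variation *within* breed-sex groups: group
#' means are removed from both shape and size before fitting, so between-group
#' shape differences do not drive the slope. Significance is assessed by
#' permuting size values within groups and counting permutations whose
#' within-group variance explained is at least the observed one, with the
#' (b + 1) / (n_perm + 1) estimator so p is never exactly zero.
#'
#' Residuals (the non-allometric shape component) keep between-group
#' variation: residual = (shape - grand mean) - slope * (size - grand mean
#' size). These feed the shape PCA.
#'
#' @param fit A [gpa()] result. The size covariate is `log_neuro_centroid`
#'   when a neurocranium subset was given, else `log_centroid`.
#' @param n_perm Number of within-group permutations (default 10000).
#' @param groups Optional factor/character overriding the breed-sex grouping.
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `allometry_fit`: list with `slope` (3k vector),
#'   `pct_var_explained` (within-group %), `permutation_p`, `residuals`
#'   (n x 3k), `fitted`, `samples`, `size_var`, `n_perm`.
#' @export
allometric_regression <- function(fit, n_perm = 10000L, groups = NULL,
                                  seed = NULL) {
  stopifnot(inherits(fit, "shape_gpa"))
  if (n_perm < 1) abort("n_perm must be >= 1")
  size_var <- if ("log_neuro_centroid" %in% names(fit$samples))
    "log_neuro_centroid" else "log_centroid"
  y <- fit$aligned
  x <- fit$samples[[size_var]]
  if (is.null(groups)) {
    groups <- paste(fit$samples$breed, fit$samples$sex, sep = ":")
  }
  groups <- as.factor(groups)
  x_til <- x - stats::ave(x, groups)
  if (sum(x_til^2) < 1e-12) {
    # singleton breed-sex cells leave no within-group variation; fall back to
    # pooling by breed
    if ("breed" %in% names(fit$samples) &&
        nlevels(as.factor(fit$samples$breed)) < nlevels(groups)) {
      warn("no within-group size variance at breed-sex level; pooling by breed")
      groups <- as.factor(fit$samples$breed)
      x_til <- x - stats::ave(x, groups)
    }
  }
  if (sum(x_til^2) < 1e-12) abort("zero within-group size variance")
  g_idx <- split(seq_along(x), groups)
  y_til <- y - apply(y, 2, function(col) ave(col, groups))

  slope_of <- function(xc) as.vector(crossprod(xc, y_til)) / sum(xc^2)
  pct_of <- function(xc) {
    b <- slope_of(xc)
    100 * sum(xc^2) * sum(b^2) / sum(y_til^2)
  }
  slope <- slope_of(x_til)
  pct <- pct_of(x_til)

  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  hits <- 0L
  for (b in seq_len(n_perm)) {
    xp <- x_til
    for (ix in g_idx) xp[ix] <- xp[ix][sample.int(length(ix))]
    if (pct_of(xp) >= pct) hits <- hits + 1L
  }
  p <- (hits + 1) / (n_perm + 1)

  x_dev <- x - mean(x)
  fitted <- outer(x_dev, slope)
  residuals <- sweep(y, 2, colMeans(y)) - fitted
  structure(list(slope = slope, pct_var_explained = pct, permutation_p = p,
                 residuals = residuals, fitted = fitted,
                 samples = fit$samples, size_var = size_var,
                 landmark_ids = fit$landmark_ids,
                 mean_shape = colMeans(y), n_perm = n_perm),
            class = "allometry_fit")
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv)
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric regression on %s: %.2f%% of within-group shape variance; permutation p = %.4g (%d permutations)\n",
    x$size_var, x$pct_var_explained, x$permutation_p, x$n_perm))
  invisible(x)
}

#' @describeIn allometric_regression One-row model summary
#' @param x An `allometry_fit`.
#' @param ... Unused.
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble(pct_var_explained = x$pct_var_explained,
         permutation_p = x$permutation_p,
         n_perm = x$n_perm, size_var = x$size_var,
         n_specimens = nrow(x$residuals))
}

#' @describeIn allometric_regression Per-coordinate slope estimates
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble(coordinate = colnames(x$residuals) %||% seq_along(x$slope),
         slope = x$slope)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
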