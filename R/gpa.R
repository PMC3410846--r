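#' Generalized Procrustes superimposition
#'
#' Iterative full Procrustes fit: each configuration is centred, scaled to
#' unit centroid size, and rotated to the current mean shape; the mean is
#' re-estimated (and rescaled to unit centroid size) until its change falls
#' below `tol` or `max_iter` iterations. Centroid sizes (and, if a subset is
#' given, neurocranium centroid sizes) are recorded before scaling.
#'
#' Specimens whose landmark id set differs from the modal id set are excluded
#' with a warning (no imputation of missing landmarks).
#'
#' @param landmarks Long landmark tibble (one configuration per specimen; use
#'   [merge_views()] first for dual-view data).
#' @param neuro_subset Optional integer ids of the neurocranium landmark
#'   subset used for the size covariate.
#' @param tol,max_iter Convergence control for the mean shape.
#' @return An object of class `shape_gpa`: list with `aligned` (n x 3k matrix,
#'   specimens in rows), `mean_shape` (3k vector), `samples` (tibble with
#'   `specimen_id, breed, sex, centroid_size, log_centroid`, plus
#'   `neuro_centroid_size` and `log_neuro_centroid` when `neuro_subset` is
#'   given), `landmark_ids`, `iterations`, `converged`.
#' @export
gpa <- function(landmarks, neuro_subset = NULL, tol = 1e-10, max_iter = 100L) {
  ids_by_spec <- split(landmarks$landmark_id, landmarks$specimen_id)
  id_sets <- purrr::map_chr(ids_by_spec, ~ paste(sort(.x), collapse = ","))
  modal <- names(sort(table(id_sets), decreasing = TRUE))[1]
  bad <- names(id_sets)[id_sets != modal]
  if (length(bad) > 0) {
    warn(paste0("excluding ", length(bad),
                " specimen(s) with missing/extra landmarks: ",
                paste(bad, collapse = ", ")))
    landmarks <- landmarks[!landmarks$specimen_id %in% bad, ]
  }
  specs <- split(landmarks, landmarks$specimen_id)
  if (length(specs) < 2) abort("GPA needs at least 2 complete configurations")
  mats <- purrr::map(specs, lm_matrix)
  lm_ids <- as.integer(rownames(mats[[1]]))
  k <- length(lm_ids)

  cs <- purrr::map_dbl(mats, function(M) sqrt(sum(sweep(M, 2, colMeans(M))^2)))
  if (any(cs <= 0)) abort("degenerate configuration with zero centroid size")
  scaled <- purrr::map2(mats, cs, function(M, s) sweep(M, 2, colMeans(M)) / s)

  ref <- scaled[[1]]
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    rot <- purrr::map(scaled, function(M) {
      f <- rigid_fit(M, ref)   # centred, so translation ~ 0
      M %*% t(f$R)
    })
    new_mean <- Reduce(`+`, rot) / length(rot)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - ref)^2))
    ref <- new_mean
    scaled <- rot
    if (delta < tol) { converged <- TRUE; break }
  }

  # canonical orientation: principal axes of the consensus, signs fixed, so
  # the fit does not depend on the (arbitrary) orientation of the first
  # input; signs come from a landmark-index-weighted functional, which is
  # stable under small consensus perturbations (an entrywise argmax is not)
  ev <- eigen(crossprod(ref), symmetric = TRUE)$vectors
  wts <- seq_len(nrow(ref))
  for (j in 1:3) {
    h <- sum(wts * (ref %*% ev[, j]))
    if (abs(h) < 1e-9) h <- ev[which.max(abs(ev[, j])), j]
    if (h < 0) ev[, j] <- -ev[, j]
  }
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  ref <- ref %*% ev
  scaled <- purrr::map(scaled, function(M) M %*% ev)

  aligned <- t(vapply(scaled, function(M) as.vector(t(M)), numeric(3 * k)))
  colnames(aligned) <- paste0(rep(lm_ids, each = 3), "_", c("x", "y", "z"))
  meta <- landmarks %>%
    distinct(.data$specimen_id, .data$breed, .data$sex) %>%
    arrange(match(.data$specimen_id, names(specs)))
  samples <- tibble(specimen_id = names(specs)) %>%
    left_join(meta, by = "specimen_id") %>%
    mutate(centroid_size = unname(cs), log_centroid = log(.data$centroid_size))
  if (!is.null(neuro_subset)) {
    ncs <- centroid_size(landmarks, subset = neuro_subset)
    samples <- samples %>%
      left_join(rename(ncs, neuro_centroid_size = "centroid_size"),
                by = "specimen_id") %>%
      mutate(log_neuro_centroid = log(.data$neuro_centroid_size))
  }
  structure(list(aligned = aligned,
                 mean_shape = as.vector(t(ref)),
                 samples = samples, landmark_ids = lm_ids,
                 iterations = iterations, converged = converged),
            class = "shape_gpa")
}

#' @export
print.shape_gpa <- function(x, ...) {
  cat("Generalized Procrustes fit:", nrow(x$aligned), "specimens,",
      length(x$landmark_ids), "landmarks;",
      x$iterations, "iterations",
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

#' @describeIn gpa Aligned coordinates as a long tibble
#' @param x A `shape_gpa` object.
#' @param ... Unused.
#' @export
tidy.shape_gpa <- function(x, ...) {
  k <- length(x$landmark_ids)
  purrr::map_dfr(seq_len(nrow(x$aligned)), function(i) {
    M <- matrix(x$aligned[i, ], ncol = 3, byrow = TRUE)
    tibble(specimen_id = x$samples$specimen_id[i],
           landmark_id = x$landmark_ids,
           x = M[, 1], y = M[, 2], z = M[, 3])
  })
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes distance: both configurations are centred and scaled to
#' unit centroid size, one is rotated onto the other, and the root summed
#' squared difference is returned.
#'
#' @param a,b k x d coordinate matrices with matching rows.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  if (ncol(a) == 2) { a <- cbind(a, 0); b <- cbind(b, 0) }
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  ca <- ca / sqrt(sum(ca^2)); cb <- cb / sqrt(sum(cb^2))
  f <- rigid_fit(ca, cb)
  sqrt(sum((ca %*% t(f$R) - cb)^2))
}
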