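#' Read a landmark coordinate table
#'
#' Landmarks are stored long: one row per digitized point, with specimen
#' metadata repeated. Coordinates are in millimetres.
#'
#' @param path CSV file with columns `specimen_id, breed, sex, view,
#'   landmark_id, x, y, z`.
#' @return A tibble with those columns; `landmark_id` is integer, `sex` one of
#'   `"M"`/`"F"`, `view` one of `"dorsal"`, `"ventral"`, `"merged"`.
#' @export
read_landmarks <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           specimen_id = readr::col_character(),
                           breed = readr::col_character(),
                           sex = readr::col_character(),
                           view = readr::col_character(),
                           landmark_id = readr::col_integer(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           z = readr::col_double()))
  validate_landmarks(tbl)
}

#' @rdname read_landmarks
#' @param landmarks A landmark tibble to write.
#' @export
write_landmarks <- function(landmarks, path) {
  readr::write_csv(landmarks, path)
  invisible(path)
}

validate_landmarks <- function(tbl) {
  need <- c("specimen_id", "breed", "sex", "view", "landmark_id", "x", "y", "z")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("landmark table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(c(tbl$x, tbl$y, tbl$z)))) {
    abort("landmark coordinates must be finite")
  }
  dup <- tbl %>%
    dplyr::count(.data$specimen_id, .data$view, .data$landmark_id) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated landmark ids within a configuration: specimen ",
                 paste(unique(dup$specimen_id), collapse = ", ")))
  }
  as_tibble(tbl)
}

# one specimen-view's rows -> k x 3 matrix with landmark ids as rownames
lm_matrix <- function(config) {
  config <- arrange(config, .data$landmark_id)
  m <- as.matrix(config[, c("x", "y", "z")])
  rownames(m) <- config$landmark_id
  m
}

lm_from_matrix <- function(m, meta, view = meta$view[1]) {
  tibble(specimen_id = meta$specimen_id[1], breed = meta$breed[1],
         sex = meta$sex[1], view = view,
         landmark_id = as.integer(rownames(m)),
         x = m[, 1], y = m[, 2], z = m[, 3])
}

# least-squares rigid transform (rotation + translation, no scaling, no
# reflection) mapping rows of A onto rows of B
rigid_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cb - as.vector(R %*% ca)
  list(R = R, t = t_vec)
}

apply_rigid <- function(A, fit) {
  sweep(A %*% t(fit$R), 2, fit$t, "+")
}

#' Merge dorsal and ventral landmark views of the same skull
#'
#' Dorsal and ventral landmark sets are digitized separately; they are merged
#' by fitting the least-squares rigid transform (rotation + translation, no
#' scaling, since both views digitize the same physical skull) on the
#' landmarks shared between views, mapping the ventral configuration into the
#' dorsal frame. Shared landmarks take the average of the two mapped
#' positions.
#'
#' @param landmarks Long landmark tibble holding `dorsal` and `ventral` views
#'   for one or more specimens.
#' @param shared_ids Integer ids of landmarks digitized in both views
#'   (default `c(1, 2, 28, 29)`).
#' @return A tibble of `merged` configurations (union of ids per specimen),
#'   with attribute `"merge_rms"`: a tibble of per-specimen RMS discrepancy
#'   (mm) over the shared landmarks after mapping.
#' @export
merge_views <- function(landmarks, shared_ids = c(1L, 2L, 28L, 29L)) {
  shared_ids <- as.integer(shared_ids)
  if (length(shared_ids) < 3) {
    abort(paste0("need at least 3 shared landmarks, got ids: ",
                 paste(shared_ids, collapse = ", ")))
  }
  specs <- unique(landmarks$specimen_id)
  out <- vector("list", length(specs))
  rms <- numeric(length(specs))
  for (i in seq_along(specs)) {
    sp <- landmarks[landmarks$specimen_id == specs[i], ]
    dor <- sp[sp$view == "dorsal", ]
    ven <- sp[sp$view == "ventral", ]
    for (v in list(dor, ven)) {
      got <- setdiff(shared_ids, v$landmark_id)
      if (length(got) > 0) {
        abort(paste0("specimen ", specs[i], ": shared landmark ids missing from ",
                     v$view[1], " view: ", paste(got, collapse = ", ")))
      }
    }
    Md <- lm_matrix(dor); Mv <- lm_matrix(ven)
    Ad <- Md[as.character(shared_ids), , drop = FALSE]
    Av <- Mv[as.character(shared_ids), , drop = FALSE]
    # collinear shared landmarks leave the roll about their axis unconstrained
    sv <- svd(sweep(Av, 2, colMeans(Av)))$d
    if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
      abort(paste0("shared landmarks are (near-)collinear for specimen ",
                   specs[i], ": ids ", paste(shared_ids, collapse = ", ")))
    }
    fit <- rigid_fit(Av, Ad)
    Mv_t <- apply_rigid(Mv, fit)
    rms[i] <- sqrt(mean(rowSums((apply_rigid(Av, fit) - Ad)^2)))
    only_v <- setdiff(rownames(Mv_t), rownames(Md))
    shared_chr <- as.character(shared_ids)
    merged <- rbind(Md, Mv_t[only_v, , drop = FALSE])
    merged[shared_chr, ] <- (Md[shared_chr, , drop = FALSE] +
                               Mv_t[shared_chr, , drop = FALSE]) / 2
    merged <- merged[order(as.integer(rownames(merged))), , drop = FALSE]
    out[[i]] <- lm_from_matrix(merged, dor, view = "merged")
  }
  res <- bind_rows(out)
  attr(res, "merge_rms") <- tibble(specimen_id = specs, rms = rms)
  res
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances of the landmarks from their centroid. A landmark
#' subset (e.g. the neurocranium landmarks) may be supplied to compute a
#' regional size such as the neurocranium centroid size.
#'
#' @param landmarks Long landmark tibble (any number of specimens).
#' @param subset Optional integer vector of landmark ids to restrict to.
#' @return Tibble with `specimen_id` and `centroid_size` (mm).
#' @export
centroid_size <- function(landmarks, subset = NULL) {
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (length(subset) < 2) abort("centroid size needs at least 2 landmarks")
    miss <- landmarks %>%
      group_by(.data$specimen_id) %>%
      summarise(missing = list(setdiff(subset, .data$landmark_id)), .groups = "drop") %>%
      filter(lengths(.data$missing) > 0)
    if (nrow(miss) > 0) {
      abort(paste0("subset landmarks missing for specimen ",
                   miss$specimen_id[1], ": ",
                   paste(miss$missing[[1]], collapse = ", ")))
    }
    landmarks <- landmarks[landmarks$landmark_id %in% subset, ]
  }
  landmarks %>%
    group_by(.data$specimen_id) %>%
    summarise(centroid_size = sqrt(sum((.data$x - mean(.data$x))^2 +
                                         (.data$y - mean(.data$y))^2 +
                                         (.data$z - mean(.data$z))^2)),
              .groups = "drop")
}

#' Symmetric component of a bilateral landmark configuration
#'
#' For object-symmetric structures the configuration is averaged with its
#' relabeled mirror image: the copy is reflected, paired left/right landmark
#' labels are swapped (midline labels map to themselves), the reflected copy
#' is rigidly aligned back onto the original, and the two are averaged. The
#' result is invariant to reflecting the input.
#'
#' @param landmarks Long landmark tibble.
#' @param pairing List with integer vectors `left`, `right` (equal length,
#'   positionally paired) and `midline`. Together they must cover every
#'   landmark id present.
#' @return Tibble of symmetric-component configurations (same ids).
#' @export
symmetric_component <- function(landmarks, pairing) {
  left <- as.integer(pairing$left); right <- as.integer(pairing$right)
  midline <- as.integer(pairing$midline)
  if (length(left) != length(right)) abort("left/right pairing lengths differ")
  ids_all <- sort(unique(landmarks$landmark_id))
  unpaired <- setdiff(ids_all, c(left, right, midline))
  if (length(unpaired) > 0) {
    abort(paste0("unpaired landmark ids: ", paste(unpaired, collapse = ", ")))
  }
  relabel <- c(setNames(right, left), setNames(left, right),
               setNames(midline, midline))
  specs <- split(landmarks, landmarks$specimen_id)
  out <- purrr::map(specs, function(sp) {
    M <- lm_matrix(sp)
    Mr <- M
    Mr[, 2] <- -Mr[, 2]                       # reflect
    rownames(Mr) <- as.character(relabel[rownames(Mr)])  # relabel pairs
    Mr <- Mr[rownames(M), , drop = FALSE]
    fit <- rigid_fit(Mr, M)                   # align mirror back onto original
    lm_from_matrix((M + apply_rigid(Mr, fit)) / 2, sp)
  })
  bind_rows(out)
}
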