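# shared in-code fixtures

# long landmark tibble from a k x 3 matrix
lm_tbl <- function(M, specimen = "s1", breed = "B", sex = "F",
                   view = "merged", ids = seq_len(nrow(M))) {
  tibble::tibble(specimen_id = specimen, breed = breed, sex = sex,
                 view = view, landmark_id = as.integer(ids),
                 x = M[, 1], y = M[, 2], z = M[, 3])
}

# generic non-degenerate 3-D configuration (deterministic)
toy_shape <- function(k = 8, scale = 10) {
  t <- seq_len(k)
  cbind(x = scale * cos(t), y = scale * 0.6 * sin(1.7 * t),
        z = scale * 0.3 * sin(0.9 * t + 1))
}

rot3 <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Rx %*% Ry %*% Rz
}

toy_geno <- function(calls, chrom = NULL, pos = NULL, breeds = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls); n <- nrow(calls)
  geno_matrix(calls,
              tibble::tibble(marker_id = paste0("m", seq_len(m)),
                             chrom = chrom %||% rep("1", m),
                             pos = pos %||% (100L * seq_len(m))),
              tibble::tibble(sample_id = paste0("s", seq_len(n)),
                             breed = breeds %||% rep("B", n),
                             sex = rep(c("M", "F"), length.out = n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal hand-made shape_gpa object for allometry tests
fake_gpa <- function(aligned, breed, sex, log_size) {
  structure(list(aligned = aligned,
                 mean_shape = colMeans(aligned),
                 samples = tibble::tibble(
                   specimen_id = paste0("sp", seq_len(nrow(aligned))),
                   breed = breed, sex = sex,
                   centroid_size = exp(log_size),
                   log_centroid = log_size,
                   neuro_centroid_size = exp(log_size),
                   log_neuro_centroid = log_size),
                 landmark_ids = seq_len(ncol(aligned) / 3),
                 iterations = 1L, converged = TRUE),
            class = "shape_gpa")
}

# numeric maximum-likelihood oracle for haplotype frequencies: direct
# maximization of the marginal multinomial likelihood over the frequency
# simplex (softmax parametrization, multi-start quasi-Newton); independent of
# the EM implementation
hap_ml_oracle <- function(calls, n_starts = 6) {
  m <- ncol(calls); nh <- 2L^m
  pairs <- lapply(seq_len(nrow(calls)), function(i) {
    geno <- calls[i, ]
    het <- which(geno == 1L)
    base <- sum(2L^(which(geno == 2L) - 1L))
    if (length(het) == 0) return(cbind(base, base))
    combos <- as.matrix(expand.grid(rep(list(0:1), length(het))))
    h1 <- base + combos %*% (2L^(het - 1L))
    h2 <- base + (1 - combos) %*% (2L^(het - 1L))
    keep <- h1 <= h2          # unordered pairs once
    cbind(h1[keep], h2[keep])
  })
  nll <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    -sum(vapply(pairs, function(pp) {
      w <- ifelse(pp[, 1] == pp[, 2], 1, 2)
      log(sum(w * f[pp[, 1] + 1] * f[pp[, 2] + 1]))
    }, numeric(1)))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1) rep(0, nh - 1) else stats::rnorm(nh - 1)
    o <- try(stats::nlminb(th0, nll,
                           control = list(rel.tol = 1e-15, iter.max = 3000)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  f <- exp(c(best$par, 0)); f <- f / sum(f)
  names(f) <- vapply(0:(nh - 1L), function(h)
    paste(as.integer(intToBits(h))[seq_len(m)], collapse = ""), character(1))
  f
}

em_freq_vector <- function(haps, m) {
  nh <- 2L^m
  keys <- vapply(0:(nh - 1L), function(h)
    paste(as.integer(intToBits(h))[seq_len(m)], collapse = ""), character(1))
  f <- setNames(rep(0, nh), keys)
  f[haps$haplotype] <- haps$freq
  f
}
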