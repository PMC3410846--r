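#' Pair genotyped individuals with breed-sex average phenotypes
#'
#' Each genotyped dog carries its breed-sex average shape score and size
#' covariate (the breed-stereotype design: the unit of analysis stays the
#' individual dog). Individuals whose (breed, sex) has no phenotype row are
#' dropped with a message; optionally the opposite sex's average can be used
#' as a fallback (off by default).
#'
#' @param g A `geno_matrix`.
#' @param pheno A [breed_sex_average()] table.
#' @param pc Phenotype column to use (default `"PC1"`).
#' @param sex_fallback If `TRUE`, individuals whose own sex has no phenotype
#'   row fall back to the opposite sex's average.
#' @return Design tibble: `sample_id, breed, sex, phenotype` plus the size
#'   covariate column(s) present in `pheno`.
#' @export
assign_phenotypes <- function(g, pheno, pc = "PC1", sex_fallback = FALSE) {
  size_cols <- intersect(c("log_neuro_centroid", "log_centroid"), names(pheno))
  ph <- pheno %>%
    select("breed", "sex", phenotype = all_of(pc), all_of(size_cols))
  design <- g$samples %>%
    left_join(ph, by = c("breed", "sex"))
  if (sex_fallback) {
    need <- is.na(design$phenotype)
    if (any(need)) {
      opp <- ph %>% mutate(sex = ifelse(.data$sex == "M", "F", "M"))
      fb <- design[need, c("sample_id", "breed", "sex")] %>%
        left_join(opp, by = c("breed", "sex"))
      design$phenotype[need] <- fb$phenotype
      for (sc in size_cols) design[[sc]][need] <- fb[[sc]]
    }
  }
  dropped <- sum(is.na(design$phenotype))
  if (dropped > 0) {
    cs_inform("assign_phenotypes: dropped ", dropped,
              " individual(s) with no matching phenotype row")
  }
  design %>% filter(!is.na(.data$phenotype))
}

new_assoc_result <- function(tbl, model, covariates, extra = list()) {
  out <- as_tibble(tbl)
  attr(out, "model") <- model
  attr(out, "covariates") <- covariates
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("assoc_result", class(out))
  out
}

build_design_matrix <- function(design, covariates) {
  W <- cbind(`(Intercept)` = rep(1, nrow(design)))
  for (cv in covariates) {
    if (!cv %in% names(design)) abort(paste0("covariate not in design: ", cv))
    W <- cbind(W, design[[cv]])
    colnames(W)[ncol(W)] <- cv
  }
  if (qr(W)$rank < ncol(W)) {
    abort(paste0("collinear covariate columns: ",
                 paste(colnames(W), collapse = ", ")))
  }
  W
}

#' Single-marker linear association scan
#'
#' Per-marker ordinary least squares of the phenotype on minor-allele dosage
#' plus covariates, with a two-sided Wald t-test. Individuals missing a
#' marker's call are dropped marker-wise.
#'
#' @param g A `geno_matrix`.
#' @param design An [assign_phenotypes()] tibble (or any tibble with
#'   `sample_id` and `phenotype`).
#' @param covariates Character vector of design columns to adjust for (e.g.
#'   `"log_neuro_centroid"`).
#' @return An `assoc_result` tibble: `marker_id, chrom, pos, beta, se,
#'   p_value, neg_log10_p, n_used`.
#' @export
linear_assoc <- function(g, design, covariates = NULL) {
  covariates <- covariates %||% character()
  idx <- match(design$sample_id, g$samples$sample_id)
  if (anyNA(idx)) abort("design contains samples absent from the genotype matrix")
  X <- g$calls[idx, , drop = FALSE]
  y <- design$phenotype
  W <- build_design_matrix(design, covariates)
  res <- ols_scan(y, X, W)
  new_assoc_result(dplyr::bind_cols(g$markers[, c("marker_id", "chrom", "pos")], res),
                   model = "linear", covariates = covariates)
}

# vectorised per-marker OLS after residualising on W; markers with missing
# calls fall back to a per-marker subset fit
ols_scan <- function(y, X, W) {
  n <- length(y)
  p <- ncol(W)
  qw <- qr(W)
  ry <- qr.resid(qw, y)
  ss_y <- sum(ry^2)
  m <- ncol(X)
  beta <- se <- pv <- rep(NA_real_, m)
  n_used <- rep(n, m)
  has_na <- colSums(is.na(X)) > 0
  if (any(!has_na)) {
    RX <- qr.resid(qw, X[, !has_na, drop = FALSE])
    xx <- colSums(RX^2)
    xy <- as.vector(crossprod(RX, ry))
    df <- n - p - 1
    b <- ifelse(xx > 1e-12, xy / xx, NA_real_)
    rss <- pmax(ss_y - b^2 * xx, 0)
    s2 <- rss / df
    s <- sqrt(s2 / xx)
    tt <- b / s
    pp <- 2 * pt(-abs(tt), df)
    pp[ss_y < 1e-24] <- 1          # constant phenotype: nothing to explain
    pp[!is.finite(pp)] <- NA_real_
    beta[!has_na] <- b; se[!has_na] <- s; pv[!has_na] <- pp
  }
  for (j in which(has_na)) {
    ok <- !is.na(X[, j])
    nj <- sum(ok)
    n_used[j] <- nj
    if (nj < p + 2) next
    sub <- ols_scan(y[ok], X[ok, j, drop = FALSE], W[ok, , drop = FALSE])
    beta[j] <- sub$beta; se[j] <- sub$se; pv[j] <- sub$p_value
  }
  tibble(beta = beta, se = se, p_value = pv,
         neg_log10_p = -log10(pv), n_used = n_used)
}

#' Centered genomic relationship matrix
#'
#' `K = Z Z' / m` where `Z` is the column-centred dosage matrix over the `m`
#' post-QC markers; missing dosages are mean-imputed for `K` only.
#'
#' @param g A `geno_matrix` (after [snp_qc()]).
#' @return Symmetric positive semidefinite matrix, individuals x individuals.
#' @export
kinship <- function(g) {
  Z <- g$calls
  storage.mode(Z) <- "double"
  cm <- colMeans(Z, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) {
    nas <- is.na(Z[, j])
    if (any(nas)) Z[nas, j] <- cm[j]
  }
  Z <- sweep(Z, 2, cm)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(g$samples$sample_id, g$samples$sample_id)
  K
}

# REML criterion for the eigen-rotated single-random-effect model,
# as a function of the log10 variance ratio lambda = sigma_g^2 / sigma_e^2
reml_neg_loglik <- function(log_ratio, ys, Ws, vals) {
  lam <- 10^log_ratio
  V <- lam * vals + 1
  w <- 1 / V
  WtW <- crossprod(Ws * w, Ws)
  Wty <- crossprod(Ws * w, ys)
  alpha <- solve(WtW, Wty)
  r <- ys - Ws %*% alpha
  rss <- sum(r^2 * w)
  n <- length(ys); p <- ncol(Ws)
  0.5 * (sum(log(V)) + determinant(WtW, logarithm = TRUE)$modulus +
           (n - p) * log(rss))
}

#' Kinship-corrected mixed-model association scan
#'
#' Single-random-effect linear mixed model `y = W a + x b + u + e` with
#' `u ~ (0, s_g^2 K)`. `K` is eigendecomposed once; the restricted likelihood
#' is profiled over the variance ratio `s_g^2 / s_e^2` by bounded 1-D search
#' (log10 ratio in `[-5, 5]`, tolerance 1e-6) under the covariate-only model,
#' then each marker is tested by Wald GLS at the fitted ratio. Markers with
#' missing calls are tested on the called subset of individuals (Cholesky GLS
#' on the corresponding submatrix of the marginal covariance).
#'
#' @param g A `geno_matrix`.
#' @param design An [assign_phenotypes()] tibble.
#' @param K Kinship matrix over `design`'s samples (default [kinship()] of
#'   `g` restricted to them).
#' @param covariates Design columns used as fixed covariates.
#' @param per_marker If `TRUE`, re-profile the variance ratio for every
#'   marker (slower; default reuses the null-model ratio).
#' @return An `assoc_result` tibble with attributes `variance_ratio` and
#'   `model = "mixed"`.
#' @export
lmm_assoc <- function(g, design, K = NULL, covariates = NULL,
                      per_marker = FALSE) {
  covariates <- covariates %||% character()
  idx <- match(design$sample_id, g$samples$sample_id)
  if (anyNA(idx)) abort("design contains samples absent from the genotype matrix")
  X <- g$calls[idx, , drop = FALSE]
  storage.mode(X) <- "double"
  y <- design$phenotype
  W <- build_design_matrix(design, covariates)
  if (is.null(K)) K <- kinship(g)
  if (!is.null(rownames(K))) {
    K <- K[design$sample_id, design$sample_id]
  }
  n <- length(y)
  if (nrow(K) != n) abort("K dimension does not match the design")
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  scale_k <- max(abs(eg$values), 1e-12)
  if (min(eg$values) < -1e-6 * scale_k) abort("K is not positive semidefinite")
  vals <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- as.vector(crossprod(U, y))
  Ws <- crossprod(U, W)

  opt <- optimize(reml_neg_loglik, interval = c(-5, 5),
                  ys = ys, Ws = Ws, vals = vals, tol = 1e-6)
  lam <- 10^opt$minimum

  m <- ncol(X)
  beta <- se <- pv <- rep(NA_real_, m)
  n_used <- rep(n, m)
  has_na <- colSums(is.na(X)) > 0
  p <- ncol(W)

  gls_block <- function(ysw, Wsw, Xsw) {
    qw <- qr(Wsw)
    ry <- qr.resid(qw, ysw)
    RX <- qr.resid(qw, Xsw)
    ss_y <- sum(ry^2)
    xx <- colSums(RX^2)
    xy <- as.vector(crossprod(RX, ry))
    df <- length(ysw) - ncol(Wsw) - 1
    b <- ifelse(xx > 1e-12, xy / xx, NA_real_)
    rss <- pmax(ss_y - b^2 * xx, 0)
    s <- sqrt(rss / df / xx)
    tt <- b / s
    pp <- 2 * pt(-abs(tt), df)
    pp[ss_y < 1e-24] <- 1
    pp[!is.finite(pp)] <- NA_real_
    list(beta = b, se = s, p = pp)
  }

  if (any(!has_na)) {
    jj <- which(!has_na)
    if (per_marker) {
      Xs <- crossprod(U, X[, jj, drop = FALSE])
      for (kk in seq_along(jj)) {
        Waug <- cbind(Ws, Xs[, kk])
        if (qr(Waug)$rank < ncol(Waug)) next
        o <- optimize(reml_neg_loglik, interval = c(-5, 5),
                      ys = ys, Ws = Waug, vals = vals, tol = 1e-6)
        w <- 1 / sqrt(10^o$minimum * vals + 1)
        r <- gls_block(ys * w, Ws * w, Xs[, kk, drop = FALSE] * w)
        beta[jj[kk]] <- r$beta; se[jj[kk]] <- r$se; pv[jj[kk]] <- r$p
      }
    } else {
      w <- 1 / sqrt(lam * vals + 1)
      Xs <- crossprod(U, X[, jj, drop = FALSE]) * w
      r <- gls_block(ys * w, Ws * w, Xs)
      beta[jj] <- r$beta; se[jj] <- r$se; pv[jj] <- r$p
    }
  }
  if (any(has_na)) {
    V_full <- lam * K + diag(n)
    for (j in which(has_na)) {
      ok <- !is.na(X[, j])
      nj <- sum(ok)
      n_used[j] <- nj
      if (nj < p + 2) next
      L <- chol(V_full[ok, ok])
      wy <- backsolve(L, y[ok], transpose = TRUE)
      wW <- backsolve(L, W[ok, , drop = FALSE], transpose = TRUE)
      wX <- backsolve(L, X[ok, j, drop = FALSE], transpose = TRUE)
      r <- gls_block(wy, wW, wX)
      beta[j] <- r$beta; se[j] <- r$se; pv[j] <- r$p
    }
  }
  new_assoc_result(
    dplyr::bind_cols(g$markers[, c("marker_id", "chrom", "pos")],
                     tibble(beta = beta, se = se, p_value = pv,
                            neg_log10_p = -log10(pv), n_used = n_used)),
    model = "mixed", covariates = covariates,
    extra = list(variance_ratio = lam))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of markers tested.
#' @return The threshold on the -log10(p) scale: `-log10(alpha / m)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  -log10(alpha / m)
}

#' Genomic inflation factor
#'
#' Median chi-square statistic of a scan divided by its null expectation.
#'
#' @param res An `assoc_result`.
#' @return Scalar lambda_GC.
#' @export
genomic_inflation <- function(res) {
  p <- res$p_value[!is.na(res$p_value)]
  median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Breed stratification for sensitivity scans
#'
#' Three stratification modes used when dissecting size confounding:
#' `size_below_median` keeps breed-sex rows whose log size covariate is
#' strictly below the table's 50th percentile; `drop_listed_breeds` removes a
#' named breed list; `pc_cutoff` removes "extreme brachycephalic" breeds,
#' defined as breeds all of whose breed-sex PC1 averages exceed the cutoff
#' (default 0.15).
#'
#' @param pheno A [breed_sex_average()] table.
#' @param mode One of `"size_below_median"`, `"drop_listed_breeds"`,
#'   `"pc_cutoff"`.
#' @param breeds Breed names for `drop_listed_breeds`.
#' @param pc PC column for `pc_cutoff` (default `"PC1"`).
#' @param cutoff PC cutoff (default 0.15).
#' @return Filtered phenotype tibble; attribute `"removed_breeds"` lists the
#'   breeds taken out.
#' @export
stratify <- function(pheno, mode = c("size_below_median", "drop_listed_breeds",
                                     "pc_cutoff"),
                     breeds = NULL, pc = "PC1", cutoff = 0.15) {
  mode <- match.arg(mode)
  out <- switch(mode,
    size_below_median = {
      size_col <- intersect(c("log_neuro_centroid", "log_centroid"),
                            names(pheno))[1]
      med <- median(pheno[[size_col]])
      pheno[pheno[[size_col]] < med, ]
    },
    drop_listed_breeds = {
      unknown <- setdiff(breeds, pheno$breed)
      if (length(unknown) > 0) {
        warn(paste0("unknown breed names: ", paste(unknown, collapse = ", ")))
      }
      pheno[!pheno$breed %in% breeds, ]
    },
    pc_cutoff = {
      flagged <- pheno %>%
        group_by(.data$breed) %>%
        summarise(extreme = all(.data[[pc]] > cutoff), .groups = "drop") %>%
        filter(.data$extreme) %>% pull("breed")
      res <- pheno[!pheno$breed %in% flagged, ]
      attr(res, "removed_breeds") <- flagged
      res
    })
  if (is.null(attr(out, "removed_breeds"))) {
    attr(out, "removed_breeds") <- setdiff(pheno$breed, out$breed)
  }
  out
}

#' @describeIn linear_assoc Manhattan plot of a scan
#' @param object An `assoc_result`.
#' @param threshold Optional -log10(p) significance line, e.g. from
#'   [bonferroni_threshold()].
#' @param ... Unused.
#' @export
autoplot.assoc_result <- function(object, threshold = NULL, ...) {
  d <- object %>%
    mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  p <- ggplot(d, aes(x = .data$pos, y = .data$neg_log10_p,
                     colour = as.integer(.data$chrom) %% 2 == 0)) +
    geom_point(size = 0.6, show.legend = FALSE) +
    facet_grid(cols = dplyr::vars(.data$chrom), scales = "free_x",
               space = "free_x", switch = "x") +
    scale_colour_manual(values = c("grey30", "steelblue")) +
    labs(x = "Chromosome", y = expression(-log[10](italic(p)))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  if (!is.null(threshold)) p <- p + geom_hline(yintercept = threshold,
                                               linetype = 2, colour = "red")
  p
}
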