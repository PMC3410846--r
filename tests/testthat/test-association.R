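test_that("single-marker OLS matches the normal-equations oracle on a hand-size problem", {
  y <- c(1.2, 0.4, -0.3, 2.2, 1.1, 0.6)
  x <- c(0, 1, 0, 2, 1, 1)
  covar <- c(4.1, 4.4, 3.9, 4.8, 4.3, 4.2)
  g <- toy_geno(matrix(as.integer(x), 6, 1))
  design <- tibble::tibble(sample_id = paste0("s", 1:6), phenotype = y,
                           size = covar)
  res <- linear_assoc(g, design, covariates = "size")
  # direct normal-equations solve
  X <- cbind(1, covar, x)
  bh <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% bh
  s2 <- sum(r^2) / (6 - 3)
  se <- sqrt(s2 * solve(crossprod(X))[3, 3])
  tval <- bh[3] / se
  p <- 2 * pt(-abs(tval), 6 - 3)
  expect_equal(res$beta, bh[3], tolerance = 1e-10)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$p_value, p, tolerance = 1e-10)
  expect_equal(res$neg_log10_p, -log10(p), tolerance = 1e-10)
})

test_that("degenerate scans are handled: constant phenotype, constant marker, collinearity", {
  g <- toy_geno(cbind(c(0L, 1L, 2L, 1L, 0L, 2L), rep(1L, 6)))
  design <- tibble::tibble(sample_id = paste0("s", 1:6),
                           phenotype = rep(2.5, 6))
  res <- linear_assoc(g, design)
  expect_equal(res$p_value[1], 1)
  design2 <- tibble::tibble(sample_id = paste0("s", 1:6),
                            phenotype = rnorm(6), a = 1:6, b = 2 * (1:6))
  expect_error(linear_assoc(g, design2, covariates = c("a", "b")),
               "collinear")
  res3 <- linear_assoc(g, dplyr::mutate(design2, phenotype = rnorm(6)))
  expect_true(is.na(res3$p_value[2]))   # constant dosage has no slope
})

test_that("missing calls are dropped marker-wise in the linear scan", {
  set.seed(31)
  calls <- matrix(sample(0:2, 40, TRUE), 20, 2)
  calls[c(3, 9), 2] <- NA
  g <- toy_geno(calls)
  design <- tibble::tibble(sample_id = paste0("s", 1:20), phenotype = rnorm(20))
  res <- linear_assoc(g, design)
  keep <- !is.na(calls[, 2])
  sub <- linear_assoc(toy_geno(matrix(calls[keep, 2], ncol = 1)),
                      tibble::tibble(sample_id = paste0("s", seq_len(sum(keep))),
                                     phenotype = design$phenotype[keep]))
  expect_equal(res$p_value[2], sub$p_value[1], tolerance = 1e-12)
  expect_equal(res$n_used, c(20L, 18L))
})

test_that("the relationship matrix is a centred cross-product with the expected structure", {
  set.seed(16)
  calls <- matrix(sample(0:2, 200, TRUE), 10, 20)
  calls[1, ] <- calls[2, ]                 # duplicate an individual
  g <- toy_geno(calls)
  K <- kinship(g)
  expect_equal(K, t(K))
  expect_equal(K[1, ], K[2, ], ignore_attr = TRUE)
  expect_equal(K[1, 2], K[2, 2], tolerance = 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  # direct construction
  Z <- scale(calls, center = TRUE, scale = FALSE)
  expect_equal(K, tcrossprod(Z) / 20, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an unstructured panel has near-zero mean relatedness off the diagonal", {
  set.seed(17)
  p <- runif(400, 0.2, 0.8)
  calls <- matrix(rbinom(50 * 400, 2, rep(p, each = 50)), 50, 400)
  K <- kinship(toy_geno(calls, pos = 100L * 1:400))
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)) / mean(diag(K)), 0.05)
})

test_that("the mixed model collapses to OLS when K is (a multiple of) the identity", {
  set.seed(18)
  n <- 40
  calls <- matrix(sample(0:2, n * 25, TRUE), n, 25)
  g <- toy_geno(calls)
  design <- tibble::tibble(sample_id = paste0("s", 1:n), phenotype = rnorm(n),
                           size = rnorm(n))
  lin <- linear_assoc(g, design, covariates = "size")
  for (c_mult in c(1, 3)) {
    mix <- lmm_assoc(g, design, K = c_mult * diag(n), covariates = "size")
    expect_equal(mix$p_value, lin$p_value, tolerance = 1e-6)
    expect_equal(mix$beta, lin$beta, tolerance = 1e-6)
  }
  expect_error(lmm_assoc(g, design, K = diag(n) - 0.5), "positive semidefinite")
})

test_that("mixed-model p-values are invariant to marker order and phenotype shifts", {
  cfg <- sim_config(seed = 19, n_breeds = 12, dogs_per_breed = 4,
                    n_chrom = 2, markers_per_chrom = 40, n_qtls = 1,
                    n_selected = 3, n_dolicho = 3)
  sim <- simulate_genotypes_and_trait(cfg)
  g <- suppressWarnings(snp_qc(sim$g))
  design <- assign_phenotypes(g, sim$pheno)
  K <- kinship(g)
  r1 <- lmm_assoc(g, design, K = K)
  # reorder whole chromosome blocks (positions stay sorted within chromosome)
  perm <- order(match(g$markers$chrom, rev(unique(g$markers$chrom))))
  g2 <- geno_matrix(g$calls[, perm], g$markers[perm, ], g$samples)
  r2 <- lmm_assoc(g2, design, K = K)
  expect_equal(r2$p_value[match(r1$marker_id, r2$marker_id)], r1$p_value,
               tolerance = 1e-9)
  design3 <- dplyr::mutate(design, phenotype = phenotype + 100)
  r3 <- lmm_assoc(g, design3, K = K)
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-6)
})

test_that("a single planted QTL is the top marker genome-wide across seeded replicates", {
  hits <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = 300 + r, n_qtls = 1, n_chrom = 5,
                      markers_per_chrom = 80)
    sim <- simulate_genotypes_and_trait(cfg)
    g <- suppressWarnings(snp_qc(sim$g))
    design <- assign_phenotypes(g, sim$pheno)
    res <- lmm_assoc(g, design)
    top <- res$marker_id[which.min(res$p_value)]
    if (top == sim$truth$qtl$marker_id[1]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("the Bonferroni threshold reproduces published marker-count values", {
  # the published 5.86 truncates -log10(0.05/36685) = 5.8655 (and the marker
  # count itself is quoted approximately); agree to the printed precision
  expect_lt(abs(bonferroni_threshold(0.05, 36685) - 5.86), 0.01)
  expect_equal(floor(bonferroni_threshold(0.05, 36685) * 100) / 100, 5.86)
  expect_equal(round(bonferroni_threshold(0.05, 1), 2), 1.30)
  expect_equal(round(bonferroni_threshold(0.05, 61270), 2), 6.09)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("phenotype assignment pairs dogs with their breed-sex averages", {
  g <- toy_geno(matrix(0:1, 4, 2),
                breeds = c("Pug", "Pug", "Collie", "Saluki"))
  pheno <- tibble::tibble(breed = c("Pug", "Pug", "Collie"),
                          sex = c("M", "F", "F"),
                          PC1 = c(0.3, 0.25, -0.2),
                          log_neuro_centroid = c(4, 4.1, 5))
  design <- suppressMessages(assign_phenotypes(g, pheno))
  # dogs alternate M/F: s1 Pug M, s2 Pug F, s3 Collie M (no row), s4 Saluki F
  expect_equal(design$sample_id, c("s1", "s2"))
  expect_equal(design$phenotype, c(0.3, 0.25))
  # the opposite-sex fallback is off by default, on demand it fills in
  design_fb <- suppressMessages(assign_phenotypes(g, pheno,
                                                  sex_fallback = TRUE))
  expect_equal(design_fb$sample_id, c("s1", "s2", "s3"))
  expect_equal(design_fb$phenotype[3], -0.2)
  # two dogs of the same breed-sex carry identical values
  g2 <- toy_geno(matrix(0L, 2, 2), breeds = c("Pug", "Pug"))
  g2$samples$sex <- c("M", "M")
  d2 <- assign_phenotypes(g2, pheno)
  expect_equal(d2$phenotype[1], d2$phenotype[2])
})

test_that("stratification modes subset the phenotype table as specified", {
  pheno <- tibble::tibble(
    breed = rep(c("Pug", "Boxer", "Collie", "Saluki"), each = 2),
    sex = rep(c("F", "M"), 4),
    PC1 = c(0.3, 0.35, 0.18, 0.12, -0.2, -0.25, -0.3, -0.28),
    log_neuro_centroid = c(4.0, 4.1, 4.6, 4.7, 5.0, 5.1, 5.2, 5.3))
  small <- stratify(pheno, "size_below_median")
  expect_setequal(unique(small$breed), c("Pug", "Boxer"))
  # strictly-below on a constant table keeps nothing
  flat <- dplyr::mutate(pheno, log_neuro_centroid = 5)
  expect_equal(nrow(stratify(flat, "size_below_median")), 0L)
  # extreme-brachycephaly cutoff: both sexes must exceed 0.15
  expect_equal(eval(formals(stratify)$cutoff), 0.15)
  nb <- stratify(pheno, "pc_cutoff")
  expect_equal(attr(nb, "removed_breeds"), "Pug")   # Boxer M is 0.12
  expect_false("Pug" %in% nb$breed)
  expect_warning(stratify(pheno, "drop_listed_breeds",
                          breeds = c("Pug", "Wolfhound")), "Wolfhound")
})
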