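#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the seeded generator that emulates the study
#' design: a panel of breeds with Balding-Nichols drift, a quantitative
#' skull-shape trait controlled by a handful of QTLs plus allometry, a
#' "selected" (brachycephalic-like) breed group whose QTL alleles are near
#' fixation, an optional selective sweep, and a small resequencing panel
#' over a critical interval with conservation and exon annotations.
#'
#' Identical config + seed always reproduce identical outputs; each
#' generator stage derives its own seed from `seed` plus a fixed offset, so
#' stages are individually reproducible.
#'
#' @param seed Integer master seed.
#' @param n_breeds,dogs_per_breed Genotyped panel dimensions.
#' @param n_selected,n_dolicho Breeds at the brachy/dolicho polar extremes;
#'   the selected group carries near-fixed QTL alleles.
#' @param n_chrom,markers_per_chrom Marker map dimensions.
#' @param f_drift Balding-Nichols drift for neutral markers.
#' @param hierarchy,f_clade Optional two-level drift (breed clades).
#' @param n_qtls,qtl_effect Number of QTLs and their effect sizes (recycled).
#' @param qtl_anc_freq,qtl_sel_freq,f_selected QTL allele frequency model:
#'   ancestral frequency, mean frequency in selected breeds, and the drift
#'   concentration around the selected mean.
#' @param breed_effect_sd,trait_noise_sd Non-QTL trait variance components.
#' @param specimens_per_breed_sex Skulls digitized per breed-sex cell.
#' @param deformation_scale mm of landmark displacement per unit trait along
#'   the deformation axis.
#' @param allometry_coef mm of displacement along the allometric axis per
#'   unit log centroid size deviation.
#' @param size_trait_coef Log-size shift per unit trait (brachy breeds run
#'   small, confounding size with shape).
#' @param sex_size_effect Additive log-size shift for males.
#' @param size_jitter_sd Within breed-sex log-size standard deviation among
#'   specimens (individual adult size variation).
#' @param landmark_noise_sd Isotropic digitizing noise, mm.
#' @param sweep_half_width,sweep_freq Sweep window half-width (markers) and
#'   target haplotype frequency in selected breeds.
#' @param panel_size,panel_variants Resequencing panel: genomes and variant
#'   count over the critical interval.
#' @param interval_chrom,interval_start,interval_end Critical interval for
#'   the resequencing panel (1-based inclusive).
#' @param gq_low_frac Exact fraction of panel genotype calls given a quality
#'   below the masking threshold.
#' @param cons_high_frac Fraction of variant positions with conservation
#'   score at or above 0.7.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_breeds = 60L, dogs_per_breed = 8L,
                       n_selected = 10L, n_dolicho = 9L,
                       n_chrom = 10L, markers_per_chrom = 150L,
                       f_drift = 0.2, hierarchy = FALSE, f_clade = 0.05,
                       n_qtls = 5L, qtl_effect = 1.0,
                       qtl_anc_freq = 0.2, qtl_sel_freq = 0.9,
                       f_selected = 0.1,
                       breed_effect_sd = 0.3, trait_noise_sd = 0.05,
                       specimens_per_breed_sex = 2L,
                       deformation_scale = 0.5, allometry_coef = 0.3,
                       size_trait_coef = -0.02, sex_size_effect = 0.05,
                       size_jitter_sd = 0.06, landmark_noise_sd = 0.2,
                       sweep_half_width = 5L, sweep_freq = 0.95,
                       panel_size = 11L, panel_variants = 452L,
                       interval_chrom = "32",
                       interval_start = 8152258L, interval_end = 8237937L,
                       gq_low_frac = 0.08, cons_high_frac = 0.15) {
  cfg <- as.list(environment())
  cfg$qtl_effect <- rep_len(qtl_effect, n_qtls)
  stopifnot(f_drift > 0, f_drift < 1, f_selected > 0, f_selected < 1,
            sweep_freq >= 0, sweep_freq <= 1, n_selected + n_dolicho <= n_breeds)
  class(cfg) <- "sim_config"
  cfg
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# ---- landmark template -----------------------------------------------------

#' Deterministic 51-landmark skull template and axes
#'
#' A stylized bilaterally symmetric configuration (mm): 17 midline landmarks
#' (ids 1-17) along the dorsal profile, 17 left/right pairs (ids 18-34 and
#' 35-51). Also returns the unit-norm deformation axis (rostrum shortening +
#' palate widening, the brachycephaly direction), an allometric axis
#' orthogonal to it, the left/right/midline pairing, and the neurocranium
#' landmark subset used for the size covariate.
#'
#' @return List: `coords` (51 x 3 matrix, ids as rownames), `def_axis`,
#'   `allo_axis` (length-153 unit vectors over x,y,z-flattened landmarks),
#'   `pairing`, `neuro_subset`.
#' @export
skull_template <- function() {
  t_mid <- seq(0, 1, length.out = 17)
  mid <- cbind(x = 100 * t_mid, y = 0, z = 28 * sin(pi * t_mid) + 4 * t_mid)
  t_lat <- seq(0.05, 0.95, length.out = 17)
  left <- cbind(x = 100 * t_lat, y = 18 + 7 * sin(pi * t_lat), z = 12 * sin(pi * t_lat))
  right <- left; right[, "y"] <- -left[, "y"]
  coords <- rbind(mid, left, right)
  rownames(coords) <- 1:51
  # deformation axis: landmarks in the rostral half retract along x and the
  # lateral points flare in |y| (shorter, wider skull)
  def <- matrix(0, 51, 3)
  rostral <- coords[, "x"] > 50
  def[rostral, 1] <- -(coords[rostral, "x"] - 50) / 50
  def[18:51, 2] <- sign(coords[18:51, "y"]) * 0.3
  def_axis <- as.vector(t(def)); def_axis <- def_axis / sqrt(sum(def_axis^2))
  # allometric axis: dorsoventral deepening, orthogonalized to the
  # deformation axis
  allo <- matrix(0, 51, 3)
  allo[, 3] <- coords[, "z"] / max(coords[, "z"])
  allo_axis <- as.vector(t(allo))
  allo_axis <- allo_axis - sum(allo_axis * def_axis) * def_axis
  allo_axis <- allo_axis / sqrt(sum(allo_axis^2))
  list(coords = coords, def_axis = def_axis, allo_axis = allo_axis,
       pairing = list(left = 18:34, right = 35:51, midline = 1:17),
       neuro_subset = c(1:8, 18:21, 35:38))
}

# ---- allele frequencies ----------------------------------------------------

#' Simulate per-breed allele frequencies under Balding-Nichols drift
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each breed's frequency
#' at each marker is drawn `Beta(p(1-F)/F, (1-p)(1-F)/F)` independently per
#' breed (optionally via an intermediate clade level). QTL markers instead
#' follow the trait-selected model: breeds in the selected group draw
#' frequencies concentrated around `qtl_sel_freq` (near fixation, emulating
#' sustained artificial selection on the trait), all other breeds drift
#' around the low ancestral `qtl_anc_freq`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_freqs`: `freq` (breeds x markers), `p_anc`,
#'   `breeds` (tibble with `breed, role`), `markers`, `qtl` (tibble with
#'   `marker_id, chrom, pos, index, effect`).
#' @export
simulate_breed_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    m <- config$n_chrom * config$markers_per_chrom
    breeds <- sprintf("Breed%02d", seq_len(config$n_breeds))
    role <- rep("rest", config$n_breeds)
    role[seq_len(config$n_selected)] <- "selected"
    role[config$n_selected + seq_len(config$n_dolicho)] <- "dolicho"
    markers <- tibble(
      marker_id = paste0("c", rep(seq_len(config$n_chrom),
                                  each = config$markers_per_chrom),
                         "_m", rep(seq_len(config$markers_per_chrom),
                                   config$n_chrom)),
      chrom = as.character(rep(seq_len(config$n_chrom),
                               each = config$markers_per_chrom)),
      pos = rep(100000L * seq_len(config$markers_per_chrom), config$n_chrom))
    p_anc <- runif(m, 0.05, 0.95)

    bn_draw <- function(p, F) {
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      rbeta(length(p), a, b)
    }
    freq <- matrix(0, config$n_breeds, m)
    if (config$hierarchy) {
      clade_of <- rep(1:2, length.out = config$n_breeds)
      clade_freq <- rbind(bn_draw(p_anc, config$f_clade),
                          bn_draw(p_anc, config$f_clade))
      for (b in seq_len(config$n_breeds)) {
        freq[b, ] <- bn_draw(clade_freq[clade_of[b], ], config$f_drift)
      }
    } else {
      for (b in seq_len(config$n_breeds)) {
        freq[b, ] <- bn_draw(p_anc, config$f_drift)
      }
    }
    # QTLs: one per chromosome (middle of the map), trait-selected frequencies
    qtl_idx <- (seq_len(config$n_qtls) - 1L) * as.integer(config$markers_per_chrom) +
      as.integer(config$markers_per_chrom) %/% 2L
    for (qi in seq_along(qtl_idx)) {
      j <- qtl_idx[qi]
      p_anc[j] <- config$qtl_anc_freq
      sel <- role == "selected"
      freq[sel, j] <- bn_draw(rep(config$qtl_sel_freq, sum(sel)),
                              config$f_selected)
      freq[!sel, j] <- bn_draw(rep(config$qtl_anc_freq, sum(!sel)),
                               config$f_drift)
    }
    freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
    structure(list(freq = freq, p_anc = p_anc,
                   breeds = tibble(breed = breeds, role = role),
                   markers = markers,
                   qtl = dplyr::bind_cols(markers[qtl_idx, ],
                                          tibble(index = qtl_idx,
                                                 effect = config$qtl_effect))),
              class = "sim_freqs")
  })
}

# ---- genotypes, trait, landmarks -------------------------------------------

#' Simulate genotypes, breed-sex trait values, and specimen landmarks
#'
#' Dogs are drawn binomially from their breed's allele frequencies. The
#' breed trait is `sum(effect_q * breed mean dosage at QTL q)` plus a breed
#' effect and noise; both sexes of a breed share the trait value (the mapped
#' phenotype is a breed-sex average). Specimen landmark configurations are
#' the template plus `trait * deformation axis`, an allometric term
#' proportional to the specimen's log size deviation, and isotropic noise,
#' all scaled to the specimen's centroid size. Sexes are assigned
#' alternately within breed.
#'
#' @param config A [sim_config()].
#' @param freqs Optional pre-computed [simulate_breed_frequencies()] result.
#' @return List of class `sim_data`: `g` (a `geno_matrix`), `pheno` (a
#'   breed-sex phenotype table with `PC1 = trait`), `landmarks` (long
#'   tibble), `freqs`, `truth` (QTL table, per-breed trait, template axes),
#'   `config`.
#' @export
simulate_genotypes_and_trait <- function(config, freqs = NULL) {
  freqs <- freqs %||% simulate_breed_frequencies(config)
  tpl <- skull_template()
  with_seed(config$seed + 2L, {
    nb <- config$n_breeds; dpb <- config$dogs_per_breed
    m <- ncol(freqs$freq)
    n <- nb * dpb
    calls <- matrix(0L, n, m)
    for (b in seq_len(nb)) {
      rows <- (b - 1L) * dpb + seq_len(dpb)
      calls[rows, ] <- matrix(
        rbinom(dpb * m, 2L, rep(freqs$freq[b, ], each = dpb)), dpb, m)
    }
    samples <- tibble(
      sample_id = sprintf("dog%04d", seq_len(n)),
      breed = rep(freqs$breeds$breed, each = dpb),
      sex = rep(c("M", "F"), length.out = n))
    g <- geno_matrix(calls, freqs$markers, samples)

    qtl_dose_breed <- vapply(seq_len(nb), function(b) {
      rows <- (b - 1L) * dpb + seq_len(dpb)
      colMeans(calls[rows, freqs$qtl$index, drop = FALSE])
    }, numeric(config$n_qtls))
    if (config$n_qtls == 1L) qtl_dose_breed <- matrix(qtl_dose_breed, nrow = 1)
    genetic_value <- as.vector(config$qtl_effect %*% qtl_dose_breed)
    trait <- genetic_value + rnorm(nb, 0, config$breed_effect_sd) +
      rnorm(nb, 0, config$trait_noise_sd)

    base_log_size <- log(120) + rnorm(nb, 0, 0.08) +
      config$size_trait_coef * trait
    pheno <- tidyr::expand_grid(breed = freqs$breeds$breed, sex = c("F", "M")) %>%
      mutate(PC1 = trait[match(.data$breed, freqs$breeds$breed)],
             log_size_target = base_log_size[match(.data$breed, freqs$breeds$breed)] +
               ifelse(.data$sex == "M", config$sex_size_effect, 0))

    tpl_cs <- sqrt(sum(sweep(tpl$coords, 2, colMeans(tpl$coords))^2))
    lm_rows <- list()
    spn <- 0L
    neuro <- tpl$neuro_subset
    log_neuro <- numeric(nrow(pheno))
    for (r in seq_len(nrow(pheno))) {
      for (s in seq_len(config$specimens_per_breed_sex)) {
        spn <- spn + 1L
        dev <- pheno$log_size_target[r] - log(120) +
          rnorm(1, 0, config$size_jitter_sd)
        shape <- as.vector(t(tpl$coords)) +
          config$deformation_scale * pheno$PC1[r] * tpl$def_axis +
          config$allometry_coef * dev * tpl$allo_axis +
          rnorm(153, 0, config$landmark_noise_sd)
        M <- unname(matrix(shape, ncol = 3, byrow = TRUE) * exp(dev))
        lm_rows[[spn]] <- tibble(
          specimen_id = sprintf("skull%04d", spn),
          breed = pheno$breed[r], sex = pheno$sex[r], view = "merged",
          landmark_id = 1:51, x = M[, 1], y = M[, 2], z = M[, 3])
      }
    }
    landmarks <- bind_rows(lm_rows)
    ncs <- centroid_size(landmarks, subset = neuro) %>%
      left_join(distinct(landmarks, .data$specimen_id, .data$breed, .data$sex),
                by = "specimen_id")
    pheno_out <- ncs %>%
      group_by(.data$breed, .data$sex) %>%
      summarise(log_neuro_centroid = mean(log(.data$centroid_size)),
                n_specimens = dplyr::n(), .groups = "drop") %>%
      left_join(select(pheno, "breed", "sex", "PC1"), by = c("breed", "sex")) %>%
      select("breed", "sex", "PC1", "log_neuro_centroid", "n_specimens")

    structure(list(g = g, pheno = pheno_out, landmarks = landmarks,
                   freqs = freqs,
                   truth = list(qtl = freqs$qtl,
                                trait = tibble(breed = freqs$breeds$breed,
                                               role = freqs$breeds$role,
                                               trait = trait,
                                               genetic_value = genetic_value),
                                template = tpl),
                   config = config),
              class = "sim_data")
  })
}

#' Plant a selective sweep in the selected breeds
#'
#' Within a window around the sweep locus (default: the first QTL), each
#' chromosome of each selected-breed dog is replaced by the swept haplotype
#' (the minor/derived allele at every window marker) with probability
#' `sweep_freq`, otherwise re-drawn from the breed's pre-sweep frequency.
#' Non-selected breeds' genotypes are untouched.
#'
#' @param config A [sim_config()].
#' @param sim A [simulate_genotypes_and_trait()] result.
#' @param locus_index Marker index of the sweep locus (default QTL 1).
#' @return `sim` with modified genotypes and `truth$sweep` describing the
#'   planted window.
#' @export
simulate_sweep <- function(config, sim, locus_index = NULL) {
  locus_index <- locus_index %||% sim$freqs$qtl$index[1]
  with_seed(config$seed + 3L, {
    chrom <- sim$freqs$markers$chrom[locus_index]
    on_chrom <- which(sim$freqs$markers$chrom == chrom)
    win <- intersect(seq(locus_index - config$sweep_half_width,
                         locus_index + config$sweep_half_width), on_chrom)
    sel_breeds <- sim$freqs$breeds$breed[sim$freqs$breeds$role == "selected"]
    rows <- which(sim$g$samples$breed %in% sel_breeds)
    for (i in rows) {
      b <- match(sim$g$samples$breed[i], sim$freqs$breeds$breed)
      for (copy in 1:2) {
        swept <- runif(1) < config$sweep_freq
        alleles <- if (swept) rep(1L, length(win))
        else rbinom(length(win), 1L, sim$freqs$freq[b, win])
        if (copy == 1) hap1 <- alleles else hap2 <- alleles
      }
      sim$g$calls[i, win] <- hap1 + hap2
    }
    sim$truth$sweep <- list(locus_index = locus_index, window = win,
                            chrom = chrom,
                            pos = sim$freqs$markers$pos[locus_index],
                            selected_breeds = sel_breeds)
    sim
  })
}

# ---- resequencing panel ----------------------------------------------------

#' Simulate the resequencing panel over the critical interval
#'
#' Emits a configured number of variants across the critical interval for a
#' small genome panel: per-sample genotypes and genotype qualities (an exact
#' fraction of calls fall below the masking threshold), a conservation track
#' with a configured fraction of positions at or above 0.7, a two-gene model
#' (one gene fully inside the interval), and one planted causal missense
#' variant — a C-to-A change in the third position of a TTC (Phe) codon at
#' high conservation, carried as homozygous-derived only by the
#' brachycephalic panel members and the designated outlier.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_panel`: `variants` (a `variant_table` with
#'   conservation filled), `models` (exon tibble with `chrom`), `cds` (named
#'   list of CDS strings), `conservation` (track tibble), `phenotype` (named
#'   per-genome vector), `panel` (sample tibble), `interval`
#'   (`genomic_interval`), `truth` (causal variant description).
#' @export
simulate_resequencing_panel <- function(config) {
  with_seed(config$seed + 4L, {
    ist <- config$interval_start; ien <- config$interval_end
    chrom <- config$interval_chrom
    # gene A: two exons fully inside the interval; CDS = 1500 nt (500 codons);
    # the causal site is the third base of codon 452, i.e. CDS index 1356,
    # which falls 456 bases into exon 2
    exA1 <- c(8190000L, 8190899L)              # 900 nt
    exA2 <- c(8195643L, 8196242L)              # 600 nt
    causal_pos <- exA2[1] + 455L               # CDS index 1356
    # gene B: starts upstream of the interval, minus strand
    models <- tibble(
      gene_id = c("geneA", "geneA", "geneB", "geneB", "geneB"),
      chrom = chrom,
      strand = c("+", "+", "-", "-", "-"),
      start = c(exA1[1], exA2[1], 8148200L, 8151900L, 8153800L),
      end = c(exA1[2], exA2[2], 8148900L, 8152500L, 8154199L))
    bases <- c("A", "C", "G", "T")
    cdsA <- paste(sample(bases, 1500, replace = TRUE), collapse = "")
    substr(cdsA, 1, 3) <- "ATG"
    substr(cdsA, 1354, 1356) <- "TTC"          # codon 452 = Phe
    substr(cdsA, 1498, 1500) <- "TAA"

    brachy <- c("Pekingese", "Bulldog", "BostonTerrier", "Pug")
    others <- c("ScottishTerrier", "Collie", "Greyhound", "Borzoi",
                "Labrador", "Beagle", "Dachshund")
    panel <- tibble(
      sample_id = c(brachy, others),
      breed = c(brachy, others),
      role = c(rep("brachy", length(brachy)), "outlier",
               rep("other", length(others) - 1)))
    panel <- panel[seq_len(config$panel_size), ]
    phenotype <- setNames(
      ifelse(panel$role == "brachy", runif(nrow(panel), 0.18, 0.30),
             ifelse(panel$role == "outlier", runif(nrow(panel), -0.30, -0.22),
                    runif(nrow(panel), -0.20, 0.10))),
      panel$sample_id)

    pool <- setdiff(seq(ist, ien), causal_pos)
    pos <- sort(c(sample(pool, config$panel_variants - 1L), causal_pos))
    nv <- length(pos)
    ns <- nrow(panel)
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    ci <- which(pos == causal_pos)
    ref[ci] <- "C"; alt[ci] <- "A"            # TTC -> TTA, Phe -> Leu

    f <- runif(nv, 0.05, 0.6)
    gt <- matrix(rbinom(nv * ns, 2L, rep(f, ns)), nv, ns)
    colnames(gt) <- panel$sample_id
    gt[ci, ] <- ifelse(panel$role %in% c("brachy", "outlier"), 2L, 0L)

    gq <- matrix(sample(20:60, nv * ns, replace = TRUE), nv, ns,
                 dimnames = list(NULL, panel$sample_id))
    n_low <- round(config$gq_low_frac * nv * ns)
    low_idx <- sample(setdiff(seq_len(nv * ns),
                              (ci - 1L) + nv * (seq_len(ns) - 1L) + 1L), n_low)
    gq[low_idx] <- sample(0:7, n_low, replace = TRUE)

    cons <- ifelse(runif(nv) < config$cons_high_frac,
                   runif(nv, 0.7, 1), runif(nv, 0, 0.699))
    cons[ci] <- 0.95

    variants <- variant_table(rep(chrom, nv), pos, ref, alt, gt, gq,
                              conservation = cons)
    track <- tibble(chrom = chrom, start = pos, end = pos, score = cons)
    structure(list(variants = variants, models = models,
                   cds = list(geneA = cdsA),
                   conservation = track, phenotype = phenotype, panel = panel,
                   interval = genomic_interval(chrom, ist, ien,
                                               n_markers = nv,
                                               provenance = "haplotype_sharing"),
                   truth = list(causal_pos = causal_pos, causal_ref = "C",
                                causal_alt = "A", gene = "geneA",
                                aa_pos = 452L, outlier = "ScottishTerrier")),
              class = "sim_panel")
  })
}

#' Split merged landmark configurations into displaced dorsal/ventral views
#'
#' Test utility for the view-merging step: splits each merged configuration
#' into a dorsal view (landmark ids 1-29) and a ventral view (ids 28-51 plus
#' the shared ids 1 and 2), then applies a random rigid motion to the
#' ventral view so the two views live in different digitizer frames.
#'
#' @param landmarks Merged long landmark tibble (ids 1-51).
#' @param seed Seed for the random rigid motions.
#' @return Long tibble of dorsal and ventral views.
#' @export
split_views <- function(landmarks, seed = 1L) {
  with_seed(seed, {
    out <- list()
    for (sp in unique(landmarks$specimen_id)) {
      cfg <- landmarks[landmarks$specimen_id == sp, ]
      dor <- cfg %>% filter(.data$landmark_id <= 29) %>% mutate(view = "dorsal")
      ven <- cfg %>% filter(.data$landmark_id >= 28 | .data$landmark_id %in% c(1L, 2L)) %>%
        mutate(view = "ventral")
      ang <- runif(3, -pi, pi)
      Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                     0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
      Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
      R <- Rx %*% Rz
      tv <- runif(3, -30, 30)
      M <- as.matrix(ven[, c("x", "y", "z")]) %*% t(R)
      M <- sweep(M, 2, tv, "+")
      ven$x <- M[, 1]; ven$y <- M[, 2]; ven$z <- M[, 3]
      out[[length(out) + 1L]] <- bind_rows(dor, ven)
    }
    bind_rows(out)
  })
}

#' Write a simulated dataset to plain-file formats
#'
#' Emits the file set the pipeline stages consume: landmarks CSV, genotypes
#' as PED/MAP and VCF, the panel VCF, gene models GFF3, conservation
#' bedGraph, a phenotype TSV, a populations YAML, and a truth JSON.
#'
#' @param sim A `sim_data` object.
#' @param panel A `sim_panel` object (optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of paths written.
#' @export
write_sim_data <- function(sim, panel = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$landmarks <- file.path(dir, "landmarks.csv")
  write_landmarks(sim$landmarks, paths$landmarks)
  prefix <- file.path(dir, "genotypes")
  write_plink(sim$g, prefix)
  paths$ped <- paste0(prefix, ".ped")
  paths$map <- paste0(prefix, ".map")
  paths$vcf <- file.path(dir, "genotypes.vcf")
  write_geno_vcf(sim$g, paths$vcf)
  paths$pheno <- file.path(dir, "phenotypes.tsv")
  readr::write_tsv(sim$pheno, paths$pheno)
  paths$pops <- file.path(dir, "populations.yaml")
  roles <- split(sim$freqs$breeds$breed, sim$freqs$breeds$role)
  yaml::write_yaml(list(brachy = roles$selected, dolicho = roles$dolicho,
                        rest = roles$rest), paths$pops)
  truth <- list(seed = sim$config$seed,
                qtl = as.list(sim$truth$qtl$marker_id),
                qtl_pos = as.list(sim$truth$qtl$pos),
                qtl_chrom = as.list(sim$truth$qtl$chrom))
  if (!is.null(sim$truth$sweep)) {
    truth$sweep <- list(chrom = sim$truth$sweep$chrom,
                        pos = sim$truth$sweep$pos)
  }
  if (!is.null(panel)) {
    paths$panel_vcf <- file.path(dir, "panel.vcf")
    write_variant_vcf(panel$variants, paths$panel_vcf)
    paths$gff <- file.path(dir, "genes.gff3")
    write_gene_models(panel$models, paths$gff)
    paths$bedgraph <- file.path(dir, "conservation.bedGraph")
    write_conservation(panel$conservation, paths$bedgraph)
    paths$panel_pheno <- file.path(dir, "panel_phenotypes.tsv")
    readr::write_tsv(tibble(sample_id = names(panel$phenotype),
                            phenotype = unname(panel$phenotype)),
                     paths$panel_pheno)
    paths$cds <- file.path(dir, "geneA_cds.txt")
    writeLines(panel$cds$geneA, paths$cds)
    truth$causal_pos <- panel$truth$causal_pos
    truth$interval <- list(chrom = panel$interval$chrom,
                           start = panel$interval$start,
                           end = panel$interval$end)
  }
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
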