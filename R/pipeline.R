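#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates the stages with plain-file handoff inside `dir`, so each
#' stage is independently re-runnable and inspectable:
#'
#' * `simulate` — write the synthetic study (landmarks, genotypes, panel,
#'   annotation tracks) via [write_sim_data()].
#' * `morpho` — landmarks -> GPA -> allometric correction -> shape PCs ->
#'   breed-sex phenotype table (`morpho_scores.tsv`, `morpho_phenotypes.tsv`).
#' * `gwas` — QC'd genotypes + phenotype table -> association scan
#'   (`gwas_results.tsv`).
#' * `sweep` — heterozygosity-ratio and F_ST sliding windows with tail flags
#'   (`sweep_windows.tsv`).
#' * `interval` — EM phasing of the top sweep window and haplotype-sharing
#'   critical interval (`interval.bed`, `interval_report.tsv`).
#' * `filter` — panel VCF + annotations -> variant-of-interest table
#'   (`variants_filtered.tsv`, `filter_summary.json`).
#'
#' Stages already run (outputs present) are skipped unless
#' `overwrite = TRUE`; a stage whose upstream outputs are missing fails
#' naming that stage.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param dir Working directory for stage files.
#' @param stages Stages to execute, in order.
#' @param model `"mixed"` or `"linear"` association model.
#' @param covariates Covariate columns for the scan (e.g.
#'   `"log_neuro_centroid"`; default none).
#' @param n_perm Permutations for the allometric regression stage.
#' @param overwrite Re-run stages whose outputs already exist.
#' @return A run-manifest tibble (stage, output, path); also written to
#'   `manifest.json` with the config hash, seed, package version and
#'   timestamps.
#' @export
run_pipeline <- function(config = sim_config(), dir,
                         stages = c("simulate", "morpho", "gwas", "sweep",
                                    "interval", "filter"),
                         model = c("mixed", "linear"),
                         covariates = NULL, n_perm = 499L,
                         overwrite = FALSE) {
  model <- match.arg(model)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, output, path) {
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage,
                                                 output = output, path = path)
  }
  p <- function(...) file.path(dir, ...)
  need <- function(stage, ...) {
    paths <- c(...)
    miss <- paths[!file.exists(paths)]
    if (length(miss) > 0) {
      abort(paste0("stage '", stage, "' is missing upstream output(s): ",
                   paste(basename(miss), collapse = ", ")))
    }
  }
  done <- function(...) all(file.exists(c(...))) && !overwrite

  if ("simulate" %in% stages && !done(p("landmarks.csv"), p("truth.json"))) {
    sim <- simulate_genotypes_and_trait(config)
    sim <- simulate_sweep(config, sim)
    panel <- simulate_resequencing_panel(config)
    paths <- write_sim_data(sim, panel, dir)
    for (nm in names(paths)) note("simulate", nm, paths[[nm]])
  } else if ("simulate" %in% stages) {
    cs_inform("simulate: outputs present, skipping")
  }

  if ("morpho" %in% stages && !done(p("morpho_phenotypes.tsv"))) {
    need("morpho", p("landmarks.csv"))
    lmk <- read_landmarks(p("landmarks.csv"))
    tpl <- skull_template()
    fit <- gpa(lmk, neuro_subset = tpl$neuro_subset)
    allo <- allometric_regression(fit, n_perm = n_perm, seed = config$seed + 10L)
    space <- shape_pca(allo)
    readr::write_tsv(space$scores, p("morpho_scores.tsv"))
    readr::write_tsv(breed_sex_average(space), p("morpho_phenotypes.tsv"))
    note("morpho", "scores", p("morpho_scores.tsv"))
    note("morpho", "phenotypes", p("morpho_phenotypes.tsv"))
  } else if ("morpho" %in% stages) {
    cs_inform("morpho: outputs present, skipping")
  }

  if ("gwas" %in% stages && !done(p("gwas_results.tsv"))) {
    need("gwas", paste0(p("genotypes"), ".ped"), p("morpho_phenotypes.tsv"))
    g <- read_plink(p("genotypes"))
    g <- snp_qc(g)
    pheno <- readr::read_tsv(p("morpho_phenotypes.tsv"), show_col_types = FALSE)
    design <- assign_phenotypes(g, pheno)
    res <- if (model == "mixed") {
      lmm_assoc(g, design, covariates = covariates)
    } else {
      linear_assoc(g, design, covariates = covariates)
    }
    res$bonferroni <- bonferroni_threshold(0.05, sum(!is.na(res$p_value)))
    readr::write_tsv(res, p("gwas_results.tsv"))
    note("gwas", "results", p("gwas_results.tsv"))
  } else if ("gwas" %in% stages) {
    cs_inform("gwas: outputs present, skipping")
  }

  if ("sweep" %in% stages && !done(p("sweep_windows.tsv"))) {
    need("sweep", paste0(p("genotypes"), ".ped"), p("populations.yaml"))
    g <- read_plink(p("genotypes"))
    pops <- yaml::read_yaml(p("populations.yaml"))
    ho_b <- obs_het(g, pops$brachy)
    ho_d <- obs_het(g, pops$dolicho)
    hr <- log_h_ratio(ho_d, ho_b)
    fst_tbl <- fst(g, pops$brachy, unlist(pops[c("dolicho", "rest")]))
    win <- bind_rows(
      percentile_flags(sliding_windows(ho_b, stat = "ho"), tail = "low",
                       frac = 0.05),
      percentile_flags(sliding_windows(hr, stat = "log_hr"), tail = "high",
                       frac = 0.05),
      percentile_flags(sliding_windows(fst_tbl, stat = "fst"), tail = "high",
                       frac = 0.05))
    readr::write_tsv(win, p("sweep_windows.tsv"))
    note("sweep", "windows", p("sweep_windows.tsv"))
  } else if ("sweep" %in% stages) {
    cs_inform("sweep: outputs present, skipping")
  }

  if ("interval" %in% stages && !done(p("interval_report.tsv"))) {
    need("interval", p("sweep_windows.tsv"), paste0(p("genotypes"), ".ped"),
         p("populations.yaml"))
    g <- read_plink(p("genotypes"))
    pops <- yaml::read_yaml(p("populations.yaml"))
    win <- readr::read_tsv(p("sweep_windows.tsv"), show_col_types = FALSE)
    top <- win %>%
      filter(.data$stat == "fst", !is.na(.data$value)) %>%
      arrange(dplyr::desc(.data$value)) %>%
      dplyr::slice(1)
    mi <- which(g$markers$chrom == top$chrom &
                  g$markers$pos >= top$start_pos &
                  g$markers$pos <= top$end_pos)
    sel_rows <- which(g$samples$breed %in% pops$brachy)
    haps <- em_phase(geno_subset(g, samples = sel_rows, markers = mi))
    present <- intersect(pops$brachy,
                         unique(haps$breed[haps$freq >= 0.2]))
    interval <- shared_interval(haps, target_breeds = present,
                                min_freq = 0.2)
    readr::write_tsv(interval, p("interval_report.tsv"))
    if (nrow(interval) > 0) interval_to_bed(interval, p("interval.bed"))
    note("interval", "report", p("interval_report.tsv"))
  } else if ("interval" %in% stages) {
    cs_inform("interval: outputs present, skipping")
  }

  if ("filter" %in% stages && !done(p("variants_filtered.tsv"))) {
    need("filter", p("panel.vcf"), p("genes.gff3"), p("conservation.bedGraph"),
         p("panel_phenotypes.tsv"), p("truth.json"))
    v <- read_variant_vcf(p("panel.vcf"))
    models <- read_gene_models(p("genes.gff3"))
    track <- read_conservation(p("conservation.bedGraph"))
    ph <- readr::read_tsv(p("panel_phenotypes.tsv"), show_col_types = FALSE)
    phenotype <- setNames(ph$phenotype, ph$sample_id)
    truth <- jsonlite::read_json(p("truth.json"))
    interval <- genomic_interval(truth$interval$chrom, truth$interval$start,
                                 truth$interval$end,
                                 provenance = "haplotype_sharing")
    out <- v %>%
      mask_gq() %>%
      variant_assoc(phenotype, exclude = "ScottishTerrier") %>%
      add_conservation(track) %>%
      conservation_filter() %>%
      gene_context_filter(models) %>%
      combine_filters(interval)
    flat <- as_tibble(out[, setdiff(names(out), c("gt", "gq"))])
    readr::write_tsv(flat, p("variants_filtered.tsv"))
    jsonlite::write_json(attr(out, "filter_summary"), p("filter_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    note("filter", "variants", p("variants_filtered.tsv"))
    note("filter", "summary", p("filter_summary.json"))
  } else if ("filter" %in% stages) {
    cs_inform("filter: outputs present, skipping")
  }

  man <- bind_rows(manifest)
  meta <- list(config_hash = rlang::hash(unclass(config)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("cranioscan")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               stages = stages)
  jsonlite::write_json(c(meta, list(outputs = man)), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  man
}
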