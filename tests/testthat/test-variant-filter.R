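toy_variants <- function(nv = 10, ns = 11, seed = 51, pos = NULL,
                         chrom = "32") {
  set.seed(seed)
  gt <- matrix(sample(0:2, nv * ns, TRUE), nv, ns)
  colnames(gt) <- paste0("g", seq_len(ns))
  gq <- matrix(sample(20:60, nv * ns, TRUE), nv, ns, dimnames = dimnames(gt))
  variant_table(rep(chrom, nv), pos %||% (1000L * seq_len(nv)),
                rep("A", nv), rep("G", nv), gt, gq,
                conservation = runif(nv))
}

test_that("genotype-quality masking is strict-below with an exact count", {
  expect_equal(eval(formals(mask_gq)$threshold), 8)
  v <- toy_variants(nv = 1, ns = 11)
  v$gq[1, 1:3] <- 5          # 3 of 11 calls below threshold
  v$gq[1, 4] <- 8            # boundary call: retained under strict below
  out <- suppressMessages(mask_gq(v))
  expect_equal(attr(out, "n_masked"), 3L)
  expect_equal(sum(is.na(out$gt)), 3L)
  expect_false(is.na(out$gt[1, 4]))
  # non-strict variant masks the boundary too
  out2 <- suppressMessages(mask_gq(v, strict = FALSE))
  expect_equal(attr(out2, "n_masked"), 4L)
})

test_that("panel association flags exactly the smallest 5% of p-values", {
  set.seed(52)
  nv <- 100; ns <- 10
  v <- toy_variants(nv = nv, ns = ns)
  phen <- setNames(rnorm(ns), colnames(v$gt))
  out <- variant_assoc(v, phen)
  evaluable <- which(!is.na(out$assoc_p))
  expect_equal(sum(out$associated), 5L)
  expect_setequal(which(out$associated),
                  evaluable[order(out$assoc_p[evaluable])[1:5]])
  # constant dosage: no p-value, never flagged
  v2 <- v; v2$gt[7, ] <- 1L
  out2 <- variant_assoc(v2, phen)
  expect_true(is.na(out2$assoc_p[7]))
  expect_false(out2$associated[7])
  # excluded samples do not enter the regression
  out3 <- variant_assoc(v, phen, exclude = c("g1", "g2"))
  expect_false(identical(out3$assoc_p, out$assoc_p))
  expect_error(variant_assoc(v, phen[1:3]), "at least 4")
})

test_that("conservation flagging is inclusive at the boundary and skips absent scores", {
  expect_equal(eval(formals(conservation_filter)$min_score), 0.7)
  v <- toy_variants(nv = 20)
  v$conservation <- c(seq(0, 0.65, length.out = 16), 0.7, 0.8, 0.95, NA)
  out <- conservation_filter(v)
  expect_equal(sum(out$conserved), 3L)        # 0.7 counts, NA does not
  expect_true(out$conserved[17])
  expect_false(out$conserved[20])
  # hand count: 4 of 20 at or above threshold
  v$conservation[1] <- 0.71
  expect_equal(sum(conservation_filter(v)$conserved), 4L)
})

test_that("gene context flags exonic and splice-adjacent positions with exact boundaries", {
  expect_equal(eval(formals(gene_context_filter)$splice_window), 20L)
  models <- tibble::tibble(gene_id = "g1", strand = "+",
                           start = c(1000L, 2000L), end = c(1199L, 2399L))
  pos <- c(999L, 1000L, 1199L, 1200L, 1219L, 1220L, 1221L,
           1980L, 1979L, 2399L, 2419L, 2420L, 5000L)
  v <- toy_variants(nv = length(pos), pos = pos)
  out <- gene_context_filter(v, models)
  expect_equal(out$in_exon,
               pos %in% c(1000L, 1199L, 2399L) | (pos >= 2000 & pos <= 2399))
  # exon1 end 1199 is an internal junction: intronic bases 1200..1219 flag
  expect_true(out$near_splice[pos == 1200])
  expect_true(out$near_splice[pos == 1219])
  expect_false(out$near_splice[pos == 1220])
  # exon2 start 2000 is an internal junction: 1980..1999 flag
  expect_true(out$near_splice[pos == 1980])
  expect_false(out$near_splice[pos == 1979])
  # outer gene edges are not splice junctions
  expect_false(out$near_splice[pos == 999])
  expect_false(out$near_splice[pos == 2419])
  expect_false(out$near_splice[pos == 2420])
  # an exonic position is never near_splice
  expect_false(any(out$near_splice & out$in_exon))
  bad <- tibble::tibble(gene_id = "broken", strand = "+",
                        start = c(10L, 15L), end = c(20L, 30L))
  expect_error(gene_context_filter(v, bad), "broken")
})

test_that("combining filters gates on the interval and matches a brute-force union", {
  cfg <- sim_config(seed = 53)
  pan <- simulate_resequencing_panel(cfg)
  out <- suppressMessages(
    pan$variants |>
      mask_gq() |>
      variant_assoc(pan$phenotype, exclude = "ScottishTerrier") |>
      conservation_filter() |>
      gene_context_filter(pan$models) |>
      combine_filters(pan$interval))
  # brute-force oracle over every record
  expected <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    in_int <- out$chrom[i] == pan$interval$chrom &&
      out$pos[i] >= pan$interval$start && out$pos[i] <= pan$interval$end
    expected[i] <- in_int && (out$conserved[i] || out$associated[i] ||
                                out$in_exon[i] || out$near_splice[i])
  }
  expect_identical(out$of_interest, expected)
  smry <- attr(out, "filter_summary")
  expect_equal(smry$n[smry$criterion == "of_interest"], sum(expected))
  # the planted causal variant always survives
  expect_true(out$of_interest[out$pos == pan$truth$causal_pos])
  # a perfect-scoring record outside the interval is never flagged
  far <- combine_filters(out, genomic_interval("1", 1, 2))
  expect_equal(sum(far$of_interest), 0L)
  expect_error(combine_filters(pan$variants, pan$interval), "criterion")
})

test_that("codon annotation translates substitutions on both strands", {
  model <- tibble::tibble(gene_id = "g", strand = "+", start = 101L, end = 190L)
  cds <- paste(rep("GCT", 30), collapse = "")                 # poly-Ala
  # plant codons: codon 4 = TTC, codon 5 = GGC, codon 6 = TAC
  substr(cds, 10, 18) <- "TTCGGCTAC"
  # TTC -> TTA: Phe -> Leu missense
  ann <- annotate_codon_change(model, cds, 100L + 12L, "A")
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$notation, "F4L")
  expect_equal(ann$label, "Phe4Leu")
  # GGC -> GGA: synonymous glycine
  ann2 <- annotate_codon_change(model, cds, 100L + 15L, "A")
  expect_equal(ann2$consequence, "synonymous")
  expect_equal(ann2$aa_ref, "G")
  # TAC -> TAA: stop gain
  ann3 <- annotate_codon_change(model, cds, 100L + 18L, "A")
  expect_equal(ann3$consequence, "stop_gain")
  # outside the CDS
  expect_equal(annotate_codon_change(model, cds, 95L, "A")$consequence,
               "non_coding")
})

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

test_that("reverse-strand annotation equals the mirrored forward-strand annotation", {
  set.seed(54)
  cds_fwd <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  start <- 501L; end <- 560L
  model_fwd <- tibble::tibble(gene_id = "f", strand = "+", start = start,
                              end = end)
  model_rev <- tibble::tibble(gene_id = "r", strand = "-", start = start,
                              end = end)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in c(505L, 523L, 544L, 560L)) {
    alt <- sample(setdiff(c("A", "C", "G", "T"),
                          substr(cds_fwd, pos - start + 1, pos - start + 1)), 1)
    a_rev <- annotate_codon_change(model_rev, revcomp(cds_fwd), pos, alt)
    # mirror the coordinate system: position start+end-pos on the plus strand
    # of the reverse-complemented sequence, with the complementary base
    a_mirror <- annotate_codon_change(model_fwd, revcomp(cds_fwd),
                                      start + end - pos, unname(comp[alt]))
    expect_equal(a_rev$consequence, a_mirror$consequence)
    expect_equal(a_rev$aa_pos, a_mirror$aa_pos)
    expect_equal(a_rev$ref_codon, a_mirror$ref_codon)
    expect_equal(a_rev$alt_codon, a_mirror$alt_codon)
  }
})

test_that("variant tables round-trip through VCF with genotype qualities", {
  v <- toy_variants(nv = 8, ns = 5)
  v$gt[2, 3] <- NA
  path <- file.path(withr::local_tempdir(), "panel.vcf")
  write_variant_vcf(v, path)
  v2 <- read_variant_vcf(path)
  expect_equal(unname(v2$gt), unname(v$gt))
  expect_equal(unname(v2$gq[!is.na(v$gt)]), unname(v$gq[!is.na(v$gt)]))
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$ref, v$ref)
})
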