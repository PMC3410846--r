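#' Mask low-quality genotype calls
#'
#' Per-sample genotypes whose genotype quality is strictly below the
#' threshold are reset to missing. (A `>=`-style boundary is available via
#' `strict = FALSE` since published descriptions of this step differ on the
#' boundary.)
#'
#' @param v A `variant_table`.
#' @param threshold GQ threshold (default 8).
#' @param strict If `TRUE` (default) mask calls with `GQ < threshold`; if
#'   `FALSE` mask `GQ <= threshold`.
#' @return `v` with masked calls; attribute `"n_masked"` counts them.
#' @export
mask_gq <- function(v, threshold = 8, strict = TRUE) {
  stopifnot(threshold >= 0)
  bad <- if (strict) v$gq < threshold else v$gq <= threshold
  bad <- bad & !is.na(v$gt)
  v$gt[bad] <- NA_integer_
  attr(v, "n_masked") <- sum(bad)
  cs_inform("mask_gq: masked ", sum(bad), " call(s) below GQ ", threshold)
  v
}

#' Per-variant association over a small genome panel
#'
#' Additive linear regression of a per-genome phenotype on dosage at each
#' variant, omitting listed outlier samples. The `associated` flag marks
#' variants whose p-value lies within the smallest `tail` fraction of the
#' panel's p-value distribution (empirical mid-rank percentile over the
#' variants that were evaluable after masking).
#'
#' @param v A `variant_table` (after [mask_gq()]).
#' @param phenotype Named numeric vector of per-genome phenotypes (names are
#'   sample ids).
#' @param exclude Sample ids omitted from the regression (e.g. a known
#'   phenotypic outlier).
#' @param tail Fraction of smallest p-values flagged (default 0.05).
#' @return `v` with `assoc_p`, `assoc_rank_frac` and `associated` columns;
#'   unevaluable variants (constant or near-empty dosage) get `NA` and are
#'   never flagged.
#' @export
variant_assoc <- function(v, phenotype, exclude = character(), tail = 0.05) {
  samples <- setdiff(intersect(variant_samples(v), names(phenotype)), exclude)
  if (length(samples) < 4) abort("need at least 4 non-excluded genomes with phenotype")
  y <- phenotype[samples]
  G <- v$gt[, samples, drop = FALSE]
  pvals <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    x <- G[i, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4 || var(x[ok]) == 0 || var(y[ok]) == 0) next
    ft <- summary(lm(y[ok] ~ x[ok]))$coefficients
    if (nrow(ft) < 2) next
    pvals[i] <- ft[2, 4]
  }
  n_eval <- sum(!is.na(pvals))
  rk <- rep(NA_real_, length(pvals))
  if (n_eval > 0) {
    rk[!is.na(pvals)] <- rank(pvals[!is.na(pvals)], ties.method = "average")
  }
  v$assoc_p <- pvals
  v$assoc_rank_frac <- rk / n_eval
  v$associated <- !is.na(rk) & rk <= tail * n_eval
  v
}

#' Flag conserved positions
#'
#' @param v A `variant_table` with a `conservation` column.
#' @param min_score Conservation threshold; positions with score `>=
#'   min_score` are flagged (default 0.7). Absent scores are never flagged.
#' @return `v` with a `conserved` column.
#' @export
conservation_filter <- function(v, min_score = 0.7) {
  v$conserved <- !is.na(v$conservation) & v$conservation >= min_score
  v
}

validate_gene_models <- function(models) {
  for (gid in unique(models$gene_id)) {
    ex <- models[models$gene_id == gid, ]
    ex <- arrange(ex, .data$start)
    if (any(ex$end < ex$start) ||
        (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))) {
      abort(paste0("malformed gene model (unsorted or overlapping exons): ",
                   gid))
    }
  }
  invisible(models)
}

#' Flag exonic and splice-adjacent positions
#'
#' `in_exon` marks positions inside any exon (1-based inclusive endpoints;
#' untranslated regions count as exonic). `near_splice` marks intronic
#' positions within `splice_window` bases of a splice junction (an internal
#' exon boundary), measured from the boundary base on the intronic side; a
#' position in an exon is never `near_splice`.
#'
#' @param v A `variant_table`.
#' @param models Gene-model exon tibble (`gene_id, strand, start, end`).
#' @param splice_window Distance window in bases (default 20).
#' @return `v` with `in_exon` and `near_splice` columns.
#' @export
gene_context_filter <- function(v, models, splice_window = 20L) {
  stopifnot(splice_window >= 0)
  validate_gene_models(models)
  in_exon <- rep(FALSE, nrow(v))
  near_splice <- rep(FALSE, nrow(v))
  for (gid in unique(models$gene_id)) {
    ex <- arrange(models[models$gene_id == gid, ], .data$start)
    for (i in seq_len(nrow(ex))) {
      in_exon <- in_exon | (v$pos >= ex$start[i] & v$pos <= ex$end[i])
    }
    if (nrow(ex) > 1) {
      donor_ends <- ex$end[-nrow(ex)]      # junction at downstream edge of exon
      acceptor_starts <- ex$start[-1]      # junction at upstream edge of exon
      for (b in donor_ends) {
        near_splice <- near_splice | (v$pos >= b + 1L & v$pos <= b + splice_window)
      }
      for (b in acceptor_starts) {
        near_splice <- near_splice | (v$pos >= b - splice_window & v$pos <= b - 1L)
      }
    }
  }
  v$in_exon <- in_exon
  v$near_splice <- near_splice & !in_exon
  v
}

#' Combine filter criteria into variants of interest
#'
#' A variant is `of_interest` when its position falls inside the active
#' critical interval AND it meets at least one criterion: conserved,
#' associated, exonic, or splice-adjacent.
#'
#' @param v A `variant_table` that has been through [variant_assoc()],
#'   [conservation_filter()] and [gene_context_filter()].
#' @param interval A `genomic_interval`.
#' @return `v` with an `of_interest` column; attribute `"filter_summary"` is
#'   a tibble of per-criterion and overall counts.
#' @export
combine_filters <- function(v, interval) {
  need <- c("conserved", "associated", "in_exon", "near_splice")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0) {
    abort(paste0("run the criterion filters first; missing: ",
                 paste(miss, collapse = ", ")))
  }
  in_int <- v$chrom == interval$chrom &
    v$pos >= interval$start & v$pos <= interval$end
  v$of_interest <- in_int &
    (v$conserved | v$associated | v$in_exon | v$near_splice)
  attr(v, "filter_summary") <- tibble(
    criterion = c("in_interval", need, "of_interest"),
    n = c(sum(in_int), sum(v$conserved & in_int), sum(v$associated & in_int),
          sum(v$in_exon & in_int), sum(v$near_splice & in_int),
          sum(v$of_interest)))
  v
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

#' Annotate the codon consequence of a coding SNV
#'
#' Maps a genomic position into the coding sequence through the gene model's
#' exons (respecting strand), substitutes the alternate base, and translates
#' reference and alternate codons with the standard genetic code.
#'
#' @param model Exon tibble for one gene (`gene_id, strand, start, end`);
#'   exons are taken to be the CDS, whose concatenated length must equal
#'   `nchar(cds_seq)` and be divisible by 3.
#' @param cds_seq Coding sequence, 5' to 3' on the coding strand.
#' @param pos Genomic position of the SNV (1-based).
#' @param alt Alternate base on the genomic plus strand.
#' @return One-row tibble: `consequence` (`missense`, `synonymous`,
#'   `stop_gain`, `stop_loss`, or `non_coding`), `aa_pos`, `aa_ref`,
#'   `aa_alt` (one-letter), `ref_codon`, `alt_codon`, `notation` (e.g.
#'   `"F452L"`), `label` (e.g. `"Phe452Leu"`).
#' @export
annotate_codon_change <- function(model, cds_seq, pos, alt) {
  validate_gene_models(model)
  ex <- arrange(model, .data$start)
  strand <- ex$strand[1]
  cds_len <- sum(ex$end - ex$start + 1)
  if (cds_len != nchar(cds_seq)) abort("cds_seq length does not match exons")
  if (cds_len %% 3 != 0) abort("CDS length not divisible by 3")
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0) {
    return(tibble(consequence = "non_coding", aa_pos = NA_integer_,
                  aa_ref = NA_character_, aa_alt = NA_character_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  notation = NA_character_, label = NA_character_))
  }
  before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] - ex$start[seq_len(hit - 1)] + 1) else 0
  fwd_index <- before + (pos - ex$start[hit] + 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (strand == "-") {
    cds_index <- cds_len - fwd_index + 1
    alt_cds <- unname(comp[toupper(alt)])
  } else {
    cds_index <- fwd_index
    alt_cds <- toupper(alt)
  }
  codon_idx <- (cds_index - 1) %/% 3 + 1
  offset <- (cds_index - 1) %% 3 + 1
  ref_codon <- toupper(substr(cds_seq, (codon_idx - 1) * 3 + 1, codon_idx * 3))
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt_cds
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon]); aa_alt <- unname(code[alt_codon])
  consequence <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stop_gain"
  else if (aa_ref == "*") "stop_loss"
  else "missense"
  tibble(consequence = consequence, aa_pos = as.integer(codon_idx),
         aa_ref = aa_ref, aa_alt = aa_alt,
         ref_codon = ref_codon, alt_codon = alt_codon,
         notation = paste0(aa_ref, codon_idx, aa_alt),
         label = paste0(AA3[aa_ref], codon_idx, AA3[aa_alt]))
}
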