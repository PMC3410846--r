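#' Construct a variant table
#'
#' One row per variant; per-sample genotypes and genotype qualities ride
#' along as matrix columns (`gt`, `gq`) so the table stays pipe-friendly.
#'
#' @param chrom,pos,ref,alt Per-variant site columns (`pos` 1-based).
#' @param gt Integer matrix variants x samples of 0/1/2 dosages (`NA`
#'   missing), with sample ids as column names.
#' @param gq Numeric matrix of genotype qualities, same shape as `gt`.
#' @param conservation Optional per-variant conservation score in `[0, 1]`
#'   (`NA` = absent).
#' @return Tibble of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gt, gq = NULL,
                          conservation = NULL) {
  gt <- as.matrix(gt); storage.mode(gt) <- "integer"
  if (is.null(gq)) gq <- matrix(99, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gq <- as.matrix(gq)
  stopifnot(nrow(gt) == length(pos), all(dim(gq) == dim(gt)))
  if (is.null(colnames(gt))) abort("gt needs sample ids as column names")
  cons <- conservation %||% rep(NA_real_, length(pos))
  if (any(!is.na(cons) & (cons < 0 | cons > 1))) {
    abort("conservation scores must lie in [0, 1]")
  }
  out <- tibble(chrom = as.character(chrom), pos = as.integer(pos),
                ref = as.character(ref), alt = as.character(alt),
                conservation = as.double(cons))
  out$gt <- gt
  out$gq <- gq
  class(out) <- c("variant_table", class(out))
  out
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x), "variants x", ncol(x$gt), "samples on",
      paste(unique(x$chrom), collapse = ","), "\n")
  NextMethod()
}

variant_samples <- function(v) colnames(v$gt)

#' Read/write a variant VCF with genotype qualities
#'
#' Reading goes through `vcfR` and keeps bi-allelic SNVs with a `GQ` FORMAT
#' field (absent GQ defaults to 99); writing emits plain-text VCF with
#' `GT:GQ`.
#'
#' @param path VCF path (plain text or bgzipped for reading).
#' @return A `variant_table`.
#' @export
read_variant_vcf <- function(path) {
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT)
  gt_raw <- vcfR::extract.gt(vc, element = "GT")[keep, , drop = FALSE]
  gq_raw <- suppressWarnings(
    vcfR::extract.gt(vc, element = "GQ", as.numeric = TRUE))
  gq_raw <- if (is.null(gq_raw)) NULL else gq_raw[keep, , drop = FALSE]
  to_dosage <- function(col) {
    d <- rep(NA_integer_, length(col))
    d[col %in% c("0/0", "0|0")] <- 0L
    d[col %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[col %in% c("1/1", "1|1")] <- 2L
    d
  }
  gt <- apply(gt_raw, 2, to_dosage)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep),
                                     dimnames = list(NULL, colnames(gt_raw)))
  if (is.null(gq_raw)) {
    gq_raw <- matrix(99, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  gq_raw[is.na(gq_raw)] <- 99
  variant_table(fix$CHROM[keep], as.integer(fix$POS[keep]), fix$REF[keep],
                fix$ALT[keep], gt, gq_raw)
}

#' @rdname read_variant_vcf
#' @param v A `variant_table`.
#' @export
write_variant_vcf <- function(v, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=cranioscan",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", variant_samples(v)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- v$gt[i, ]
    cells <- paste0(ifelse(is.na(d), "./.", gt_str[d + 1L]), ":",
                    round(v$gq[i, ]))
    info <- if (!is.na(v$conservation[i]))
      sprintf("CONS=%g", v$conservation[i]) else "."
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            info, "GT:GQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports exon features via `rtracklayer` and returns the tidy exon table
#' the filters consume.
#'
#' @param path GFF3 file whose exon features carry a gene identifier in
#'   `Parent` or `gene_id`.
#' @return Tibble: `gene_id, strand, start, end` (1-based inclusive), sorted
#'   by gene and start.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  md <- S4Vectors::mcols(ex)
  gene <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) sub("^.*:", "", as.character(p)[1]), character(1))
  } else if ("gene_id" %in% names(md)) as.character(md$gene_id)
  else as.character(md$ID)
  tibble(gene_id = gene,
         strand = as.character(BiocGenerics::strand(ex)),
         start = BiocGenerics::start(ex), end = BiocGenerics::end(ex)) %>%
    arrange(.data$gene_id, .data$start)
}

#' @rdname read_gene_models
#' @param models A gene-model exon tibble (with a `chrom` column or `chrom`
#'   argument).
#' @param chrom Chromosome name used when `models` lacks one.
#' @export
write_gene_models <- function(models, path, chrom = "32") {
  ch <- if ("chrom" %in% names(models)) models$chrom else rep(chrom, nrow(models))
  gr <- GenomicRanges::GRanges(
    seqnames = ch,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand,
    type = "exon",
    ID = paste0(models$gene_id, ":exon", seq_len(nrow(models))),
    Parent = paste0("gene:", models$gene_id))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write a per-base conservation track (bedGraph)
#'
#' @param path bedGraph path (0-based half-open intervals with a score).
#' @return Tibble: `chrom, start, end, score` with 1-based inclusive
#'   coordinates.
#' @export
read_conservation <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
         score = gr$score)
}

#' @rdname read_conservation
#' @param track Conservation tibble (`chrom, start, end, score`, 1-based
#'   inclusive).
#' @export
write_conservation <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start, end = track$end),
    score = track$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Attach conservation scores to variants
#'
#' @param v A `variant_table`.
#' @param track A [read_conservation()] tibble.
#' @return `v` with its `conservation` column filled where the track covers
#'   the position.
#' @export
add_conservation <- function(v, track) {
  for (i in seq_len(nrow(v))) {
    hit <- which(track$chrom == v$chrom[i] & track$start <= v$pos[i] &
                   track$end >= v$pos[i])
    if (length(hit) > 0) v$conservation[i] <- track$score[hit[1]]
  }
  v
}
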