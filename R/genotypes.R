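#' Construct a genotype matrix object
#'
#' Thin container pairing a dogs x SNPs minor-allele dosage matrix with its
#' marker map and sample metadata.
#'
#' @param calls Integer matrix (individuals x markers), entries 0/1/2 or `NA`.
#' @param markers Tibble with `marker_id, chrom, pos` (1-based) and optional
#'   `a1, a2` allele columns; positions must be strictly increasing within a
#'   chromosome.
#' @param samples Tibble with `sample_id, breed, sex`.
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- as_tibble(markers)
  samples <- as_tibble(samples)
  if (nrow(markers) != ncol(calls)) abort("markers do not match call columns")
  if (nrow(samples) != nrow(calls)) abort("samples do not match call rows")
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls))) {
    abort("calls must be 0/1/2 or NA")
  }
  if (!"marker_id" %in% names(markers)) {
    markers$marker_id <- paste0("snp", seq_len(nrow(markers)))
  }
  bad <- markers %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("marker positions not strictly increasing on chromosome ",
                 paste(bad$chrom, collapse = ", ")))
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- markers$marker_id
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "markers on", length(unique(x$markers$chrom)), "chromosome(s);",
      length(unique(x$samples$breed)), "breed(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# subset helper used across modules
geno_subset <- function(g, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(g$calls)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(g$calls)) else markers
  geno_matrix(g$calls[si, mi, drop = FALSE],
              g$markers[mi, , drop = FALSE],
              g$samples[si, , drop = FALSE])
}

#' Marker quality control
#'
#' Retains markers with missing-call fraction strictly below `max_missing`
#' and minor allele frequency strictly above `min_maf` (frequencies computed
#' among non-missing calls).
#'
#' @param g A `geno_matrix`.
#' @param max_missing,min_maf QC thresholds (defaults 0.10 and 0.01).
#' @return Filtered `geno_matrix` with attribute `"qc"`: tibble of counts
#'   removed per criterion.
#' @export
snp_qc <- function(g, max_missing = 0.10, min_maf = 0.01) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  miss <- colMeans(is.na(g$calls))
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- miss < max_missing & maf > min_maf
  qc <- tibble(criterion = c("missingness", "maf", "kept"),
               n = c(sum(miss >= max_missing),
                     sum(maf <= min_maf & miss < max_missing),
                     sum(keep)))
  if (!any(keep)) warn("snp_qc removed every marker")
  out <- geno_subset(g, markers = which(keep))
  attr(out, "qc") <- qc
  out
}

#' Write/read genotypes as PLINK text PED/MAP
#'
#' Minimal text PED/MAP support for bi-allelic SNPs: alleles are written as
#' `A` (major) / `B` (minor); missing calls as `0 0`. The MAP file carries
#' `chrom, marker_id, 0, pos`.
#'
#' @param g A `geno_matrix`.
#' @param prefix Path prefix; `.ped` and `.map` are appended.
#' @export
write_plink <- function(g, prefix) {
  al <- function(d) {
    out <- c("A A", "A B", "B B")[d + 1L]
    out[is.na(d)] <- "0 0"
    out
  }
  ped <- vapply(seq_len(nrow(g$calls)), function(i) {
    paste(g$samples$breed[i], g$samples$sample_id[i], 0, 0,
          ifelse(g$samples$sex[i] == "M", 1, 2), -9,
          paste(al(g$calls[i, ]), collapse = " "))
  }, character(1))
  writeLines(ped, paste0(prefix, ".ped"))
  writeLines(paste(g$markers$chrom, g$markers$marker_id, 0, g$markers$pos,
                   sep = "\t"),
             paste0(prefix, ".map"))
  invisible(prefix)
}

#' @rdname write_plink
#' @return `read_plink()` returns a `geno_matrix` (dosage of allele `B`).
#' @export
read_plink <- function(prefix) {
  map <- readr::read_tsv(paste0(prefix, ".map"),
                         col_names = c("chrom", "marker_id", "cm", "pos"),
                         col_types = "ccid", progress = FALSE)
  lines <- readLines(paste0(prefix, ".ped"))
  fields <- strsplit(trimws(lines), "\\s+")
  m <- nrow(map)
  calls <- matrix(NA_integer_, nrow = length(fields), ncol = m)
  samples <- tibble(sample_id = character(length(fields)),
                    breed = character(length(fields)),
                    sex = character(length(fields)))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6 + 2 * m) abort(paste0("malformed PED line ", i))
    samples$breed[i] <- f[1]; samples$sample_id[i] <- f[2]
    samples$sex[i] <- if (f[5] == "1") "M" else "F"
    a <- f[seq(7, length(f), by = 2)]
    b <- f[seq(8, length(f), by = 2)]
    d <- (a == "B") + (b == "B")
    d[a == "0" | b == "0"] <- NA_integer_
    calls[i, ] <- as.integer(d)
  }
  geno_matrix(calls, mutate(map, pos = as.integer(.data$pos)) %>%
                select("marker_id", "chrom", "pos"), samples)
}

#' Write/read genotypes as VCF
#'
#' Writes a minimal plain-text VCF (GT field only, unphased) for a
#' `geno_matrix`; reads any bi-allelic-SNP VCF back via `vcfR`. Breed and sex
#' metadata travel in `##SAMPLE=` header lines.
#'
#' @param g A `geno_matrix`.
#' @param path Output `.vcf` path (plain text).
#' @export
write_geno_vcf <- function(g, path) {
  a1 <- if ("a1" %in% names(g$markers)) g$markers$a1 else rep("A", ncol(g$calls))
  a2 <- if ("a2" %in% names(g$markers)) g$markers$a2 else rep("C", ncol(g$calls))
  gt <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=cranioscan",
              sprintf("##SAMPLE=<ID=%s,Breed=%s,Sex=%s>",
                      g$samples$sample_id, g$samples$breed, g$samples$sex),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$samples$sample_id), collapse = "\t"))
  body <- vapply(seq_len(ncol(g$calls)), function(j) {
    d <- g$calls[, j]
    cells <- gt[d + 1L]
    cells[is.na(d)] <- "./."
    paste(c(g$markers$chrom[j], g$markers$pos[j], g$markers$marker_id[j],
            a1[j], a2[j], ".", "PASS", ".", "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_geno_vcf
#' @export
read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, 2, function(col) {
    d <- rep(NA_integer_, length(col))
    d[col %in% c("0/0", "0|0")] <- 0L
    d[col %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[col %in% c("1/1", "1|1")] <- 2L
    d
  })
  calls <- t(dos)
  meta <- v@meta
  sm <- meta[grepl("^##SAMPLE=", meta)]
  samples <- tibble(sample_id = colnames(gt), breed = "unknown", sex = "F")
  if (length(sm) > 0) {
    ids <- sub(".*<ID=([^,>]+).*", "\\1", sm)
    breeds <- ifelse(grepl("Breed=", sm), sub(".*Breed=([^,>]+).*", "\\1", sm), "unknown")
    sexes <- ifelse(grepl("Sex=", sm), sub(".*Sex=([^,>]+).*", "\\1", sm), "F")
    idx <- match(samples$sample_id, ids)
    ok <- !is.na(idx)
    samples$breed[ok] <- breeds[idx[ok]]
    samples$sex[ok] <- sexes[idx[ok]]
  }
  markers <- tibble(marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                       paste0(fix$CHROM, ":", fix$POS), fix$ID),
                    chrom = fix$CHROM, pos = as.integer(fix$POS),
                    a1 = fix$REF, a2 = fix$ALT)
  geno_matrix(calls, markers, samples)
}
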