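#' Haplotype frequency estimation by expectation-maximization
#'
#' Small-window EM over the full `2^m` haplotype space: the E-step
#' distributes each unphased genotype over its compatible haplotype pairs in
#' proportion to current frequencies, the M-step re-estimates frequencies
#' from the expected pair counts. Frequencies are estimated per breed (each
#' breed's frequencies sum to 1). Individuals with a missing call inside the
#' window are dropped from that breed with a message.
#'
#' @param g A `geno_matrix` restricted to the window of interest.
#' @param max_markers Safety cap on window width (default 12; the haplotype
#'   space is `2^m`).
#' @param tol Convergence threshold on the largest frequency change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param min_freq Haplotypes below this frequency are pruned from the output
#'   (default 1e-6).
#' @param by_breed If `FALSE`, estimate a single pooled frequency vector
#'   (reported under breed `"pooled"`).
#' @return Object of class `phased_haplotypes`: tibble `breed, haplotype`
#'   (allele string over the window markers, `0` = ref/major, `1` = minor),
#'   `freq`, `n_chromosomes`; attribute `"markers"` carries the marker map.
#' @export
em_phase <- function(g, max_markers = 12L, tol = 1e-8, max_iter = 500L,
                     min_freq = 1e-6, by_breed = TRUE) {
  m <- ncol(g$calls)
  if (m > max_markers) {
    abort(paste0("window has ", m, " markers (> max_markers = ", max_markers,
                 "); split the window"))
  }
  n_h <- 2L^m
  hap_alleles <- function(h) as.integer(intToBits(h))[seq_len(m)]
  hap_strings <- vapply(0:(n_h - 1L), function(h)
    paste(hap_alleles(h), collapse = ""), character(1))

  # compatible ordered pairs for a genotype vector: het sites split 2 ways
  pairs_for <- function(geno) {
    het <- which(geno == 1L)
    base <- sum(bitwShiftL(1L, which(geno == 2L) - 1L))
    if (length(het) == 0) return(cbind(base, base))
    combos <- as.matrix(expand.grid(rep(list(0:1), length(het))))
    h1 <- base + combos %*% bitwShiftL(1L, het - 1L)
    h2 <- base + (1 - combos) %*% bitwShiftL(1L, het - 1L)
    cbind(as.integer(h1), as.integer(h2))
  }

  em_fit <- function(calls) {
    n <- nrow(calls)
    plist <- lapply(seq_len(n), function(i) pairs_for(calls[i, ]))
    used <- sort(unique(unlist(plist)))
    f <- rep(0, n_h)
    f[used + 1L] <- 1 / length(used)
    for (it in seq_len(max_iter)) {
      expected <- rep(0, n_h)
      for (pp in plist) {
        w <- f[pp[, 1] + 1L] * f[pp[, 2] + 1L]
        if (sum(w) <= 0) w <- rep(1, nrow(pp))
        w <- w / sum(w)
        for (r in seq_len(nrow(pp))) {
          expected[pp[r, 1] + 1L] <- expected[pp[r, 1] + 1L] + w[r]
          expected[pp[r, 2] + 1L] <- expected[pp[r, 2] + 1L] + w[r]
        }
      }
      f_new <- expected / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    f
  }

  groups <- if (by_breed) split(seq_len(nrow(g$calls)), g$samples$breed)
  else list(pooled = seq_len(nrow(g$calls)))
  res <- purrr::imap(groups, function(ix, br) {
    calls <- g$calls[ix, , drop = FALSE]
    ok <- rowSums(is.na(calls)) == 0
    if (!all(ok)) {
      cs_inform("em_phase: dropping ", sum(!ok),
                " individual(s) with missing calls in breed ", br)
      calls <- calls[ok, , drop = FALSE]
    }
    if (nrow(calls) == 0) return(NULL)
    f <- em_fit(calls)
    keep <- f >= min_freq
    f_kept <- f[keep] / sum(f[keep])
    tibble(breed = br, haplotype = hap_strings[keep], freq = f_kept,
           n_chromosomes = 2L * nrow(calls))
  })
  out <- bind_rows(res) %>% arrange(.data$breed, dplyr::desc(.data$freq))
  attr(out, "markers") <- g$markers
  class(out) <- c("phased_haplotypes", class(out))
  out
}

#' Critical interval from haplotype sharing
#'
#' Among the haplotypes contributed by the target breeds (those at or above
#' `min_freq` within their breed), finds the maximal run of consecutive
#' markers over which all contributing haplotypes carry identical alleles.
#' The interval is reported as the positions of the run's first and last
#' marker (ties broken leftmost).
#'
#' @param haps A `phased_haplotypes` table (needs its `"markers"` attribute),
#'   or a tibble of the same shape passed with `markers`.
#' @param target_breeds Breeds that must each contribute at least one
#'   haplotype.
#' @param min_freq Minimum within-breed frequency for a haplotype to
#'   contribute (default 0.2: a haplotype must be common within its breed to
#'   define that breed's selected haplotype, which keeps low-frequency
#'   phasing noise from breaking the shared run).
#' @param markers Optional marker map overriding the attribute.
#' @return A `genomic_interval` (provenance `"haplotype_sharing"`); empty
#'   when no marker is shared by all contributing haplotypes.
#' @export
shared_interval <- function(haps, target_breeds, min_freq = 0.2,
                            markers = NULL) {
  markers <- markers %||% attr(haps, "markers")
  if (is.null(markers)) abort("no marker map available")
  contrib <- haps %>%
    filter(.data$breed %in% target_breeds, .data$freq >= min_freq)
  missing_breeds <- setdiff(target_breeds, unique(contrib$breed))
  if (length(missing_breeds) > 0) {
    abort(paste0("no haplotype at min_freq for breed(s): ",
                 paste(missing_breeds, collapse = ", ")))
  }
  H <- do.call(rbind, lapply(strsplit(contrib$haplotype, ""), as.integer))
  agree <- apply(H, 2, function(col) length(unique(col)) == 1L)
  if (!any(agree)) {
    cs_inform("shared_interval: no shared marker; empty interval")
    return(empty_interval())
  }
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]   # which.max is leftmost on ties
  i1 <- starts[best]; i2 <- ends[best]
  genomic_interval(markers$chrom[1], markers$pos[i1], markers$pos[i2],
                   n_markers = i2 - i1 + 1L, provenance = "haplotype_sharing")
}

#' Refine a critical interval by two-genome allelic agreement
#'
#' Scans positions inside the interval in ascending order and truncates the
#' interval at the last position where the two genomes' genotypes agree
#' before their first disagreement (heterozygous versus homozygous counts as
#' disagreement; a missing call in either genome is skipped, not a
#' disagreement).
#'
#' @param calls_a,calls_b Tibbles with `pos` and `gt` (0/1/2 dosage or `NA`)
#'   covering the interval for the two genomes.
#' @param interval A `genomic_interval`.
#' @return A `genomic_interval` with provenance `"breakpoint_refined"`;
#'   empty (with a message) when the genomes disagree before agreeing
#'   anywhere.
#' @export
refine_breakpoint <- function(calls_a, calls_b, interval) {
  joined <- inner_join(rename(calls_a, gt_a = "gt"),
                       rename(calls_b, gt_b = "gt"), by = "pos") %>%
    filter(.data$pos >= interval$start, .data$pos <= interval$end) %>%
    arrange(.data$pos) %>%
    filter(!is.na(.data$gt_a), !is.na(.data$gt_b))
  agree <- joined$gt_a == joined$gt_b
  first_dis <- which(!agree)[1]
  if (is.na(first_dis)) {
    out <- interval
    out$provenance <- "breakpoint_refined"
    return(out)
  }
  if (first_dis == 1L) {
    cs_inform("refine_breakpoint: disagreement at the first informative ",
              "position (", joined$pos[1], "); empty interval")
    return(empty_interval())
  }
  last_agree <- joined$pos[first_dis - 1L]
  genomic_interval(interval$chrom, interval$start, last_agree,
                   n_markers = sum(joined$pos <= last_agree),
                   provenance = "breakpoint_refined")
}

#' Tabulate panel support for a refined-interval haplotype
#'
#' Pure tabulation over a genotyping panel at a few named markers: per-marker
#' allele counts and the fraction of called panel chromosomes carrying the
#' expected (interval-haplotype) allele.
#'
#' @param panel A `geno_matrix` of panel individuals over (at least) the
#'   named markers; dosage is counted with `0` = expected allele.
#' @param marker_ids Markers to tabulate (default: all markers in `panel`).
#' @return Tibble: `marker_id, chrom, pos, n_chromosomes, n_consistent,
#'   fraction_consistent`; attribute `"overall"` gives the pooled fraction.
#' @export
confirm_breakpoint <- function(panel, marker_ids = NULL) {
  marker_ids <- marker_ids %||% panel$markers$marker_id
  mi <- match(marker_ids, panel$markers$marker_id)
  if (anyNA(mi)) {
    abort(paste0("markers absent from panel: ",
                 paste(marker_ids[is.na(mi)], collapse = ", ")))
  }
  calls <- panel$calls[, mi, drop = FALSE]
  n_chr <- unname(2L * colSums(!is.na(calls)))
  n_cons <- n_chr - unname(colSums(calls, na.rm = TRUE))  # dosage counts the non-expected allele
  out <- dplyr::bind_cols(panel$markers[mi, c("marker_id", "chrom", "pos")],
                          tibble(n_chromosomes = as.integer(n_chr),
                                 n_consistent = as.integer(n_cons),
                                 fraction_consistent = ifelse(n_chr > 0,
                                                              n_cons / n_chr,
                                                              NA_real_)))
  attr(out, "overall") <- sum(n_cons) / sum(n_chr)
  out
}
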