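#' Observed heterozygosity per marker within a population
#'
#' Fraction of heterozygous calls among non-missing calls, per marker, within
#' a named breed population (e.g. the brachycephalic or dolichocephalic polar
#' extreme of the shape axis).
#'
#' @param g A `geno_matrix`.
#' @param breeds Breed names defining the population.
#' @return Tibble: `marker_id, chrom, pos, ho, n_called`; `ho` is `NA` where
#'   no call is available.
#' @export
obs_het <- function(g, breeds) {
  keep <- g$samples$breed %in% breeds
  if (!any(keep)) abort("empty population: no samples match the breed list")
  calls <- g$calls[keep, , drop = FALSE]
  n_called <- unname(colSums(!is.na(calls)))
  het <- unname(colSums(calls == 1L, na.rm = TRUE))
  ho <- ifelse(n_called > 0, het / n_called, NA_real_)
  dplyr::bind_cols(g$markers[, c("marker_id", "chrom", "pos")],
                   tibble(ho = ho, n_called = n_called))
}

#' Log ratio of observed heterozygosities between two populations
#'
#' `log10((ho_a + pseudocount) / (ho_b + pseudocount))` per marker; markers
#' undefined in either population (or with a zero denominator at pseudocount
#' 0) come back `NA`. Conventionally population `a` is the dolichocephalic
#' set and `b` the brachycephalic set, so sweeps in `b` push the ratio up.
#'
#' @param ho_a,ho_b [obs_het()] tables over the same markers.
#' @param pseudocount Added to both heterozygosities before the ratio
#'   (default 0, with undefined values flagged `NA`).
#' @param base Logarithm base (default 10).
#' @return Tibble: `marker_id, chrom, pos, log_hr`.
#' @export
log_h_ratio <- function(ho_a, ho_b, pseudocount = 0, base = 10) {
  if (!identical(ho_a$marker_id, ho_b$marker_id)) {
    abort("marker vectors differ between the two populations")
  }
  num <- ho_a$ho + pseudocount
  den <- ho_b$ho + pseudocount
  val <- ifelse(is.na(num) | is.na(den) | num <= 0 | den <= 0,
                NA_real_, log(num / den, base = base))
  dplyr::bind_cols(ho_a[, c("marker_id", "chrom", "pos")],
                   tibble(log_hr = val))
}

#' Per-marker F_ST between two populations
#'
#' Default is the Hudson two-population estimator computed from sample allele
#' frequencies and allele counts (robust to unequal sample sizes); a Nei-type
#' `(H_T - H_S) / H_T` estimator is also offered. Values are clipped to
#' `[0, 1]`; markers monomorphic in both populations are `NA`.
#'
#' @param g A `geno_matrix`.
#' @param pop1,pop2 Breed name vectors defining the two populations (e.g. the
#'   brachycephalic subpopulation versus the rest).
#' @param method `"hudson"` (default) or `"nei"`.
#' @return Tibble: `marker_id, chrom, pos, fst`.
#' @export
fst <- function(g, pop1, pop2, method = c("hudson", "nei")) {
  method <- match.arg(method)
  freq_of <- function(breeds) {
    keep <- g$samples$breed %in% breeds
    if (!any(keep)) abort("empty population in fst()")
    calls <- g$calls[keep, , drop = FALSE]
    n_al <- unname(2 * colSums(!is.na(calls)))
    p <- ifelse(n_al > 0, unname(colSums(calls, na.rm = TRUE)) / n_al, NA_real_)
    list(p = p, n = n_al)
  }
  f1 <- freq_of(pop1); f2 <- freq_of(pop2)
  p1 <- f1$p; p2 <- f2$p; n1 <- f1$n; n2 <- f2$n
  mono <- !is.na(p1) & !is.na(p2) &
    ((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  val <- if (method == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
      p2 * (1 - p2) / pmax(n2 - 1, 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ifelse(den > 0, num / den, NA_real_)
  } else {
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  }
  val <- pmin(pmax(val, 0), 1)
  val[mono | is.na(p1) | is.na(p2)] <- NA_real_
  dplyr::bind_cols(g$markers[, c("marker_id", "chrom", "pos")],
                   tibble(fst = val))
}

#' Sliding-window means of a per-marker statistic
#'
#' Means of the defined values over `k`-marker windows advanced by `step`
#' markers, never spanning chromosomes. Windows in which more than 20% of
#' markers are undefined are flagged.
#'
#' @param values Tibble with `chrom, pos` and one statistic column (the last
#'   non-coordinate column, or name it via `stat`).
#' @param k Markers per window (default 10).
#' @param step Advance between windows (default 1).
#' @param stat Name of the statistic column.
#' @param max_undef_frac Flagging threshold for the undefined fraction.
#' @return Tibble: `chrom, start_index, end_index, start_pos, end_pos, stat,
#'   value, n_defined, flagged_undef`.
#' @export
sliding_windows <- function(values, k = 10L, step = 1L, stat = NULL,
                            max_undef_frac = 0.2) {
  stopifnot(k >= 1, step >= 1)
  if (is.null(stat)) {
    stat <- setdiff(names(values), c("marker_id", "chrom", "pos"))[1]
  }
  out <- list()
  for (ch in unique(values$chrom)) {
    v <- values[values$chrom == ch, ]
    m <- nrow(v)
    if (m < k) {
      cs_inform("sliding_windows: chromosome ", ch, " has fewer than ", k,
                " markers; no windows emitted")
      next
    }
    starts <- seq(1L, m - k + 1L, by = step)
    x <- v[[stat]]
    win_mean <- vapply(starts, function(s) mean(x[s:(s + k - 1L)], na.rm = TRUE),
                       numeric(1))
    n_def <- vapply(starts, function(s) sum(!is.na(x[s:(s + k - 1L)])),
                    numeric(1))
    win_mean[n_def == 0] <- NA_real_
    out[[length(out) + 1L]] <- tibble(
      chrom = ch, start_index = starts, end_index = starts + k - 1L,
      start_pos = v$pos[starts], end_pos = v$pos[starts + k - 1L],
      stat = stat, value = win_mean, n_defined = as.integer(n_def),
      flagged_undef = (k - n_def) / k > max_undef_frac)
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start_index = integer(),
                  end_index = integer(), start_pos = integer(),
                  end_pos = integer(), stat = character(), value = double(),
                  n_defined = integer(), flagged_undef = logical()))
  }
  bind_rows(out)
}

#' Flag windows in an empirical tail of the genome-wide distribution
#'
#' Percentile ranks are mid-ranks (ties share their average rank) against the
#' genome-wide distribution of the statistic; a window is flagged when its
#' mid-rank, counted from the relevant end, lies within the requested tail
#' fraction. With all values equal nothing is flagged.
#'
#' @param windows A [sliding_windows()] table.
#' @param tail `"low"` or `"high"`.
#' @param frac Tail fraction (e.g. `0.05` for the top/bottom 5%; the study
#'   used the top 5% for F_ST and the lowest 0.2% for the heterozygosity
#'   ratio).
#' @return `windows` with `percentile` (0-100, mid-rank) and `flagged`
#'   columns.
#' @export
percentile_flags <- function(windows, tail = c("high", "low"), frac = 0.05) {
  tail <- match.arg(tail)
  v <- windows$value
  ok <- !is.na(v)
  n <- sum(ok)
  midrank <- rep(NA_real_, length(v))
  midrank[ok] <- rank(v[ok], ties.method = "average")
  pct <- 100 * midrank / n
  from_end <- if (tail == "low") midrank else (n + 1 - midrank)
  flagged <- !is.na(from_end) & from_end <= frac * n
  windows %>% mutate(percentile = pct, flagged = flagged)
}
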