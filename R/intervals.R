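#' Genomic interval records
#'
#' Intervals are 1-based inclusive, both endpoints being marker positions.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive endpoint positions (`start <= end`).
#' @param n_markers Number of markers spanned (optional).
#' @param provenance How the interval was derived, e.g.
#'   `"haplotype_sharing"` or `"breakpoint_refined"`.
#' @return One-row tibble of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, n_markers = NA_integer_,
                             provenance = "manual") {
  if (length(start) == 1 && length(end) == 1 && start > end) {
    abort("interval start must be <= end")
  }
  out <- tibble(chrom = as.character(chrom), start = as.double(start),
                end = as.double(end), n_markers = as.integer(n_markers),
                provenance = provenance)
  class(out) <- c("genomic_interval", class(out))
  out
}

empty_interval <- function() {
  out <- tibble(chrom = character(), start = double(), end = double(),
                n_markers = integer(), provenance = character())
  class(out) <- c("genomic_interval", class(out))
  out
}

#' Interval length in kilobases
#'
#' `(end - start) / 1000`, rounded to `digits` decimal places; with the
#' default `digits = 0` a 8,152,258-8,342,370 interval reports 190 kb, and at
#' one decimal the 8,152,258-8,237,937 interval reports 85.7 kb.
#'
#' @param interval A `genomic_interval`.
#' @param digits Decimal places for rounding.
#' @return Numeric length(s) in kb.
#' @export
interval_length_kb <- function(interval, digits = 0) {
  round((interval$end - interval$start) / 1000, digits)
}

#' Export intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is decremented by one and `end` kept.
#'
#' @param interval A `genomic_interval` tibble.
#' @param path Output BED path.
#' @export
interval_to_bed <- function(interval, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", interval$chrom,
                   as.integer(interval$start) - 1L,
                   as.integer(interval$end), interval$provenance)
  writeLines(lines, path)
  invisible(path)
}
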