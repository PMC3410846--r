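hap_bits <- function(h, m) as.integer(intToBits(h))[seq_len(m)]

test_that("fully homozygous windows are phased exactly with observed frequencies", {
  # 6 individuals, 3 markers, two homozygous haplotypes 000 (x4) and 111 (x2)
  calls <- rbind(matrix(0L, 4, 3), matrix(2L, 2, 3))
  g <- toy_geno(calls)
  haps <- em_phase(g)
  expect_equal(sort(haps$haplotype), c("000", "111"))
  expect_equal(haps$freq[haps$haplotype == "000"], 4 / 6, tolerance = 1e-9)
  expect_equal(haps$freq[haps$haplotype == "111"], 2 / 6, tolerance = 1e-9)
  expect_equal(sum(haps$freq), 1, tolerance = 1e-9)
})

test_that("EM frequencies match the direct maximum-likelihood oracle on small windows", {
  set.seed(41)
  for (m in c(2, 3, 4)) {
    nh <- 2L^m
    ftrue <- rexp(nh) + 0.2; ftrue <- ftrue / sum(ftrue)
    hapmat <- t(sapply(0:(nh - 1L), hap_bits, m = m))
    n <- 40
    h1 <- sample(nh, n, TRUE, prob = ftrue)
    h2 <- sample(nh, n, TRUE, prob = ftrue)
    calls <- hapmat[h1, , drop = FALSE] + hapmat[h2, , drop = FALSE]
    g <- toy_geno(calls)
    em <- em_phase(g, tol = 1e-12, min_freq = 0)
    f_em <- em_freq_vector(em, m)
    f_ml <- hap_ml_oracle(calls)
    expect_lt(max(abs(f_em - f_ml[names(f_em)])), 1e-6)
  }
})

test_that("double-heterozygote mixtures resolve against the analytic anchored solution", {
  # anchored two-locus design: homozygotes pin 00 and 11; double
  # heterozygotes then split between coupling (00/11) and repulsion (01/10)
  calls <- rbind(matrix(0L, 3, 2), matrix(2L, 3, 2),
                 matrix(1L, 4, 2))
  g <- toy_geno(calls)
  em <- em_phase(g, tol = 1e-12, min_freq = 0)
  f_em <- em_freq_vector(em, 2)
  f_ml <- hap_ml_oracle(calls)
  expect_lt(max(abs(f_em - f_ml[names(f_em)])), 1e-6)
  expect_equal(sum(em$freq), 1, tolerance = 1e-9)
  # window-size cap
  wide <- toy_geno(matrix(0L, 2, 13))
  expect_error(em_phase(wide), "split the window")
  # per-breed frequencies each sum to one
  g2 <- toy_geno(rbind(matrix(0L, 4, 2), matrix(2L, 4, 2)),
                 breeds = rep(c("x", "y"), each = 4))
  h2 <- em_phase(g2)
  sums <- as.numeric(tapply(h2$freq, h2$breed, sum))
  expect_equal(sums, c(1, 1), tolerance = 1e-9)
})

make_haps <- function(hap_list, markers = NULL) {
  m <- nchar(hap_list[[1]][1])
  out <- purrr::imap_dfr(hap_list, function(h, br)
    tibble::tibble(breed = br, haplotype = h,
                   freq = rep(1 / length(h), length(h)),
                   n_chromosomes = 10L))
  attr(out, "markers") <- markers %||%
    tibble::tibble(marker_id = paste0("m", 1:m), chrom = "32",
                   pos = 1000L * (1:m))
  class(out) <- c("phased_haplotypes", class(out))
  out
}

test_that("haplotype sharing yields the maximal identical run, leftmost on ties", {
  # all identical: full map
  h <- make_haps(list(a = "0101010101", b = "0101010101"))
  iv <- shared_interval(h, c("a", "b"), min_freq = 0)
  expect_equal(iv$start, 1000)
  expect_equal(iv$end, 10000)
  expect_equal(iv$n_markers, 10L)
  # disagreement at markers 3 and 9 of 12: shared run is markers 4-8
  base <- strsplit("000000000000", "")[[1]]
  alt <- base; alt[3] <- "1"; alt[9] <- "1"
  h2 <- make_haps(list(a = paste(base, collapse = ""),
                       b = paste(alt, collapse = "")))
  iv2 <- shared_interval(h2, c("a", "b"), min_freq = 0)
  expect_equal(iv2$start, 4000)
  expect_equal(iv2$end, 8000)
  expect_equal(iv2$n_markers, 5L)
  # leftmost maximal run on ties: disagreement at marker 5 of 9 gives two
  # 4-runs; the left one wins
  alt3 <- strsplit("000000000", "")[[1]]; alt3[5] <- "1"
  h3 <- make_haps(list(a = "000000000", b = paste(alt3, collapse = "")))
  iv3 <- shared_interval(h3, c("a", "b"), min_freq = 0)
  expect_equal(c(iv3$start, iv3$end), c(1000, 4000))
  # no shared marker: empty interval, with a message
  h4 <- make_haps(list(a = "00", b = "11"))
  expect_message(iv4 <- shared_interval(h4, c("a", "b"), min_freq = 0),
                 "empty interval")
  expect_equal(nrow(iv4), 0L)
  # a breed with no qualifying haplotype is an error naming it
  h5 <- make_haps(list(a = "00", b = "00"))
  expect_error(shared_interval(h5, c("a", "b", "c"), min_freq = 0), "c")
})

test_that("adding a haplotype never lengthens the shared interval", {
  set.seed(44)
  m <- 12
  for (rep in 1:20) {
    pool <- replicate(4, paste(sample(0:1, m, TRUE), collapse = ""))
    h_small <- make_haps(list(a = pool[1], b = pool[2]))
    h_big <- make_haps(list(a = pool[1], b = pool[2], c = pool[3]))
    len <- function(iv) if (nrow(iv) == 0) -1 else iv$n_markers
    iv_s <- suppressMessages(shared_interval(h_small, c("a", "b"), min_freq = 0))
    iv_b <- suppressMessages(shared_interval(h_big, c("a", "b", "c"), min_freq = 0))
    expect_lte(len(iv_b), len(iv_s))
  }
})

test_that("breakpoint refinement truncates at the last agreement before the first conflict", {
  iv <- genomic_interval("32", 1000, 9000, provenance = "haplotype_sharing")
  pos <- seq(1000L, 9000L, by = 1000L)
  a <- tibble::tibble(pos = pos, gt = c(0L, 1L, 2L, 0L, 0L, 1L, 2L, 0L, 1L))
  # no disagreement: unchanged apart from provenance
  out0 <- refine_breakpoint(a, a, iv)
  expect_equal(c(out0$start, out0$end), c(1000, 9000))
  expect_equal(out0$provenance, "breakpoint_refined")
  # first disagreement at 6000: end at 5000
  b <- a; b$gt[b$pos == 6000] <- 2L; b$gt[b$pos == 8000] <- 1L
  out1 <- refine_breakpoint(a, b, iv)
  expect_equal(out1$end, 5000)
  expect_equal(out1$n_markers, 5L)
  # heterozygous vs homozygous is a disagreement
  c1 <- a; c1$gt[c1$pos == 3000] <- 1L
  expect_equal(refine_breakpoint(a, c1, iv)$end, 2000)
  # a missing call is skipped, not a disagreement
  d <- b; d$gt[d$pos == 6000] <- NA
  out2 <- refine_breakpoint(a, d, iv)
  expect_equal(out2$end, 7000)
  # disagreement at the very first informative position: empty, with message
  e <- a; e$gt[1] <- 2L
  expect_message(out3 <- refine_breakpoint(a, e, iv), "empty interval")
  expect_equal(nrow(out3), 0L)
  # refined interval is always inside the input interval
  expect_gte(out1$start, iv$start)
  expect_lte(out1$end, iv$end)
})

test_that("panel tabulation reports per-marker support for the interval haplotype", {
  # 4 dogs at one marker, dosage of the non-expected allele: 0,0,1,1
  # -> 6 of 8 chromosomes consistent
  panel <- toy_geno(matrix(c(0L, 0L, 1L, 1L), 4, 1), pos = 8237937L,
                    chrom = "32")
  rep1 <- confirm_breakpoint(panel)
  expect_equal(rep1$fraction_consistent, 0.75)
  expect_equal(attr(rep1, "overall"), 0.75)
  expect_equal(rep1$pos, 8237937L)   # marker positions pass through verbatim
  # all homozygous for the shared allele
  panel2 <- toy_geno(matrix(0L, 8, 3), chrom = "32",
                     pos = c(8196098L, 8237937L, 8296162L))
  rep2 <- confirm_breakpoint(panel2)
  expect_equal(rep2$fraction_consistent, rep(1, 3))
  expect_error(confirm_breakpoint(panel2, marker_ids = "nope"), "nope")
})

test_that("interval arithmetic reproduces the published lengths", {
  shared <- genomic_interval("32", 8152258, 8342370,
                             provenance = "haplotype_sharing")
  expect_equal(interval_length_kb(shared), 190)
  refined <- genomic_interval("32", 8152258, 8237937,
                              provenance = "breakpoint_refined")
  expect_equal(interval_length_kb(refined, digits = 1), 85.7)
  expect_error(genomic_interval("32", 10, 5), "start")
  # BED export converts 1-based inclusive to 0-based half-open
  path <- file.path(withr::local_tempdir(), "iv.bed")
  interval_to_bed(shared, path)
  expect_equal(readLines(path), "32\t8152257\t8342370\thaplotype_sharing")
})
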