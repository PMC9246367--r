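# Site-pattern statistics: D3, D4, the rate ratio, FST partitioning.

test_that("taxon frequencies collapse dosage columns correctly", {
  g <- tibble::tibble(chrom = "c", pos = c(1, 2),
                      s1 = c(1, NA), s2 = c(2, NA), o = c(0, 2))
  f <- site_frequencies(g, list(p1 = c("s1", "s2"), o1 = "o"))
  expect_equal(f$p1, c(0.75, NA))
  expect_equal(f$o1, c(0, 1))
  expect_error(site_frequencies(g, list(p1 = "nope")), "absent")
})

test_that("D3 and D4 reproduce direct arithmetic", {
  counts <- tibble::tibble(block = c("a", "b"), n_sites = c(4L, 4L),
                           abb = c(1, 2), bab = c(3, 2),
                           abba = c(10, 15), baba = c(40, 35),
                           rr_num = 0, rr_den = 0)
  expect_equal(suppressWarnings(d3(counts)$estimate), (3 - 5) / (3 + 5))
  expect_equal(suppressWarnings(d4(counts)$estimate), (25 - 75) / (25 + 75))
  sym <- dplyr::mutate(counts, bab = abb, baba = abba)
  expect_equal(suppressWarnings(d3(sym)$estimate), 0)
  expect_equal(suppressWarnings(d4(sym)$estimate), 0)
})

test_that("pattern sums are polarized by the fixed outgroup allele", {
  # o1 fixed ancestral (0): ABB = p1 (1 - p2)
  s <- freq_sites(p1 = c(0.5, 0.25), p2 = c(0, 0.25), o1 = c(0, 0))
  counts <- site_pattern_counts(s)
  expect_equal(counts$abb, 0.5 * 1 + 0.25 * 0.75)
  expect_equal(counts$bab, 0 + 0.75 * 0.25)
  # o1 fixed for the alternate allele: polarity flips
  s2 <- freq_sites(p1 = 0.5, p2 = 1, o1 = 1)
  c2 <- site_pattern_counts(s2)
  expect_equal(c2$abb, 0.5 * 1)   # derived rel. o1 is the reference allele
  expect_equal(c2$bab, 0)
  # polymorphic outgroup sites are excluded
  s3 <- freq_sites(p1 = 0.5, p2 = 0, o1 = 0.5)
  c3 <- site_pattern_counts(s3)
  expect_equal(c3$abb + c3$bab, 0)
})

test_that("swapping the focal taxa negates D3/D4 and inverts r", {
  set.seed(41)
  s <- freq_sites(p1 = runif(50), p2 = runif(50),
                  o1 = rbinom(50, 1, 0.5), o2 = rbinom(50, 1, 0.5))
  sw <- dplyr::rename(s, p1 = p2, p2 = p1)
  a <- site_pattern_counts(s)
  b <- site_pattern_counts(sw)
  suppressWarnings({
    expect_equal(d3(b)$estimate, -d3(a)$estimate, tolerance = 1e-12)
    expect_equal(d4(b)$estimate, -d4(a)$estimate, tolerance = 1e-12)
    expect_equal(rate_ratio(b)$estimate, 1 / rate_ratio(a)$estimate,
                 tolerance = 1e-12)
  })
})

test_that("the rate ratio evaluates the frequency form of single draws", {
  s <- freq_sites(p1 = c(0.5, 0), p2 = c(0, 1), o1 = c(0, 0), o2 = c(0, 0))
  expect_equal(suppressWarnings(rate_ratio(s)$estimate), 0.5 / 1)
  # sites where outgroups disagree are excluded from the rate-ratio sums
  s2 <- freq_sites(p1 = c(0.5, 0.9), p2 = c(0, 0), o1 = c(0, 0),
                   o2 = c(0, 1))
  counts <- site_pattern_counts(s2)
  expect_equal(counts$rr_num, 0.5)
  # zero pooled denominator is flagged
  s3 <- freq_sites(p1 = 0.5, p2 = 0, o1 = 0, o2 = 0)
  expect_warning(res <- rate_ratio(s3), "denominator")
  expect_true(is.na(res$estimate))
})

test_that("pattern sums are block-additive", {
  set.seed(43)
  s <- freq_sites(p1 = runif(200), p2 = runif(200),
                  o1 = rbinom(200, 1, 0.7), o2 = rbinom(200, 1, 0.7),
                  pos = sort(sample.int(5e6, 200)))
  fine <- site_pattern_counts(s, block_size = 1e6)
  coarse <- site_pattern_counts(s, block_size = 5e6)
  for (col in c("abb", "bab", "abba", "baba", "rr_num", "rr_den")) {
    expect_equal(sum(fine[[col]]), sum(coarse[[col]]), tolerance = 1e-12)
  }
  expect_equal(sum(fine$n_sites), 200L)
  # statistics from pooled blocks equal statistics from summed counts
  expect_equal(suppressWarnings(d3(fine)$estimate),
               suppressWarnings(d3(coarse)$estimate), tolerance = 1e-12)
})

test_that("sampled-allele mode approximates the frequency form", {
  set.seed(47)
  s <- freq_sites(p1 = runif(4000), p2 = runif(4000),
                  o1 = rbinom(4000, 1, 0.6),
                  pos = sort(sample.int(1e6, 4000)))
  freq <- suppressWarnings(d3(site_pattern_counts(s)))
  samp <- suppressWarnings(d3(site_pattern_counts(s, mode = "sample",
                                                  seed = 2)))
  expect_lt(abs(freq$estimate - samp$estimate), 0.05)
  expect_error(site_pattern_counts(s, mode = "sample"), "seed")
})

test_that("background FST is the mean of covering sliding windows", {
  ws <- tibble::tibble(chrom = "chr1",
                       start = c(0, 10, 20), end = c(20, 30, 40),
                       fst = c(0.2, 0.4, 0.9))
  sites <- tibble::tibble(chrom = "chr1", pos = c(5, 15, 25, 100))
  expect_warning(res <- assign_background_fst(sites, ws), "outside")
  # brute force over all windows
  brute <- vapply(sites$pos, function(p) {
    inw <- ws$fst[ws$start <= p & p < ws$end]
    if (length(inw)) mean(inw) else NA_real_
  }, 0)
  expect_equal(res$bg_fst, brute)
  res_max <- suppressWarnings(
    assign_background_fst(sites, ws, summary = "max"))
  expect_equal(res_max$bg_fst[2], 0.4)
})

test_that("threshold partitions are cumulative and monotone", {
  ws <- tibble::tibble(chrom = "chr1", start = 0, end = 100, fst = 0.3)
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 50), p1 = 1, p2 = 0,
                          o1 = 0)
  parts <- partition_by_fst(sites, ws, thresholds = c(0, 0.2, 0.4))
  expect_equal(parts$n_sites, c(2L, 2L, 0L))    # kept at 0.2, dropped at 0.4
  expect_true(all(diff(parts$n_sites) <= 0))
  ws$fst <- 0.35
  bins <- partition_by_fst(sites, ws, mode = "bins", n_bins = 10)
  expect_equal(sum(bins$n_sites), 2L)           # each site assigned once
  expect_equal(bins$n_sites[4], 2L)             # fst 0.35 -> bin [0.3, 0.4)
})
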