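# Seeded generators: reproducibility and agreement with coalescent theory.

test_that("generators are bit-reproducible given a seed", {
  a <- simulate_im_pair(200, N = 50, m = 0.02, mu1 = 1, mu2 = 2, seed = 5)
  b <- simulate_im_pair(200, N = 50, m = 0.02, mu1 = 1, mu2 = 2, seed = 5)
  expect_identical(a, b)
  c <- simulate_im_pair(200, N = 50, m = 0.02, mu1 = 1, mu2 = 2, seed = 6)
  expect_false(identical(a$t_coal, c$t_coal))
  expect_error(simulate_im_pair(10, 50, 0.02, 1, 2),
               "argument \"seed\" is missing")
  l1 <- simulate_im_landscape(tibble::tibble(nm = 1, n_windows = 2),
                              n_dip = 2, seed = 9)
  l2 <- simulate_im_landscape(tibble::tibble(nm = 1, n_windows = 2),
                              n_dip = 2, seed = 9)
  expect_identical(l1$genotypes, l2$genotypes)
})

test_that("pair simulation matches sojourn and rate-ratio theory", {
  N <- 100
  m <- 0.0025    # 4Nm = 1, FST = 0.5
  sim <- simulate_im_pair(4e4, N, m, mu1 = 1, mu2 = 2, seed = 101)
  # symmetric-rate control: pooled ratio near 1
  sym <- simulate_im_pair(4e4, N, m, mu1 = 1.3, mu2 = 1.3, seed = 102)
  rr <- im_pair_ratio(sym)
  expect_lt(abs(rr$estimate - 1), 3 * rr$se)
  # r0 = 2 at FST 0.5: ratio near 1.4
  rr2 <- im_pair_ratio(sim)
  expect_lt(abs(rr2$estimate - r_from_fst(0.5, 2)), 3 * rr2$se)
  # mean pairwise sojourn matches the closed forms
  s <- im_sojourn(N, m)
  tot <- sim$s1_d1 + sim$s1_d2 + sim$s2_d1 + sim$s2_d2
  se_tot <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 2 * (s$s11 + s$s21)), 3 * se_tot)
  # lineage sojourns match S11 / S21 individually
  se1 <- sd(sim$s1_d1) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$s1_d1) - s$s11), 3 * se1)
  se2 <- sd(sim$s1_d2) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$s1_d2) - s$s21), 3 * se2)
})

test_that("pair-simulation FST converges to the equilibrium value", {
  N <- 100
  m <- 0.0025
  between <- simulate_im_pair(4e4, N, m, 1, 1, seed = 103)
  within <- simulate_im_pair(4e4, N, m, 1, 1, sampling = "within",
                             seed = 104)
  fst <- im_pair_fst(between, within)
  expect_lt(abs(fst$estimate - 0.5), 3 * fst$se)
})

test_that("landscape windows center on their equilibrium FST", {
  land <- simulate_im_landscape(tibble::tibble(nm = 0.5, n_windows = 25),
                                N = 50, n_dip = 4, seed = 31)
  pa <- paste0("p1_", 1:4)
  pb <- paste0("p2_", 1:4)
  res <- windowed_stats(land$genotypes, pa, pb,
                        land$windows[c("chrom", "start", "end")])
  expect_lt(abs(mean(res$fst, na.rm = TRUE) - 1 / 3),
            3 * sd(res$fst, na.rm = TRUE) / sqrt(sum(!is.na(res$fst))))
  expect_gt(mean(res$n_sites), 0)
  expect_equal(unique(land$windows$fst_expected), 1 / 3)
})

test_that("landscape recurrent mutations bias D3 and D4 as predicted", {
  land <- simulate_im_landscape(
    tibble::tibble(nm = 0.25, n_windows = 40), N = 50, n_dip = 4,
    mu1 = 0.2, mu2 = 0.2 * 2, p_recur = c(0.05, 0.15), conversion = 1,
    seed = 33)
  sites <- site_frequencies(
    land$genotypes,
    list(p1 = paste0("p2_", 1:4), p2 = paste0("p1_", 1:4),
         o1 = "o1", o2 = "o2"))
  counts <- site_pattern_counts(sites)
  # faster first taxon: more derived alleles exclusive to it -> D3 > 0 in
  # this orientation; recurrent O2 mutations with p2 > p1 push D4 the same
  # sign as the true D3 asymmetry
  expect_gt(d3(counts)$estimate, 0)
  expect_gt(d4(counts)$estimate, 0)
  # flip orientation to the slower-first convention used in the field:
  swapped <- dplyr::rename(sites, p1 = p2, p2 = p1)
  expect_lt(d4(site_pattern_counts(swapped))$estimate, 0)
})

test_that("the two-deme stepping stone matches the pair engine's moments", {
  N <- 80
  m <- 0.005
  ss <- simulate_stepping_stone(3e4, n_demes = 2, split = 1, N = N,
                                m_within = m, mu1 = 1, mu2 = 2, seed = 51)
  im <- simulate_im_pair(3e4, N, m, 1, 2, seed = 52)
  t_se <- sqrt(var(ss$t_coal) / nrow(ss) + var(im$t_coal) / nrow(im))
  expect_lt(abs(mean(ss$t_coal) - mean(im$t_coal)), 3 * t_se)
  r_ss <- mean(ss$n2) / mean(ss$n1)
  r_im <- im_pair_ratio(im)
  expect_lt(abs(r_ss - r_im$estimate), 4 * r_im$se)
})

test_that("a symmetric stepping stone with equal rates gives r near 1", {
  ss <- simulate_stepping_stone(2e4, n_demes = 6, N = 50, m_within = 0.02,
                                mu1 = 1, mu2 = 1, seed = 53)
  m1 <- mean(ss$n1)
  m2 <- mean(ss$n2)
  se <- (m2 / m1) * sqrt(var(ss$n1) / (nrow(ss) * m1^2) +
                           var(ss$n2) / (nrow(ss) * m2^2))
  expect_lt(abs(m2 / m1 - 1), 3 * se)
})

test_that("within-species structure depresses apparent rate divergence", {
  # strong internal structure, permeable species boundary: FST is inflated
  # relative to the surviving rate divergence (r-1)/(r0-1)
  n <- 3e4
  r0 <- 2
  ss <- simulate_stepping_stone(n, n_demes = 6, split = 3, N = 30,
                                m_within = 0.002, m_between = 0.05,
                                mu1 = 1, mu2 = r0,
                                sample_demes = c(1, 6), seed = 55)
  w1 <- simulate_stepping_stone(n, n_demes = 6, split = 3, N = 30,
                                m_within = 0.002, m_between = 0.05,
                                mu1 = 1, mu2 = r0,
                                sample_demes = c(1, 1), seed = 56)
  w2 <- simulate_stepping_stone(n, n_demes = 6, split = 3, N = 30,
                                m_within = 0.002, m_between = 0.05,
                                mu1 = 1, mu2 = r0,
                                sample_demes = c(6, 6), seed = 57)
  fst <- 1 - mean(c(w1$t_coal, w2$t_coal)) / mean(ss$t_coal)
  r_obs <- mean(ss$n2) / mean(ss$n1)
  expect_lt((r_obs - 1) / (r0 - 1), fst)
  expect_error(simulate_stepping_stone(10, 2, N = 10, m_within = 0,
                                       mu1 = 1, mu2 = 1, seed = 1),
               "connected")
})

test_that("recurrent-mutation pattern simulation matches expectation", {
  # no recurrent mutation: counts unchanged
  sp0 <- simulate_site_patterns(500, 300, p1 = 0, conversion = 0.5,
                                seed = 61)
  expect_equal(sum(sp0$abb), 500)
  expect_equal(sum(sp0$bab), 300)
  expect_equal(sum(sp0$abba) + sum(sp0$baba), 0)
  # symmetric counts stay symmetric in expectation
  reps <- vapply(1:100, function(i) {
    sp <- simulate_site_patterns(3000, 3000, p1 = 0.1, conversion = 0.6,
                                 seed = 1000 + i)
    suppressWarnings(d3(sp)$estimate)
  }, 0)
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("simulated D3 converges to the exact recurrent-mutation value", {
  truth <- d3_observed(-0.2, 0.1, 0.5)
  reps <- vapply(1:200, function(i) {
    sp <- simulate_site_patterns(4000, 6000, p1 = 0.1, conversion = 0.5,
                                 seed = 2000 + i)
    d3(sp)$estimate
  }, 0)
  expect_lt(abs(mean(reps) - truth), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("block-ancestry cohorts span the two entropy regimes", {
  # fully linked, pure ancestry: constant signals, zero entropy
  for (q in c(0, 1)) {
    sim <- simulate_block_ancestry(200, break_prob = 0, q = q, n_ind = 4,
                                   seed = 71)
    d <- sim$dosage[[1]]
    expect_true(all(d == q))
    expect_equal(within_entropy(d[, 1])$sw, 0)
    expect_equal(between_entropy(d)$sb, 0, tolerance = 1e-9)
  }
  # independent markers at q = 1/2: both entropies far above the linked
  # regime (the phasor's nonzero mean keeps a DC component, so the exact
  # ceilings ln(M/2) and ln J are not reachable by i.i.d. dosage signals)
  iid <- simulate_block_ancestry(1000, break_prob = 1, q = 0.5, n_ind = 6,
                                 seed = 72)$dosage[[1]]
  linked <- simulate_block_ancestry(1000, break_prob = 0.005, q = 0.5,
                                    n_ind = 6, seed = 73)$dosage[[1]]
  expect_gt(within_entropy(iid[, 1])$sw, 2 * within_entropy(linked[, 1])$sw)
  expect_gt(between_entropy(iid)$sb, between_entropy(linked)$sb)
  expect_gt(between_entropy(iid)$sb, 0.4 * log(6))
  expect_true(all(iid %in% c(0, 0.5, 1)))
  expect_error(simulate_block_ancestry(1, 0.5, 0.5, seed = 1), "n_snps")
})
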