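# Closed-form theory: equilibrium FST, the coalescent generator, sojourn
# times, the r-FST curve, recurrent-mutation corrections, r0 fitting.

test_that("equilibrium FST follows 1/(1+4Nm) and inverts cleanly", {
  expect_equal(fst_equilibrium(100, 0.01), 0.2)
  expect_lt(fst_equilibrium(1e6, 1), 1e-6)            # Nm -> Inf: FST -> 0
  for (N in c(10, 100, 1000)) {
    for (m in c(1e-4, 1e-2, 0.3)) {
      expect_equal(m_from_fst(fst_equilibrium(N, m), N), m,
                   tolerance = 1e-12)
    }
  }
  expect_error(fst_equilibrium(-1, 0.1), "positive")
  expect_error(m_from_fst(1.2, 10), "fst")
})

test_that("the two-lineage generator conserves probability", {
  A <- im_rate_matrix(37, 0.013)
  expect_equal(colSums(A), rep(0, 6), ignore_attr = TRUE,
               tolerance = 1e-14)
  # migration entries vanish as m -> 0 (coalescence-only dynamics)
  A0 <- im_rate_matrix(37, 1e-300)
  off <- A0
  diag(off) <- 0
  expect_equal(sum(abs(off[1:2, ])), 0, tolerance = 1e-290)
  expect_equal(A0[5, 3], 1 / 37)
})

test_that("transition density matches I + At at small t", {
  A <- im_rate_matrix(50, 0.02)
  for (t in c(1e-3, 1e-4)) {
    P <- expm_eigen(A * t)
    err <- max(abs(P - diag(6) - A * t))
    expect_lt(err, 4 * max(abs(A))^2 * t^2)   # O(t^2) remainder
  }
})

test_that("numeric sojourn routes agree with the closed forms", {
  cl <- im_sojourn(100, 0.01)
  expect_equal(cl$s11, 150)
  expect_equal(cl$s21, 100)
  expect_equal(cl$s11, cl$s22)   # deme symmetry
  expect_equal(cl$s12, cl$s21)
  for (N in c(20, 200)) {
    for (m in c(0.001, 0.05)) {
      closed <- im_sojourn(N, m)
      lin <- im_sojourn(N, m, "linear")
      quad <- im_sojourn(N, m, "quadrature")
      expect_equal(lin$s11, closed$s11, tolerance = 1e-10)
      expect_equal(lin$s21, closed$s21, tolerance = 1e-10)
      expect_equal(quad$s11, closed$s11, tolerance = 1e-6)
      expect_equal(quad$s21, closed$s21, tolerance = 1e-6)
    }
  }
  # m -> large: sojourn difference s11 - s21 = 1/(2m) -> 0
  big <- im_sojourn(10, 50)
  expect_equal(big$s11 - big$s21, 1 / (2 * 50), tolerance = 1e-12)
})

test_that("the r-FST curve has the right limits and symmetries", {
  expect_equal(r_from_fst(0, 3.2), 1)                  # full mixing
  expect_equal(r_from_fst(c(0.1, 0.6, 1), 1), c(1, 1, 1))
  expect_equal(r_from_fst(1, 2.7), 2.7)                # complete isolation
  expect_equal(r_from_fst(0.5, 2), 1.4)
  # reported genome-wide setting: r0 = 1.837 at the sex-chromosome FST 0.78
  expect_equal(r_from_fst(0.78, 1.837), 1.598, tolerance = 1e-3)
  fst <- seq(0, 1, 0.05)
  expect_true(all(diff(r_from_fst(fst, 1.5)) > 0))     # increasing, r0 > 1
  expect_true(all(diff(r_from_fst(fst, 0.6)) < 0))     # decreasing, r0 < 1
  # swapping lineage labels inverts the ratio
  for (r0 in c(0.3, 1.837, 6)) {
    expect_equal(r_from_fst(fst, r0) * r_from_fst(fst, 1 / r0),
                 rep(1, length(fst)), tolerance = 1e-12)
  }
})

test_that("linearized FST approximation tightens as r0 -> 1", {
  fst <- seq(0.05, 0.95, 0.1)
  for (r0 in c(1.5, 1.1, 1.01)) {
    err <- abs(fst_linear_approx(r_from_fst(fst, r0), r0) - fst)
    # remainder is O((r0 - 1) * fst * (1 - fst))
    expect_true(all(err <= 1.1 * (r0 - 1) * fst * (1 - fst) + 1e-12))
  }
})

test_that("sojourn assembly reproduces the r-FST curve on a grid", {
  for (N in c(25, 400)) {
    for (m in c(0.002, 0.08)) {
      for (r0 in c(0.5, 1, 1.837)) {
        s <- im_sojourn(N, m)
        mu1 <- 1
        mu2 <- r0
        r_sojourn <- (mu2 * s$s22 + mu1 * s$s12) /
          (mu1 * s$s11 + mu2 * s$s21)
        expect_equal(r_sojourn, r_from_fst(fst_equilibrium(N, m), r0),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("recurrent-mutation corrections evaluate exactly", {
  expect_equal(d3_observed(-0.37, 0, 0.4), -0.37)       # no recurrent mutation
  expect_equal(d3_observed(-0.37, 1, 1), 0.37)          # full conversion flips
  expect_equal(d3_observed(-0.2, 0.1, 0.5), 0.85 / 0.95 * -0.2)
  expect_equal(d3_observed(-0.2, 0.1, 0.5, method = "linear"), -0.18)
  expect_equal(d4_observed(-0.4, 0.2, 0.2), 0)          # equal p: no bias
  expect_equal(d4_observed(-0.2, 0.1, 0.3), -0.1)
  expect_warning(d4_observed(-0.2, 0.3, 0.1), "p2 < p1")
  expect_error(d3_observed(-0.2, 1.5, 0.5), "p1")
})

test_that("r0 fitting recovers noiseless curves exactly", {
  bins <- tibble::tibble(fst = seq(0.05, 0.95, length.out = 10))
  bins$r <- r_from_fst(bins$fst, 1.8)
  fit <- fit_r0(bins, n_boot = 0)
  expect_equal(fit$r0_hat, 1.8, tolerance = 1e-9)
  flat <- tibble::tibble(fst = seq(0.1, 0.9, 0.1), r = 1)
  expect_equal(fit_r0(flat, n_boot = 0)$r0_hat, 1, tolerance = 1e-6)
  expect_error(fit_r0(tibble::tibble(fst = rep(0.4, 5), r = 1.2)),
               "variation")
  expect_error(fit_r0(tibble::tibble(fst = 0.4, r = 1.2)), "2 bins")
})

test_that("r0 fitting is calibrated under bin noise", {
  set.seed(42)
  fst <- seq(0.05, 0.95, length.out = 10)
  hits <- vapply(seq_len(500), function(i) {
    bins <- tibble::tibble(fst = fst,
                           r = r_from_fst(fst, 1.8) + rnorm(10, 0, 0.02))
    abs(fit_r0(bins, n_boot = 0)$r0_hat / 1.8 - 1) < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("tidiers summarize a rate fit", {
  bins <- tibble::tibble(fst = seq(0.1, 0.9, 0.2))
  bins$r <- r_from_fst(bins$fst, 1.4)
  fit <- fit_r0(bins, n_boot = 25, seed = 3)
  td <- tidy(fit)
  expect_true(all(c("fst", "r", "fitted", "resid") %in% names(td)))
  expect_equal(td$resid, td$r - td$fitted)
  gl <- glance(fit)
  expect_equal(gl$n_bins, 5)
  expect_true(is.finite(gl$se))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
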