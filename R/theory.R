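#' Equilibrium relative divergence of the two-deme IM model
#'
#' At migration-drift equilibrium, two haploid populations of size `N`
#' exchanging migrants at per-generation rate `m` have relative divergence
#' \deqn{F_{ST} = \frac{1}{1 + 4Nm}.}
#'
#' @param N Haploid population size (positive; one value or a vector).
#' @param m Per-generation, per-lineage migration rate (positive).
#' @return Numeric vector of FST values in (0, 1).
#' @seealso [m_from_fst()] for the algebraic inverse, [r_from_fst()] for the
#'   induced rate-ratio curve.
#' @export
#' @examples
#' fst_equilibrium(N = 100, m = 0.01)  # Nm = 1 -> 0.2
fst_equilibrium <- function(N, m) {
  check_positive(N, "N")
  check_positive(m, "m")
  1 / (1 + 4 * N * m)
}

#' Migration rate implied by an equilibrium FST
#'
#' Inverts [fst_equilibrium()]: `m = (1/fst - 1) / (4N)`.
#'
#' @param fst Relative divergence in (0, 1).
#' @param N Haploid population size.
#' @return Migration rate `m`.
#' @export
m_from_fst <- function(fst, N) {
  if (any(fst <= 0 | fst >= 1)) abort("`fst` must lie strictly in (0, 1).")
  check_positive(N, "N")
  (1 / fst - 1) / (4 * N)
}

#' Generator of the two-lineage structured coalescent
#'
#' Builds the 6x6 rate matrix of the continuous-time Markov chain followed
#' backward in time by two haploid lineages in the symmetric two-deme IM
#' model. States, in order: `(1|2)`, `(2|1)`, `(1,2|)`, `(|1,2)`, `(0|)`,
#' `(|0)` where `1`/`2` are the uncoalesced lineages, `0` the coalesced
#' state, and the bar separates the two demes. Columns are "from" states, so
#' the transition density satisfies dp/dt = A p and each column sums to zero.
#'
#' @inheritParams fst_equilibrium
#' @return A 6x6 numeric matrix with state dimnames.
#' @export
im_rate_matrix <- function(N, m) {
  check_positive(N, "N", scalar = TRUE)
  check_positive(m, "m", scalar = TRUE)
  s <- c("(1|2)", "(2|1)", "(1,2|)", "(|1,2)", "(0|)", "(|0)")
  A <- matrix(0, 6, 6, dimnames = list(s, s))
  A[, 1] <- c(-2 * m, 0, m, m, 0, 0)
  A[, 2] <- c(0, -2 * m, m, m, 0, 0)
  A[, 3] <- c(m, m, -2 * m - 1 / N, 0, 1 / N, 0)
  A[, 4] <- c(m, m, 0, -2 * m - 1 / N, 0, 1 / N)
  A[, 5] <- c(0, 0, 0, 0, -m, m)
  A[, 6] <- c(0, 0, 0, 0, m, -m)
  A
}

#' Expected sojourn times before coalescence in the IM model
#'
#' For a pair of lineages sampled one per deme, `S[i|j]` is the expected
#' total time the lineage sampled in deme `j` spends in deme `i` before the
#' pair coalesces. Closed forms: `S[1|1] = S[2|2] = (1 + 2Nm) / (2m)` and
#' `S[2|1] = S[1|2] = N`. Two independent numeric routes are provided as
#' cross-checks of the closed forms: a linear solve for the expected
#' occupancy of the transient states, and adaptive quadrature of the
#' (spectrally evaluated) matrix exponential of [im_rate_matrix()] under an
#' exponential change of variable that absorbs the infinite horizon.
#'
#' @inheritParams fst_equilibrium
#' @param method `"closed"` (default), `"linear"` or `"quadrature"`.
#' @param tol Relative tail/quadrature tolerance for `method = "quadrature"`
#'   (default `1e-8`).
#' @return A one-row tibble with columns `s11`, `s22`, `s12`, `s21`,
#'   `method`.
#' @export
#' @examples
#' im_sojourn(100, 0.01)                      # s11 = 150, s21 = 100
#' im_sojourn(100, 0.01, method = "linear")   # same, numerically
im_sojourn <- function(N, m, method = c("closed", "linear", "quadrature"),
                       tol = 1e-8) {
  method <- match.arg(method)
  check_positive(N, "N", scalar = TRUE)
  check_positive(m, "m", scalar = TRUE)
  if (method == "closed") {
    s11 <- (1 + 2 * N * m) / (2 * m)
    s21 <- N
  } else if (method == "linear") {
    A <- im_rate_matrix(N, m)
    occ <- unname(solve(-A[1:4, 1:4], c(1, 0, 0, 0)))  # time per transient state
    # lineage 1 (sampled in deme 1) occupies deme 1 in states (1|2), (1,2|)
    s11 <- occ[1] + occ[3]
    s21 <- occ[2] + occ[4]
  } else {
    A <- im_rate_matrix(N, m)
    in1 <- c(1, 0, 1, 0)  # transient states where lineage 1 is in deme 1
    in2 <- c(0, 1, 0, 1)
    # spectral form of the transient matrix exponential: occupancy of the
    # transient states is sum_k c_k exp(lambda_k t), stable at any t
    eg <- eigen(A[1:4, 1:4])
    coef <- solve(eg$vectors, c(1, 0, 0, 0))
    occ_at <- function(t, w) {
      wv <- as.vector(t(w) %*% eg$vectors) * coef
      vapply(t, function(ti) Re(sum(wv * exp(eg$values * ti))), 0)
    }
    # slowest transient decay rate; substitution u = exp(-lam t) maps the
    # infinite horizon to (0, 1] with a bounded smooth integrand (every
    # transient mode decays at least as fast as lam), so adaptive
    # quadrature needs no tail bound
    lam <- min(abs(Re(eg$values)))
    g <- function(u, w) {
      out <- numeric(length(u))
      pos <- u > 0
      out[pos] <- occ_at(-log(u[pos]) / lam, w) / (lam * u[pos])
      out
    }
    int1 <- stats::integrate(g, 0, 1, w = in1, rel.tol = tol,
                             subdivisions = 1000L)
    int2 <- stats::integrate(g, 0, 1, w = in2, rel.tol = tol,
                             subdivisions = 1000L)
    if (int1$message != "OK" || int2$message != "OK") {
      abort("quadrature for sojourn times did not converge")
    }
    s11 <- int1$value
    s21 <- int2$value
  }
  tibble::tibble(s11 = s11, s22 = s11, s12 = s21, s21 = s21, method = method)
}

#' Observed rate ratio implied by FST under the equilibrium IM model
#'
#' The observed ratio `r` of derived-allele counts exclusive to each lineage
#' relates to relative divergence and the true substitution-rate ratio
#' `r0 = mu2 / mu1` by
#' \deqn{r = \frac{1 + r_0 + F_{ST}(r_0 - 1)}{1 + r_0 - F_{ST}(r_0 - 1)}.}
#' At `FST = 0` rates are fully mixed (`r = 1`); at `FST = 1` lineages evolve
#' independently (`r = r0`).
#'
#' @param fst Relative divergence in \[0, 1\] (vectorized).
#' @param r0 True substitution-rate ratio (positive scalar or vector).
#' @return Numeric vector of observed rate ratios.
#' @seealso [fst_linear_approx()] for the small-`(r0 - 1)` approximation.
#' @export
#' @examples
#' r_from_fst(0.5, r0 = 2)      # 1.4
#' r_from_fst(0.78, r0 = 1.837)
r_from_fst <- function(fst, r0) {
  if (any(fst < 0 | fst > 1)) abort("`fst` must lie in [0, 1].")
  check_positive(r0, "r0")
  (1 + r0 + fst * (r0 - 1)) / (1 + r0 - fst * (r0 - 1))
}

#' Linearized FST implied by an observed rate ratio
#'
#' When `r0` is close to 1 the rate-ratio curve linearizes to
#' `FST ~ (r - 1) / (r0 - 1)`: the surviving fraction of rate divergence
#' equals the fraction of variance explained by population structure.
#'
#' @param r Observed rate ratio.
#' @param r0 True rate ratio (must not equal 1).
#' @return Approximate FST.
#' @export
fst_linear_approx <- function(r, r0) {
  if (any(r0 == 1)) abort("linear approximation undefined at r0 = 1")
  (r - 1) / (r0 - 1)
}

#' Expected D3 under recurrent mutation in the outgroup
#'
#' With true (recurrent-mutation-free) asymmetry `d3_true`, a per-site
#' probability `p1` of recurrent mutation in the outgroup and conversion
#' probability `c` to the focal derived allele, the expected observed
#' three-taxon statistic is
#' \deqn{D_3 = \hat D_3 \, \frac{1 - (c + 1) p_1}{1 + (c - 1) p_1}
#'   \approx (1 - 2 c p_1) \hat D_3.}
#'
#' @param d3_true True D3 (typically in \[-1, 0\] when the second focal
#'   lineage evolves faster).
#' @param p1 Recurrent-mutation probability per site in the outgroup, in
#'   \[0, 1\].
#' @param conversion Probability `c` that a recurrent mutation re-creates the
#'   focal derived allele, in \[0, 1\].
#' @param method `"exact"` (default) or `"linear"` for the small-`p1`
#'   approximation.
#' @return Expected observed D3 (vectorized over any argument).
#' @export
d3_observed <- function(d3_true, p1, conversion,
                        method = c("exact", "linear")) {
  method <- match.arg(method)
  check_prob(p1, "p1")
  check_prob(conversion, "conversion")
  if (method == "exact") {
    d3_true * (1 - (conversion + 1) * p1) / (1 + (conversion - 1) * p1)
  } else {
    d3_true * (1 - 2 * conversion * p1)
  }
}

#' Expected D4 under recurrent mutation in two outgroups
#'
#' Without gene flow, the four-taxon (ABBA-BABA) statistic is driven purely
#' by recurrent mutations converting outgroup alleles, giving
#' \deqn{D_4 = \hat D_3 \, \frac{p_2 - p_1}{p_2 + p_1}.}
#' A more distant second outgroup (`p2 > p1`) together with a negative true
#' `d3_true` yields a spuriously negative D4 - a false positive for the
#' ABBA-BABA introgression test.
#'
#' @inheritParams d3_observed
#' @param p2 Recurrent-mutation probability in the more distant outgroup.
#'   Expected to satisfy `p2 >= p1`; a warning (not an error) is raised
#'   otherwise.
#' @return Expected observed D4.
#' @export
d4_observed <- function(d3_true, p1, p2) {
  check_prob(p1, "p1")
  check_prob(p2, "p2")
  if (any(p1 + p2 <= 0)) abort("`p1 + p2` must be positive.")
  if (any(p2 < p1)) {
    warn("`p2 < p1`: recurrent mutation usually increases with outgroup distance.")
  }
  d3_true * (p2 - p1) / (p2 + p1)
}

#' Fit the true rate ratio r0 to binned (FST, r) observations
#'
#' Weighted least squares of observed per-bin rate ratios against the
#' equilibrium curve [r_from_fst()], profiled over the single parameter
#' `r0`. The normal equation is solved by root-finding on the gradient
#' (the curve is monotone in `r0`), with a golden-section fallback; the
#' standard error comes from a bootstrap over bins.
#'
#' @param bins Data frame with columns `fst`, `r` and optionally `se`
#'   (per-bin jackknife SE of `r`). Weights are `1/se^2`. Bins with missing
#'   or zero `se` (typically sparse partitions whose sites fall in a single
#'   jackknife block) carry no usable precision estimate and are excluded
#'   from a weighted fit, with a warning; if no bin has a finite SE the fit
#'   is unweighted over all bins.
#' @param bounds Search interval for `r0` (default `c(0.1, 10)`).
#' @param n_boot Bootstrap replicates over bins for the SE of `r0_hat`
#'   (default 200; set 0 to skip).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `rate_fit`: a list with elements `r0_hat`,
#'   `se`, `bins` (input plus `fitted` and `resid` columns), `rss`,
#'   `n_bins`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' bins <- tibble::tibble(fst = seq(0.05, 0.95, length.out = 10))
#' bins$r <- r_from_fst(bins$fst, r0 = 1.8)
#' fit_r0(bins)$r0_hat  # 1.8
fit_r0 <- function(bins, bounds = c(0.1, 10), n_boot = 200, seed = NULL) {
  bins <- tibble::as_tibble(bins)
  if (!all(c("fst", "r") %in% names(bins))) {
    abort("`bins` needs columns `fst` and `r`.")
  }
  ok <- is.finite(bins$fst) & is.finite(bins$r)
  bins <- bins[ok, , drop = FALSE]
  w <- fit_weights(bins)
  bins <- bins[w > 0, , drop = FALSE]
  w <- w[w > 0]
  if (nrow(bins) < 2) abort("need at least 2 bins with finite `fst` and `r`.")
  if (length(unique(bins$fst)) < 2) {
    abort("no variation in `fst` across bins: r0 is not identifiable.")
  }

  r0_hat <- solve_r0(bins$fst, bins$r, w, bounds)
  fitted <- r_from_fst(bins$fst, r0_hat)
  bins$fitted <- fitted
  bins$resid <- bins$r - fitted

  se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_seed(old), add = TRUE)
      set.seed(seed)
    }
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(bins), replace = TRUE)
      if (length(unique(bins$fst[idx])) < 2) return(NA_real_)
      solve_r0(bins$fst[idx], bins$r[idx], w[idx], bounds)
    }, 0)
    se <- stats::sd(boot, na.rm = TRUE)
  }

  structure(
    list(r0_hat = r0_hat, se = se, bins = bins,
         rss = sum(w * bins$resid^2), n_bins = nrow(bins)),
    class = "rate_fit"
  )
}

fit_weights <- function(bins) {
  if (!"se" %in% names(bins)) return(rep(1, nrow(bins)))
  w <- 1 / bins$se^2
  bad <- !is.finite(w) | w <= 0
  if (all(bad)) return(rep(1, nrow(bins)))
  if (any(bad)) {
    warn(paste(sum(bad), "bin(s) without a finite SE dropped from the",
               "weighted fit."))
    w[bad] <- 0
  }
  w
}

# d r / d r0 of the equilibrium curve, used in the WLS normal equation
dr_dr0 <- function(fst, r0) {
  u <- 1 + r0 + fst * (r0 - 1)
  v <- 1 + r0 - fst * (r0 - 1)
  ((1 + fst) * v - (1 - fst) * u) / v^2
}

solve_r0 <- function(fst, r, w, bounds) {
  grad <- function(r0) sum(w * (r - r_from_fst(fst, r0)) * dr_dr0(fst, r0))
  g_lo <- grad(bounds[1])
  g_hi <- grad(bounds[2])
  if (is.finite(g_lo) && is.finite(g_hi) && sign(g_lo) != sign(g_hi)) {
    stats::uniroot(grad, bounds, tol = 1e-12)$root
  } else {
    # gradient does not change sign on the interval: minimize the WLS loss
    stats::optimize(function(r0) sum(w * (r - r_from_fst(fst, r0))^2),
                    bounds, tol = 1e-10)$minimum
  }
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Equilibrium IM rate-ratio fit\n")
  cat(sprintf("  r0_hat = %.4f (bootstrap SE %.4f), %d bins, weighted RSS %.3g\n",
              x$r0_hat, x$se, x$n_bins, x$rss))
  invisible(x)
}

# ---- input checks ----------------------------------------------------------

check_positive <- function(x, name, scalar = FALSE) {
  if (scalar && length(x) != 1) abort(paste0("`", name, "` must be a scalar."))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be positive and finite."))
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort(paste0("`", name, "` must lie in [0, 1]."))
  }
  invisible(x)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run `expr` under a temporary seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) abort("a `seed` is required for stochastic generators.")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  expr
}
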