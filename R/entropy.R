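#' Complex bi-ancestry signal from diploid local-ancestry dosage
#'
#' Maps the diploid ancestry fraction `p1(l)` of parental population 1 at
#' each marker (0, 1/2 or 1 after discretization) to the unit-modulus
#' complex signal
#' \deqn{z(l) = \sqrt{p_1(l)} + i\sqrt{p_2(l)} = e^{i \arccos \sqrt{p_1(l)}},}
#' so that ancestry acts as the phase of a unit phasor whose power splits
#' exactly into the two ancestry fractions
#' (`Re(z)^2 = p1`, `Im(z)^2 = p2`, `|z|^2 = p1 + p2 = 1`). Swapping the
#' arbitrary ancestry labels maps `z` to `i * Conj(z)`, which leaves both
#' entropy metrics exactly unchanged. Local-ancestry software typically
#' emits an expected diploid dosage in \[0, 2\] per source; divide by 2
#' before calling, or pass the dosage already as a fraction.
#'
#' @param p1 Numeric vector of ancestry fractions in \[0, 1\].
#' @param positions Optional strictly increasing marker positions (bp);
#'   defaults to a unit grid. Markers are treated as equally spaced samples
#'   of the continuous signal.
#' @param snap If `TRUE` (default) snap fractions to the nearest of
#'   \{0, 1/2, 1\}; ties at 0.25 / 0.75 round toward 1/2.
#' @return Tibble of class `ancestry_signal` with columns `position`, `p1`,
#'   `z` (complex).
#' @export
#' @examples
#' ancestry_signal(c(1, 0.5, 0))$z  # 1, exp(i pi/4), i
ancestry_signal <- function(p1, positions = NULL, snap = TRUE) {
  if (any(!is.finite(p1)) || any(p1 < 0 | p1 > 1)) {
    abort("ancestry fractions must lie in [0, 1].")
  }
  if (is.null(positions)) positions <- seq_along(p1) - 1
  if (length(positions) != length(p1) || is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing and match `p1`.")
  }
  if (snap) p1 <- snap_dosage(p1)
  out <- tibble::tibble(position = positions, p1 = p1,
                        z = dosage_phasor(p1))
  class(out) <- c("ancestry_signal", class(out))
  out
}

# snap to {0, 1/2, 1}; ties at the 0.25/0.75 boundaries go to 1/2
snap_dosage <- function(p1) {
  ifelse(p1 < 0.25, 0, ifelse(p1 <= 0.75, 0.5, 1))
}

# amplitude convention: the phasor's power decomposes as (p1, p2)
dosage_phasor <- function(p1) {
  complex(real = sqrt(p1), imaginary = sqrt(1 - p1))
}

dosage_phasor_matrix <- function(P) {
  matrix(dosage_phasor(as.numeric(P)), nrow = nrow(P),
         dimnames = dimnames(P))
}

signal_z <- function(signal) {
  if (is.complex(signal)) return(signal)
  if (is.data.frame(signal) && "z" %in% names(signal)) return(signal$z)
  if (is.numeric(signal)) return(dosage_phasor(signal))
  abort("expected an `ancestry_signal`, a complex vector, or p1 fractions.")
}

#' Within-individual spectral entropy of an ancestry signal
#'
#' Discrete Fourier transform of the complex ancestry signal, normalized so
#' the squared coefficient moduli sum to 1 (discrete Parseval for a
#' unit-power signal); the power spectrum is folded around zero frequency
#' (`zeta_0 = |Z_0|^2`, `zeta_n = |Z_n|^2 + |Z_-n|^2` for `n > 0`) and the
#' within-individual entropy is its Shannon entropy in nats,
#' `Sw = -sum zeta_n log zeta_n` (with `0 log 0 = 0`). Highly autocorrelated
#' ancestry concentrates the spectrum and lowers `Sw`.
#'
#' @param signal An [ancestry_signal()], a complex vector, or a numeric
#'   vector of p1 fractions.
#' @return List of class `within_entropy`: `sw` (nats), `zeta` (folded
#'   spectrum, index `n` starting at 0), `n_markers`.
#' @export
#' @examples
#' within_entropy(rep(1, 64))$sw  # constant ancestry -> 0
within_entropy <- function(signal) {
  z <- signal_z(signal)
  M <- length(z)
  if (M < 1) abort("empty signal.")
  if (M == 1) {
    warn("single marker: Sw is 0 by construction.")
    out <- list(sw = 0, zeta = 1, n_markers = 1L)
    class(out) <- "within_entropy"
    return(out)
  }
  Z <- stats::fft(z) / M            # sum |Z|^2 = mean |z|^2 = 1
  pw <- Mod(Z)^2
  half <- (M - 1) %/% 2
  zeta <- numeric(half + 1 + (M %% 2 == 0))
  zeta[1] <- pw[1]
  if (half >= 1) {
    zeta[1 + seq_len(half)] <- pw[1 + seq_len(half)] + pw[M + 1 - seq_len(half)]
  }
  if (M %% 2 == 0) zeta[length(zeta)] <- pw[M / 2 + 1]  # Nyquist bin
  out <- list(sw = entropy_nats(zeta), zeta = zeta, n_markers = M)
  class(out) <- "within_entropy"
  out
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Between-individual spectral entropy of a cohort of ancestry signals
#'
#' Averages the cross-correlation `z_j(l) * Conj(z_j'(l))` over markers to
#' form the J x J Hermitian cohort matrix `C` (unit diagonal), then takes
#' the Shannon entropy of its normalized eigenvalue spectrum,
#' `Sb = -sum (lambda_j / J) log(lambda_j / J)`. Identical signals give
#' `Sb = 0`; signals with zero average cross-correlation give the maximum
#' `ln J`. Eigenvalues in `(-1e-9, 0)` from finite-precision decomposition
#' are clipped to zero.
#'
#' @param signals A list of [ancestry_signal()]s on a common marker grid, or
#'   a complex matrix (markers x individuals), or a numeric matrix of p1
#'   fractions.
#' @return List of class `between_entropy`: `sb` (nats), `lambda`
#'   (eigenvalues, sum = J), `C` (cohort matrix), `n_individuals`.
#' @export
between_entropy <- function(signals) {
  if (is.list(signals) && !is.data.frame(signals) && !is.matrix(signals)) {
    zs <- lapply(signals, signal_z)
    if (length(unique(lengths(zs))) != 1) {
      abort("all signals must share one marker grid.")
    }
    Zm <- do.call(cbind, zs)
  } else if (is.matrix(signals)) {
    Zm <- if (is.complex(signals)) signals else dosage_phasor_matrix(signals)
  } else {
    abort("`signals` must be a list of signals or a markers-x-individuals matrix.")
  }
  J <- ncol(Zm)
  if (J < 2) abort("need at least 2 individuals.")
  M <- nrow(Zm)
  C <- crossprod(Conj(Zm), Zm) / M     # c[j,j'] = mean_l Conj(z_j) z_j'
  C <- Conj(C)                          # -> mean_l z_j Conj(z_j')
  lambda <- Re(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (any(lambda < -1e-9)) {
    warn("cohort matrix has eigenvalues below -1e-9; check input signals.")
  }
  lambda <- pmax(lambda, 0)
  out <- list(sb = entropy_nats(lambda / J), lambda = lambda, C = C,
              n_individuals = J)
  class(out) <- "between_entropy"
  out
}

#' @export
print.within_entropy <- function(x, ...) {
  cat(sprintf("Within-individual spectral entropy: Sw = %.4f nats (%d markers)\n",
              x$sw, x$n_markers))
  invisible(x)
}

#' @export
print.between_entropy <- function(x, ...) {
  cat(sprintf("Between-individual spectral entropy: Sb = %.4f nats (J = %d, max %.4f)\n",
              x$sb, x$n_individuals, log(x$n_individuals)))
  invisible(x)
}

# folded power spectra for all columns at once (markers x individuals)
folded_spectra <- function(Zm) {
  M <- nrow(Zm)
  Z <- stats::mvfft(Zm) / M
  pw <- Mod(Z)^2
  half <- (M - 1) %/% 2
  zeta <- pw[1, , drop = FALSE]
  if (half >= 1) {
    zeta <- rbind(zeta, pw[1 + seq_len(half), , drop = FALSE] +
                    pw[M + 1 - seq_len(half), , drop = FALSE])
  }
  if (M %% 2 == 0) zeta <- rbind(zeta, pw[M / 2 + 1, , drop = FALSE])
  zeta
}

# cohort-mean Sw and Sb for one markers-x-individuals phasor matrix
cohort_entropy <- function(Zm) {
  zeta <- folded_spectra(Zm)
  sw <- apply(zeta, 2, entropy_nats)
  list(sw = sw, sb = between_entropy(Zm)$sb)
}

#' Per-segment entropy of a dosage table
#'
#' Splits each chromosome into `k` equal-length segments and computes, per
#' segment, the within-individual entropy `Sw` of every individual plus the
#' cohort between-individual entropy `Sb`.
#'
#' @param dosages Tibble with columns `chrom`, `position` and one p1
#'   fraction column per individual.
#' @param k Segments per chromosome.
#' @param chrom_sizes Optional chromosome sizes (defaults to max position
#'   + 1 per chromosome).
#' @return Tibble with `chrom`, `segment`, `individual`, `sw`, `sb`
#'   (repeated across the segment's individuals) and `n_markers`.
#' @export
entropy_by_segment <- function(dosages, k, chrom_sizes = NULL) {
  dosages <- tibble::as_tibble(dosages)
  ind_cols <- setdiff(names(dosages), c("chrom", "position"))
  if (length(ind_cols) < 2) abort("need at least 2 individual columns.")
  if (is.null(chrom_sizes)) {
    sizes <- dplyr::summarise(dplyr::group_by(dosages, .data$chrom),
                              size = max(.data$position) + 1, .groups = "drop")
  } else {
    sizes <- as_chrom_sizes(chrom_sizes)
  }
  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    ch <- sizes$chrom[i]
    d <- dosages[dosages$chrom == ch, ]
    d <- d[order(d$position), ]
    bounds <- seq(0, sizes$size[i], length.out = k + 1)
    seg_idx <- pmin(pmax(findInterval(d$position, bounds,
                                      rightmost.closed = TRUE), 1L), k)
    purrr::map_dfr(seq_len(k), function(s) {
      ds <- d[seg_idx == s, ind_cols, drop = FALSE]
      if (nrow(ds) < 2) {
        return(tibble::tibble(chrom = ch, segment = s,
                              individual = ind_cols, sw = NA_real_,
                              sb = NA_real_, n_markers = nrow(ds)))
      }
      P <- snap_dosage(as.matrix(ds))
      ce <- cohort_entropy(dosage_phasor_matrix(P))
      tibble::tibble(chrom = ch, segment = s, individual = ind_cols,
                     sw = ce$sw, sb = ce$sb, n_markers = nrow(ds))
    })
  })
}
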