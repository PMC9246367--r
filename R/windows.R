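#' Sliding-window scheme over chromosomes
#'
#' Tiles each chromosome with left-closed, right-open windows of `width` bp
#' every `step` bp (0-based, half-open coordinates). The terminal partial
#' window is kept. The defaults reproduce a 50 kb / 10 kb sliding scan.
#'
#' @param chrom_sizes Named numeric vector (or two-column data frame
#'   `chrom`, `size`) of chromosome lengths in bp.
#' @param width Window width in bp.
#' @param step Step between window starts in bp (default `width`:
#'   non-overlapping).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' make_windows(c(chr1 = 120e3), width = 50e3, step = 10e3)
make_windows <- function(chrom_sizes, width = 50e3, step = width) {
  sizes <- as_chrom_sizes(chrom_sizes)
  check_positive(width, "width", scalar = TRUE)
  check_positive(step, "step", scalar = TRUE)
  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    L <- sizes$size[i]
    starts <- seq(0, max(0, L - 1), by = step)
    starts <- starts[starts < L]
    tibble::tibble(chrom = sizes$chrom[i], start = starts,
                   end = pmin(starts + width, L))
  })
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
    tibble::as_tibble(chrom_sizes[c("chrom", "size")])
  } else {
    if (is.null(names(chrom_sizes))) abort("`chrom_sizes` must be named.")
    tibble::tibble(chrom = names(chrom_sizes), size = as.numeric(chrom_sizes))
  }
}

# Per-site Hudson components from diploid dosage matrices (rows = sites).
# Returns tibble with allele freqs, called-allele counts and per-site terms.
site_components <- function(geno_a, geno_b) {
  na <- 2 * rowSums(!is.na(geno_a))
  nb <- 2 * rowSums(!is.na(geno_b))
  pa <- rowSums(geno_a, na.rm = TRUE) / pmax(na, 1)
  pb <- rowSums(geno_b, na.rm = TRUE) / pmax(nb, 1)
  pa[na == 0] <- NA_real_
  pb[nb == 0] <- NA_real_

  dxy <- pa * (1 - pb) + pb * (1 - pa)
  pi_a <- ifelse(na >= 2, 2 * pa * (1 - pa) * na / (na - 1), NA_real_)
  pi_b <- ifelse(nb >= 2, 2 * pb * (1 - pb) * nb / (nb - 1), NA_real_)
  # Hudson estimator terms (ratio of averages across sites)
  hud_ok <- na >= 2 & nb >= 2
  fst_num <- ifelse(hud_ok,
                    (pa - pb)^2 -
                      pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1),
                    NA_real_)
  fst_den <- ifelse(hud_ok, dxy, NA_real_)
  tibble::tibble(p_a = pa, p_b = pb, n_called_a = na, n_called_b = nb,
                 fst_num = fst_num, fst_den = fst_den,
                 dxy = dxy, pi_a = pi_a, pi_b = pi_b)
}

#' Windowed FST, DXY and nucleotide diversity
#'
#' Computes per-window Hudson's FST (ratio of per-site averages), absolute
#' divergence DXY and within-population diversity pi from unphased diploid
#' genotypes of two populations. Sites must be biallelic; allele frequencies
#' use called alleles only (a site enters FST and pi only where both
#' populations have at least two called alleles). DXY and pi are per-site
#' values normalized by the window span (or by accessible sites when an
#' accessibility count per window is supplied).
#'
#' @param genotypes Tibble with columns `chrom`, `pos` (0-based) and one
#'   column per sample holding alternate-allele dosage 0/1/2 (`NA` =
#'   missing).
#' @param pop_a,pop_b Character vectors of sample column names for the two
#'   populations.
#' @param windows Window tibble from [make_windows()] (columns `chrom`,
#'   `start`, `end`).
#' @param accessible Optional numeric vector (length `nrow(windows)`) of
#'   accessible-site counts used instead of the window span to normalize
#'   DXY and pi.
#' @return The `windows` tibble with added columns `n_sites`, `fst`, `dxy`,
#'   `pi_a`, `pi_b`, `pi_mean`. Windows monomorphic in both populations (or
#'   empty) have `fst = NA`; empty windows have all statistics `NA` and
#'   `n_sites = 0`.
#' @export
windowed_stats <- function(genotypes, pop_a, pop_b, windows,
                           accessible = NULL) {
  genotypes <- tibble::as_tibble(genotypes)
  windows <- tibble::as_tibble(windows)
  if (length(pop_a) < 1 || length(pop_b) < 1) {
    abort("each population needs at least one sample.")
  }
  missing_cols <- setdiff(c(pop_a, pop_b), names(genotypes))
  if (length(missing_cols)) {
    abort(paste("samples absent from genotype table:",
                paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(unique(genotypes$chrom), unique(windows$chrom))
  if (length(unknown)) {
    abort(paste("chromosome(s) not covered by the window scheme:",
                paste(unknown, collapse = ", ")))
  }

  comp <- site_components(as.matrix(genotypes[pop_a]),
                          as.matrix(genotypes[pop_b]))
  comp$chrom <- genotypes$chrom
  comp$pos <- genotypes$pos

  span <- if (is.null(accessible)) windows$end - windows$start else accessible
  out <- windows
  out$n_sites <- 0L
  for (col in c("fst", "dxy", "pi_a", "pi_b")) out[[col]] <- NA_real_

  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- comp[comp$chrom == ch, ]
    ord <- order(si$pos)
    si <- si[ord, ]
    # cumulative sums over sorted site positions; window sum by two lookups
    csum <- function(v) cumsum(ifelse(is.na(v), 0, v))
    cums <- lapply(si[c("fst_num", "fst_den", "dxy", "pi_a", "pi_b")], csum)
    cnt <- seq_along(si$pos)
    at <- function(cv, idx) {
      # cumulative value before/at index; 0 for idx = 0 (indexing with a
      # zero would silently drop elements)
      out <- numeric(length(idx))
      ok <- idx > 0
      out[ok] <- cv[idx[ok]]
      out
    }
    lo <- findInterval(windows$start[wi] - 0.5, si$pos)
    hi <- findInterval(windows$end[wi] - 0.5, si$pos)
    out$n_sites[wi] <- as.integer(at(cnt, hi) - at(cnt, lo))
    num <- at(cums$fst_num, hi) - at(cums$fst_num, lo)
    den <- at(cums$fst_den, hi) - at(cums$fst_den, lo)
    out$fst[wi] <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), NA_real_)
    out$dxy[wi] <- (at(cums$dxy, hi) - at(cums$dxy, lo)) / span[wi]
    out$pi_a[wi] <- (at(cums$pi_a, hi) - at(cums$pi_a, lo)) / span[wi]
    out$pi_b[wi] <- (at(cums$pi_b, hi) - at(cums$pi_b, lo)) / span[wi]
  }
  empty <- out$n_sites == 0
  out$dxy[empty] <- NA_real_
  out$pi_a[empty] <- NA_real_
  out$pi_b[empty] <- NA_real_
  out$pi_mean <- (out$pi_a + out$pi_b) / 2
  out
}

#' Average window statistics over equal-length chromosome segments
#'
#' Partitions each chromosome into `k` equal-length bp segments and averages
#' every numeric window statistic over the windows whose midpoints fall in
#' each segment. Segments containing no window midpoint are kept with `NA`
#' values. The result is invariant to the ordering of the input windows.
#'
#' @param stats Window tibble from [windowed_stats()] (columns `chrom`,
#'   `start`, `end` plus numeric statistics).
#' @param k Number of segments per chromosome (>= 1).
#' @param chrom_sizes Optional chromosome sizes; defaults to the maximum
#'   window `end` per chromosome.
#' @return Tibble with `chrom`, `segment` (1-based), `start`, `end`,
#'   `n_windows` and the segment means of each numeric statistic.
#' @export
segment_means <- function(stats, k, chrom_sizes = NULL) {
  if (k < 1) abort("`k` must be >= 1.")
  stats <- tibble::as_tibble(stats)
  if (is.null(chrom_sizes)) {
    sizes <- dplyr::summarise(dplyr::group_by(stats, .data$chrom),
                              size = max(.data$end), .groups = "drop")
  } else {
    sizes <- as_chrom_sizes(chrom_sizes)
  }
  stat_cols <- setdiff(names(stats)[vapply(stats, is.numeric, TRUE)],
                       c("start", "end", "n_sites"))
  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    ch <- sizes$chrom[i]
    L <- sizes$size[i]
    bounds <- seq(0, L, length.out = k + 1)
    w <- stats[stats$chrom == ch, ]
    mid <- (w$start + w$end) / 2
    seg_idx <- pmin(pmax(findInterval(mid, bounds, rightmost.closed = TRUE),
                         1L), k)
    seg <- tibble::tibble(chrom = ch, segment = seq_len(k),
                          start = bounds[-(k + 1)], end = bounds[-1])
    seg$n_windows <- as.integer(tabulate(seg_idx, nbins = k))
    for (col in stat_cols) {
      sums <- vapply(seq_len(k), function(s) {
        v <- w[[col]][seg_idx == s]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, 0)
      seg[[col]] <- sums
    }
    seg
  })
}
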