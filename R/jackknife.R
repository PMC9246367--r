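#' Block-jackknife estimate for a statistic of blockwise sums
#'
#' Delete-one-block jackknife for any statistic expressible as a function of
#' column sums over genomic blocks (ratios of sums cover FST, D3, D4 and the
#' rate ratio). Uses the weighted delete-m jackknife, which reduces exactly
#' to the classic delete-one jackknife when all blocks have equal weight.
#'
#' @param blocks Data frame with one row per block; all numeric columns are
#'   summed. An optional `n_sites` (or `n`) column supplies block weights;
#'   otherwise blocks are weighted equally.
#' @param stat Function mapping a named numeric vector of column totals to a
#'   scalar statistic, e.g. `function(s) s["num"] / s["den"]`.
#' @param weights Optional explicit numeric block weights, overriding
#'   `n_sites`.
#' @return A one-row tibble (`estimate`, `se`, `z`, `n_blocks`). `z` is
#'   `estimate / se`; when `se` is exactly zero `z` is `NA` and flagged by a
#'   warning; the point estimate is always the all-data statistic.
#' @export
#' @examples
#' b <- tibble::tibble(num = c(3, 3) - c(5, 5), den = c(8, 8))
#' block_jackknife(b, function(s) s[["num"]] / s[["den"]])  # D3 = -0.25, se 0
block_jackknife <- function(blocks, stat, weights = NULL) {
  blocks <- tibble::as_tibble(blocks)
  num_cols <- names(blocks)[vapply(blocks, is.numeric, TRUE)]
  if (length(num_cols) == 0) abort("`blocks` has no numeric columns.")
  X <- as.matrix(blocks[num_cols])
  g <- nrow(X)
  if (g < 2) abort("block jackknife needs at least 2 non-empty blocks.")

  if (is.null(weights)) {
    wcol <- intersect(c("n_sites", "n"), num_cols)
    weights <- if (length(wcol)) X[, wcol[1]] else rep(1, g)
  }
  if (any(weights <= 0)) {
    keep <- weights > 0
    X <- X[keep, , drop = FALSE]
    weights <- weights[keep]
    g <- nrow(X)
    if (g < 2) abort("block jackknife needs at least 2 non-empty blocks.")
  }

  totals <- colSums(X)
  theta <- as.numeric(stat(totals))
  loo <- vapply(seq_len(g), function(j) as.numeric(stat(totals - X[j, ])), 0)

  n <- sum(weights)
  h <- n / weights
  theta_j <- g * theta - sum((1 - weights / n) * loo)
  pseudo <- h * theta - (h - 1) * loo
  se <- sqrt(sum((pseudo - theta_j)^2 / (h - 1)) / g)

  z <- if (is.finite(se) && se > 0) theta / se else NA_real_
  if (is.na(z)) warn("jackknife SE is zero or undefined; z flagged as NA.")
  tibble::tibble(estimate = theta, se = se, z = z, n_blocks = g)
}

#' Jackknife for a ratio-of-sums statistic
#'
#' Convenience wrapper around [block_jackknife()] for statistics of the form
#' `sum(num) / sum(den)` with per-block numerator and denominator sums.
#'
#' @param num,den Numeric vectors of per-block numerator and denominator
#'   sums.
#' @param n_sites Optional per-block site counts used as jackknife weights.
#' @return A one-row tibble as in [block_jackknife()]. If the pooled
#'   denominator is zero the estimate is `NA` (flagged by a warning).
#' @export
jackknife_ratio <- function(num, den, n_sites = NULL) {
  stopifnot(length(num) == length(den))
  if (sum(den) == 0) {
    warn("pooled denominator is zero; statistic undefined.")
    return(tibble::tibble(estimate = NA_real_, se = NA_real_, z = NA_real_,
                          n_blocks = length(num)))
  }
  if (length(num) < 2) {
    warn("single block: point estimate only, SE undefined.")
    return(tibble::tibble(estimate = sum(num) / sum(den), se = NA_real_,
                          z = NA_real_, n_blocks = length(num)))
  }
  blocks <- tibble::tibble(num = num, den = den)
  if (!is.null(n_sites)) blocks$n_sites <- n_sites
  block_jackknife(blocks, function(s) s[["num"]] / s[["den"]])
}

#' Pearson correlation with delete-one-segment jackknife significance
#'
#' Computes Pearson's rho between paired per-segment values and estimates
#' its standard error and Z-score by deleting one segment at a time, the
#' scheme used for entropy-divergence correlations across chromosome
#' segments.
#'
#' @param x,y Numeric vectors of paired per-segment values; pairs with
#'   missing values are dropped.
#' @return A one-row tibble (`estimate`, `se`, `z`, `n_blocks`). If either
#'   vector has zero variance the correlation is undefined (`NA`, with a
#'   warning).
#' @export
#' @examples
#' correlate_with_jackknife(1:10, (1:10) * 2)  # rho = 1
correlate_with_jackknife <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete segment pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance in `x` or `y`; correlation undefined.")
    return(tibble::tibble(estimate = NA_real_, se = NA_real_, z = NA_real_,
                          n_blocks = n))
  }
  rho <- stats::cor(x, y)
  loo <- vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]), 0)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  z <- if (se > 0) rho / se else NA_real_
  tibble::tibble(estimate = rho, se = se, z = z, n_blocks = n)
}

#' Assign positions to fixed-width genomic blocks
#'
#' Blocks are `block_size` bp wide, never span chromosomes, and are labelled
#' `chrom:index`. Used to prepare 1 Mb jackknife blocks.
#'
#' @param chrom Chromosome identifiers.
#' @param pos 0-based positions.
#' @param block_size Block width in bp (default 1e6).
#' @return Character vector of block labels, parallel to the input.
#' @export
block_of <- function(chrom, pos, block_size = 1e6) {
  paste0(chrom, ":", floor(pos / block_size))
}
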