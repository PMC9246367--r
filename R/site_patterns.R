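#' Per-taxon allele frequencies from a genotype table
#'
#' Collapses sample dosage columns into alternate-allele frequencies for
#' each taxon of a site-pattern analysis (focal populations `p1`, `p2` and
#' outgroups `o1`, `o2`, ...), using called alleles only.
#'
#' @param genotypes Genotype tibble (`chrom`, `pos`, dosage columns).
#' @param taxa Named list mapping taxon labels (`p1`, `p2`, `o1`, `o2`,
#'   ...) to character vectors of sample columns.
#' @return Tibble with `chrom`, `pos` and one frequency column per taxon
#'   (`NA` where a taxon has no called allele).
#' @export
site_frequencies <- function(genotypes, taxa) {
  genotypes <- tibble::as_tibble(genotypes)
  missing_cols <- setdiff(unlist(taxa), names(genotypes))
  if (length(missing_cols)) {
    abort(paste("samples absent from genotype table:",
                paste(missing_cols, collapse = ", ")))
  }
  out <- genotypes[c("chrom", "pos")]
  for (tx in names(taxa)) {
    G <- as.matrix(genotypes[taxa[[tx]]])
    called <- 2 * rowSums(!is.na(G))
    f <- rowSums(G, na.rm = TRUE) / pmax(called, 1)
    f[called == 0] <- NA_real_
    out[[tx]] <- f
  }
  out
}

#' Blockwise site-pattern sums from per-taxon allele frequencies
#'
#' From per-site alternate/derived allele frequencies in the two focal taxa
#' and up to two outgroups, accumulates - per jackknife block - the expected
#' frequency sums of the three-taxon patterns ABB / BAB, the four-taxon
#' patterns ABBA / BABA, and the numerator / denominator of the observed
#' rate-ratio estimator.
#'
#' Pattern probabilities are the frequency-analytic expectation of drawing
#' one allele at random per taxon, which makes the statistics deterministic;
#' `mode = "sample"` instead draws one allele per taxon per site (seeded)
#' for cross-checking. Polarization follows the outgroup carrying the site:
#' * ABB / BAB ("D3"): sites where `o1` is non-polymorphic; the `o1` allele
#'   is ancestral ("B"), so `ABB = d1 (1 - d2)`, `BAB = (1 - d1) d2` with
#'   `d` the focal frequencies of the allele absent from `o1`.
#' * ABBA / BABA ("D4"): sites where `o2` is non-polymorphic; relative to
#'   the `o2` allele, `ABBA = (1 - d1) d2 do1`, `BABA = d1 (1 - d2) do1`.
#' * rate ratio: sites where every outgroup column is fixed for the same
#'   allele (the ancestral state); `num = d1 (1 - d2)`, `den = (1 - d1) d2`.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `p1`, `p2` (focal
#'   alternate-allele frequencies in \[0, 1\]) and outgroup frequency
#'   columns `o1` and optionally `o2`, `o3`, ... Sites with missing
#'   frequencies in a required taxon are skipped for the affected statistic.
#' @param block_size Jackknife block width in bp (default 1 Mb); blocks
#'   never span chromosomes.
#' @param rr_outgroups Character vector of outgroup columns whose joint
#'   fixity gates the rate-ratio sums (default: all `o*` columns present).
#' @param mode `"frequency"` (default, deterministic) or `"sample"`.
#' @param seed Integer seed, required for `mode = "sample"`.
#' @return Tibble with one row per block: `block`, `n_sites`, `abb`, `bab`,
#'   `abba`, `baba`, `rr_num`, `rr_den`. Sums are block-additive.
#' @export
site_pattern_counts <- function(sites, block_size = 1e6, rr_outgroups = NULL,
                                mode = c("frequency", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "p1", "p2", "o1") %in% names(sites)))
  out_cols <- grep("^o[0-9]+$", names(sites), value = TRUE)
  if (is.null(rr_outgroups)) rr_outgroups <- out_cols

  f <- sites
  if (mode == "sample") {
    f <- with_seed(seed, {
      g <- sites
      for (col in c("p1", "p2", out_cols)) {
        g[[col]] <- as.numeric(rbinom(nrow(g), 1, replace(g[[col]],
                                                          is.na(g[[col]]), 0)))
        g[[col]][is.na(sites[[col]])] <- NA_real_
      }
      g
    })
  }

  fixed <- function(x) !is.na(x) & (x == 0 | x == 1)
  # D3: polarize against the fixed o1 allele
  ok3 <- fixed(f$o1) & !is.na(f$p1) & !is.na(f$p2)
  d1 <- ifelse(f$o1 == 0, f$p1, 1 - f$p1)
  d2 <- ifelse(f$o1 == 0, f$p2, 1 - f$p2)
  abb <- ifelse(ok3, d1 * (1 - d2), 0)
  bab <- ifelse(ok3, (1 - d1) * d2, 0)

  # D4: polarize against the fixed o2 allele
  if ("o2" %in% names(f)) {
    ok4 <- fixed(f$o2) & !is.na(f$p1) & !is.na(f$p2) & !is.na(f$o1)
    e1 <- ifelse(f$o2 == 0, f$p1, 1 - f$p1)
    e2 <- ifelse(f$o2 == 0, f$p2, 1 - f$p2)
    eo1 <- ifelse(f$o2 == 0, f$o1, 1 - f$o1)
    abba <- ifelse(ok4, (1 - e1) * e2 * eo1, 0)
    baba <- ifelse(ok4, e1 * (1 - e2) * eo1, 0)
  } else {
    abba <- baba <- rep(0, nrow(f))
  }

  # rate ratio: all gating outgroups fixed for one common allele
  if (length(rr_outgroups)) {
    og <- as.matrix(f[rr_outgroups])
    all_zero <- rowSums(og == 0, na.rm = TRUE) == length(rr_outgroups) &
      rowSums(is.na(og)) == 0
    all_one <- rowSums(og == 1, na.rm = TRUE) == length(rr_outgroups) &
      rowSums(is.na(og)) == 0
    okr <- (all_zero | all_one) & !is.na(f$p1) & !is.na(f$p2)
    r1 <- ifelse(all_one, 1 - f$p1, f$p1)
    r2 <- ifelse(all_one, 1 - f$p2, f$p2)
    rr_num <- ifelse(okr, r1 * (1 - r2), 0)
    rr_den <- ifelse(okr, (1 - r1) * r2, 0)
  } else {
    rr_num <- rr_den <- rep(0, nrow(f))
  }

  tb <- tibble::tibble(
    block = block_of(f$chrom, f$pos, block_size),
    n_sites = 1L, abb = abb, bab = bab, abba = abba, baba = baba,
    rr_num = rr_num, rr_den = rr_den
  )
  dplyr::summarise(dplyr::group_by(tb, .data$block),
                   dplyr::across(dplyr::everything(), sum), .groups = "drop")
}

#' Three-taxon site-pattern asymmetry D3
#'
#' `D3 = (sum ABB - sum BAB) / (sum ABB + sum BAB)` over all blocks, with
#' block-jackknife SE and Z. Under equal substitution rates and no gene flow
#' with the outgroup, `D3 = 0` in expectation; a faster-evolving second
#' focal lineage drives `D3` negative.
#'
#' @param counts Block tibble from [site_pattern_counts()] (columns `abb`,
#'   `bab`; optional `n_sites` weights).
#' @return One-row jackknife tibble (`estimate`, `se`, `z`, `n_blocks`).
#' @export
d3 <- function(counts) {
  jackknife_ratio(counts$abb - counts$bab, counts$abb + counts$bab,
                  counts$n_sites)
}

#' Four-taxon (ABBA-BABA) site-pattern asymmetry D4
#'
#' `D4 = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)` with block-jackknife
#' SE and Z: the classic ABBA-BABA D statistic, used here as a general
#' asymmetry metric (recurrent outgroup mutations combined with unequal
#' focal substitution rates also drive it away from zero).
#'
#' @param counts Block tibble from [site_pattern_counts()] (columns `abba`,
#'   `baba`).
#' @return One-row jackknife tibble.
#' @export
d4 <- function(counts) {
  jackknife_ratio(counts$abba - counts$baba, counts$abba + counts$baba,
                  counts$n_sites)
}

#' Observed substitution-rate ratio between the focal lineages
#'
#' Over sites where all gating outgroups are fixed for the same (ancestral)
#' allele, \deqn{r = \frac{\sum_s f_{P1} (1 - f_{P2})}{\sum_s (1 - f_{P1})
#' f_{P2}},} the frequency-analytic form of sampling one allele at random
#' from each focal lineage and counting derived alleles exclusive to each.
#' Block-jackknife SE over 1 Mb blocks.
#'
#' @param counts Block tibble from [site_pattern_counts()] (columns
#'   `rr_num`, `rr_den`), or a site tibble accepted by
#'   [site_pattern_counts()].
#' @param ... Passed to [site_pattern_counts()] when `counts` is a site
#'   table.
#' @return One-row jackknife tibble.
#' @export
rate_ratio <- function(counts, ...) {
  if (!all(c("rr_num", "rr_den") %in% names(counts))) {
    counts <- site_pattern_counts(counts, ...)
  }
  jackknife_ratio(counts$rr_num, counts$rr_den, counts$n_sites)
}

#' Background FST of individual sites from a sliding-window scan
#'
#' Assigns each site the mean (or max) FST of the sliding windows covering
#' it. Sites covered by no window get `NA` and are counted in a warning.
#'
#' @param sites Site tibble with `chrom`, `pos`.
#' @param window_stats Window tibble from [windowed_stats()] with `fst`.
#' @param summary `"mean"` (default) or `"max"` over covering windows.
#' @return `sites` with an added `bg_fst` column.
#' @export
assign_background_fst <- function(sites, window_stats,
                                  summary = c("mean", "max")) {
  summary <- match.arg(summary)
  sites <- tibble::as_tibble(sites)
  sites$bg_fst <- NA_real_
  for (ch in unique(sites$chrom)) {
    w <- window_stats[window_stats$chrom == ch & !is.na(window_stats$fst), ]
    si <- which(sites$chrom == ch)
    if (!nrow(w) || !length(si)) next
    pos <- sites$pos[si]
    # windows are uniform-width sliding; do a simple interval sweep
    vals <- vapply(pos, function(p) {
      inw <- w$fst[w$start <= p & p < w$end]
      if (!length(inw)) return(NA_real_)
      if (summary == "mean") mean(inw) else max(inw)
    }, 0)
    sites$bg_fst[si] <- vals
  }
  n_uncov <- sum(is.na(sites$bg_fst))
  if (n_uncov > 0) {
    warn(paste(n_uncov, "site(s) outside all windows: bg_fst set to NA."))
  }
  sites
}

#' Partition sites by background FST
#'
#' Threshold mode reproduces a cumulative FST-threshold scan: for each
#' threshold `t` the partition holds all sites with background FST `>= t`
#' (site counts are monotone non-increasing in `t`). Bin mode assigns each
#' site once to one of `n_bins` equal-width FST intervals spanning \[0, 1\].
#'
#' @param sites Site tibble carrying `bg_fst` (see
#'   [assign_background_fst()]); if absent, `window_stats` must be given
#'   and is used to compute it.
#' @param window_stats Optional window tibble for computing `bg_fst`.
#' @param mode `"threshold"` or `"bins"`.
#' @param thresholds Numeric thresholds for threshold mode (default
#'   `seq(0, 0.9, 0.1)`).
#' @param n_bins Number of equal-width bins for bin mode (default 10).
#' @param summary Passed to [assign_background_fst()].
#' @return Tibble with columns `partition` (label), `fst_lower` (threshold
#'   or bin lower edge), `fst_mid` (bin midpoint, bins mode), `n_sites`, and
#'   a list-column `data` of the site subsets.
#' @export
partition_by_fst <- function(sites, window_stats = NULL,
                             mode = c("threshold", "bins"),
                             thresholds = seq(0, 0.9, by = 0.1),
                             n_bins = 10, summary = "mean") {
  mode <- match.arg(mode)
  sites <- tibble::as_tibble(sites)
  if (!"bg_fst" %in% names(sites)) {
    if (is.null(window_stats)) {
      abort("supply `window_stats` or a precomputed `bg_fst` column.")
    }
    sites <- assign_background_fst(sites, window_stats, summary = summary)
  }
  if (mode == "threshold") {
    purrr::map_dfr(thresholds, function(t) {
      sub <- sites[!is.na(sites$bg_fst) & sites$bg_fst >= t, , drop = FALSE]
      tibble::tibble(partition = sprintf("fst>=%.3g", t), fst_lower = t,
                     fst_mid = NA_real_, n_sites = nrow(sub),
                     data = list(sub))
    })
  } else {
    edges <- seq(0, 1, length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(sites$bg_fst, edges,
                                  rightmost.closed = TRUE), 1L), n_bins)
    bin[is.na(sites$bg_fst)] <- NA_integer_
    purrr::map_dfr(seq_len(n_bins), function(b) {
      sub <- sites[!is.na(bin) & bin == b, , drop = FALSE]
      tibble::tibble(partition = sprintf("bin%02d", b),
                     fst_lower = edges[b],
                     fst_mid = (edges[b] + edges[b + 1]) / 2,
                     n_sites = nrow(sub), data = list(sub))
    })
  }
}
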