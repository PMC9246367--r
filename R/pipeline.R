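#' Windowed and segment-level divergence scan
#'
#' Stage one of the analysis: windowed Hudson FST / DXY / pi between the
#' two focal populations plus segment averages, optionally written to TSV.
#'
#' @param genotypes Genotype tibble (see [read_genotypes_vcf()]) or a path
#'   to a VCF file.
#' @param pop_map Tibble `sample`, `population` (or path readable by
#'   [read_pop_map()]) with exactly two populations.
#' @param chrom_sizes Chromosome sizes (named vector or tibble); defaults
#'   to max site position + width per chromosome.
#' @param width,step Sliding-window scheme in bp (defaults 50 kb / 10 kb).
#' @param k_segments Segments per chromosome for [segment_means()]
#'   (default 20).
#' @param out_dir Optional directory for `windows.tsv` / `segments.tsv`.
#' @return List with `windows` and `segments` tibbles.
#' @export
run_window_stats <- function(genotypes, pop_map, chrom_sizes = NULL,
                             width = 5e4, step = 1e4, k_segments = 20,
                             out_dir = NULL) {
  if (is.character(genotypes)) genotypes <- read_genotypes_vcf(genotypes)
  if (is.character(pop_map)) pop_map <- read_pop_map(pop_map)
  pops <- split(pop_map$sample, pop_map$population)
  if (length(pops) != 2) abort("`pop_map` must define exactly two populations.")
  absent <- setdiff(unlist(pops), names(genotypes))
  if (length(absent)) {
    abort(paste("population map samples missing from genotypes:",
                paste(absent, collapse = ", ")))
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- dplyr::summarise(
      dplyr::group_by(genotypes, .data$chrom),
      size = max(.data$pos) + width, .groups = "drop")
  }
  windows <- make_windows(chrom_sizes, width = width, step = step)
  stats <- windowed_stats(genotypes, pops[[1]], pops[[2]], windows)
  segments <- segment_means(stats, k = k_segments, chrom_sizes = chrom_sizes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(width = width, step = step, k = k_segments)
    write_result_tsv(stats, file.path(out_dir, "windows.tsv"), config = cfg)
    write_result_tsv(segments, file.path(out_dir, "segments.tsv"),
                     config = cfg)
  }
  list(windows = stats, segments = segments)
}

#' Entropy of local ancestry and its correlation with divergence
#'
#' Stage two: per-segment within- and between-individual spectral entropy
#' of hybrid-population local-ancestry dosages (per replicate run), the
#' across-replicate mean and SE, and Pearson correlations (with
#' delete-one-segment jackknife Z-scores) between entropy and per-segment
#' pi / DXY / FST from the pure-population scan.
#'
#' @param dosages Dosage tibble (`replicate`, `chrom`, `position`,
#'   individual p1-fraction columns) as from [read_dosage_tsv()]; a
#'   `replicate` column is added if absent.
#' @param segments Segment tibble from [run_window_stats()].
#' @param k_segments Segments per chromosome (must match `segments`).
#' @param exclude_chroms Chromosomes dropped from the correlation analysis
#'   (default `"chrZ"`; sex chromosomes behave differently).
#' @param out_dir Optional output directory.
#' @return List: `entropy` (per replicate x segment x individual),
#'   `segment_entropy` (per segment: mean/SE of cohort-mean Sw and of Sb
#'   across replicates), `correlations` (one row per statistic x entropy
#'   metric with jackknife estimate/se/z).
#' @export
run_entropy <- function(dosages, segments, k_segments = 20,
                        exclude_chroms = "chrZ", out_dir = NULL) {
  dosages <- tibble::as_tibble(dosages)
  if (!"replicate" %in% names(dosages)) {
    dosages <- dplyr::bind_cols(tibble::tibble(replicate = 1L), dosages)
  }
  sizes <- dplyr::summarise(dplyr::group_by(segments, .data$chrom),
                            size = max(.data$end), .groups = "drop")
  reps <- split(dosages, dosages$replicate)
  ent <- purrr::map_dfr(names(reps), function(rp) {
    d <- reps[[rp]][setdiff(names(dosages), "replicate")]
    grids <- dplyr::summarise(dplyr::group_by(d, .data$chrom),
                              n = dplyr::n(), .groups = "drop")
    e <- entropy_by_segment(d, k = k_segments, chrom_sizes = sizes)
    dplyr::bind_cols(tibble::tibble(replicate = as.integer(rp),
                                    .rows = nrow(e)), e)
  })
  # grids must agree across replicates
  marker_counts <- dplyr::summarise(
    dplyr::group_by(ent, .data$replicate, .data$chrom, .data$segment),
    n = .data$n_markers[1], .groups = "drop")
  chk <- dplyr::summarise(
    dplyr::group_by(marker_counts, .data$chrom, .data$segment),
    distinct = dplyr::n_distinct(.data$n), .groups = "drop")
  if (any(chk$distinct > 1)) {
    abort("replicate dosage tables are not on a common marker grid.")
  }

  seg_ent <- dplyr::summarise(
    dplyr::group_by(ent, .data$replicate, .data$chrom, .data$segment),
    sw = mean(.data$sw), sb = .data$sb[1], .groups = "drop")
  n_rep <- dplyr::n_distinct(seg_ent$replicate)
  se_or_na <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  seg_sum <- dplyr::summarise(
    dplyr::group_by(seg_ent, .data$chrom, .data$segment),
    sw_mean = mean(.data$sw), sw_se = se_or_na(.data$sw),
    sb_mean = mean(.data$sb), sb_se = se_or_na(.data$sb),
    .groups = "drop")

  joined <- dplyr::inner_join(seg_sum, segments, by = c("chrom", "segment"))
  joined <- joined[!joined$chrom %in% exclude_chroms, ]
  stat_cols <- intersect(c("pi_mean", "pi_a", "pi_b", "dxy", "fst"),
                         names(joined))
  correlations <- purrr::map_dfr(stat_cols, function(sc) {
    purrr::map_dfr(c(sw = "sw_mean", sb = "sb_mean"), function(ec) {
      x <- joined[[ec]]
      y <- joined[[sc]]
      res <- if (sum(is.finite(x) & is.finite(y)) >= 3) {
        suppressWarnings(correlate_with_jackknife(x, y))
      } else {
        tibble::tibble(estimate = NA_real_, se = NA_real_, z = NA_real_,
                       n_blocks = sum(is.finite(x) & is.finite(y)))
      }
      dplyr::bind_cols(tibble::tibble(statistic = sc,
                                      entropy = sub("_mean", "", ec)), res)
    })
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(ent, file.path(out_dir, "entropy_segments.tsv"))
    write_result_tsv(correlations, file.path(out_dir,
                                             "entropy_correlations.tsv"))
  }
  list(entropy = ent, segment_entropy = seg_sum, correlations = correlations)
}

#' D-statistic scan over FST thresholds and rate ratio by FST bin
#'
#' Stage three: from polarized site frequencies and the window scan,
#' computes D3, D4 and the rate ratio on cumulative FST-threshold
#' partitions (and the rate ratio on ten equal-width FST bins), each with
#' 1 Mb block-jackknife errors. Site classes (e.g. synonymous /
#' nonsynonymous / intron), when present in a `site_class` column, are
#' analysed separately.
#'
#' @param sites Site-frequency tibble (see [site_pattern_counts()]),
#'   optionally with a `site_class` column.
#' @param window_stats Window tibble from [run_window_stats()].
#' @param thresholds FST thresholds for the cumulative scan.
#' @param n_bins FST bins for the rate-ratio partition (default 10).
#' @param block_size Jackknife block size in bp (default 1 Mb).
#' @param min_sites Partitions with fewer sites are flagged
#'   (`low_n = TRUE`), not suppressed (default 100).
#' @param out_dir Optional output directory.
#' @return List: `d_by_threshold` (site class x threshold: D3, D4, r with
#'   SE/Z), `r_by_bin` (site class x FST bin: `fst`, `r`, `se`, `n_sites`).
#' @export
run_dstats <- function(sites, window_stats, thresholds = seq(0, 0.9, 0.1),
                       n_bins = 10, block_size = 1e6, min_sites = 100,
                       out_dir = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!"site_class" %in% names(sites)) sites$site_class <- "all"
  sites <- assign_background_fst(sites, window_stats)
  per_class <- split(sites, sites$site_class)

  # single-block partitions get point estimates with undefined errors
  safe_jk <- function(counts, fn, num, den) {
    if (nrow(counts) >= 2) return(fn(counts))
    est <- if (sum(counts[[den]]) > 0) {
      sum(counts[[num]]) / sum(counts[[den]])
    } else {
      NA_real_
    }
    tibble::tibble(estimate = est, se = NA_real_, z = NA_real_,
                   n_blocks = nrow(counts))
  }
  stat_row <- function(counts) {
    counts$d3_num <- counts$abb - counts$bab
    counts$d3_den <- counts$abb + counts$bab
    counts$d4_num <- counts$abba - counts$baba
    counts$d4_den <- counts$abba + counts$baba
    est3 <- safe_jk(counts, d3, "d3_num", "d3_den")
    est4 <- safe_jk(counts, d4, "d4_num", "d4_den")
    estr <- safe_jk(counts, rate_ratio, "rr_num", "rr_den")
    tibble::tibble(
      d3 = est3$estimate, d3_se = est3$se, d3_z = est3$z,
      d4 = est4$estimate, d4_se = est4$se, d4_z = est4$z,
      r = estr$estimate, r_se = estr$se)
  }
  d_by_threshold <- purrr::map_dfr(names(per_class), function(cl) {
    parts <- partition_by_fst(per_class[[cl]], mode = "threshold",
                              thresholds = thresholds)
    purrr::map_dfr(seq_len(nrow(parts)), function(i) {
      sub <- parts$data[[i]]
      base <- tibble::tibble(site_class = cl, threshold = parts$fst_lower[i],
                             n_sites = parts$n_sites[i],
                             low_n = parts$n_sites[i] < min_sites)
      if (nrow(sub) < 2) {
        return(dplyr::bind_cols(base, tibble::tibble(
          d3 = NA_real_, d3_se = NA_real_, d3_z = NA_real_,
          d4 = NA_real_, d4_se = NA_real_, d4_z = NA_real_,
          r = NA_real_, r_se = NA_real_)))
      }
      counts <- site_pattern_counts(sub, block_size = block_size)
      dplyr::bind_cols(base, stat_row(counts))
    })
  })

  r_by_bin <- purrr::map_dfr(names(per_class), function(cl) {
    parts <- partition_by_fst(per_class[[cl]], mode = "bins", n_bins = n_bins)
    purrr::map_dfr(seq_len(nrow(parts)), function(i) {
      sub <- parts$data[[i]]
      base <- tibble::tibble(site_class = cl, bin = parts$partition[i],
                             fst = parts$fst_mid[i],
                             n_sites = parts$n_sites[i],
                             low_n = parts$n_sites[i] < min_sites)
      if (nrow(sub) < 2) {
        return(dplyr::bind_cols(base, tibble::tibble(r = NA_real_,
                                                     se = NA_real_)))
      }
      counts <- site_pattern_counts(sub, block_size = block_size)
      est <- safe_jk(counts, rate_ratio, "rr_num", "rr_den")
      dplyr::bind_cols(base, tibble::tibble(r = est$estimate, se = est$se))
    })
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(d_by_threshold, file.path(out_dir, "d_by_threshold.tsv"))
    write_result_tsv(r_by_bin, file.path(out_dir, "r_by_bin.tsv"))
  }
  list(d_by_threshold = d_by_threshold, r_by_bin = r_by_bin)
}

#' Fit the true rate ratio to binned observations
#'
#' Stage four: fits `r0` through [fit_r0()] to the per-bin rate ratios of
#' [run_dstats()] and reports the fitted curve.
#'
#' @param r_by_bin Tibble with `fst`, `r` and optionally `se` (rows with
#'   missing values are dropped); the `r_by_bin` element of [run_dstats()]
#'   works directly (one site class at a time).
#' @param out_dir Optional output directory for the report and curve
#'   samples.
#' @param ... Passed to [fit_r0()].
#' @return The `rate_fit` object.
#' @export
run_rate_fit <- function(r_by_bin, out_dir = NULL, ...) {
  usable <- r_by_bin[is.finite(r_by_bin$fst) & is.finite(r_by_bin$r), ]
  if (nrow(usable) < 2) abort("fewer than 2 usable bins.")
  fit <- fit_r0(usable, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(tidy(fit), file.path(out_dir, "rate_fit_bins.tsv"))
    curve <- tibble::tibble(fst = seq(0, 1, length.out = 101))
    curve$r <- r_from_fst(curve$fst, fit$r0_hat)
    write_result_tsv(curve, file.path(out_dir, "rate_fit_curve.tsv"))
    writeLines(c(sprintf("r0_hat\t%.6f", fit$r0_hat),
                 sprintf("se\t%.6f", fit$se),
                 sprintf("n_bins\t%d", fit$n_bins),
                 sprintf("weighted_rss\t%.6g", fit$rss)),
               file.path(out_dir, "rate_fit_report.tsv"))
  }
  fit
}

#' Dispatch a synthetic-data generator by model name
#'
#' Front end for the simulators: `"im_pair"`, `"im_landscape"`,
#' `"stepping_stone"`, `"site_patterns"` or `"block_ancestry"`. The seed
#' is mandatory; outputs are bit-reproducible given (model, params, seed).
#'
#' @param model Model name.
#' @param params Named list of arguments for the generator.
#' @param seed Integer seed.
#' @param out_dir Optional directory; the landscape model writes a VCF and
#'   window annotations, the others write their tibbles as TSV, all with
#'   seed and config hash embedded.
#' @return The generator's value.
#' @export
run_simulation <- function(model, params = list(), seed = NULL,
                           out_dir = NULL) {
  models <- c("im_pair", "im_landscape", "stepping_stone", "site_patterns",
              "block_ancestry")
  if (!model %in% models) {
    abort(paste0("unknown model '", model, "'; available: ",
                 paste(models, collapse = ", ")))
  }
  if (is.null(seed)) abort("a `seed` is required for stochastic generators.")
  fn <- switch(model,
               im_pair = simulate_im_pair,
               im_landscape = simulate_im_landscape,
               stepping_stone = simulate_stepping_stone,
               site_patterns = simulate_site_patterns,
               block_ancestry = simulate_block_ancestry)
  res <- do.call(fn, c(params, list(seed = seed)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(seed = as.character(seed),
              config_hash = rlang::hash(params), model = model)
    if (model == "im_landscape") {
      write_genotypes_vcf(res$genotypes,
                          file.path(out_dir, "landscape.vcf"), meta = meta)
      write_result_tsv(res$windows, file.path(out_dir, "windows.tsv"),
                       config = params, seed = seed)
    } else if (model == "block_ancestry") {
      flat <- purrr::map_dfr(seq_len(nrow(res)), function(i) {
        d <- res$dosage[[i]]
        colnames(d) <- paste0("ind", seq_len(ncol(d)))
        dplyr::bind_cols(tibble::tibble(replicate = res$replicate[i],
                                        position = seq_len(nrow(d)) - 1),
                         tibble::as_tibble(d))
      })
      write_result_tsv(flat, file.path(out_dir, "ancestry_dosage.tsv"),
                       config = params, seed = seed)
    } else {
      write_result_tsv(res, file.path(out_dir, paste0(model, ".tsv")),
                       config = params, seed = seed)
    }
  }
  res
}
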