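#' Read a multi-sample VCF into a dosage genotype table
#'
#' Reads biallelic SNPs from a VCF (plain or bgzipped) into the tidy
#' genotype layout used across the package: one row per site, one
#' alternate-allele dosage column (0/1/2, `NA` for missing) per sample.
#' Multiallelic and indel records are skipped with a message reporting the
#' count. VCF positions (1-based) are converted to 0-based.
#'
#' @param path Path to the VCF file.
#' @return Tibble with `chrom`, `pos` (0-based) and one column per sample.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " multiallelic/indel record(s) skipped.")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  dose <- apply(gt, 2, function(col) {
    cleaned <- gsub("|", "/", col, fixed = TRUE)
    out <- rep(NA_real_, length(col))
    out[cleaned %in% c("0/0", "0")] <- 0
    out[cleaned %in% c("0/1", "1/0")] <- 1
    out[cleaned %in% c("1/1", "1")] <- 2
    out
  })
  out <- tibble::tibble(chrom = fix[keep, "CHROM"],
                        pos = as.numeric(fix[keep, "POS"]) - 1)
  dplyr::bind_cols(out, tibble::as_tibble(dose))
}

#' Write a genotype table as a minimal VCF
#'
#' Emits the package's tidy genotype table (alternate-allele dosage per
#' sample) as an uncompressed VCFv4.2 file with synthetic REF/ALT alleles,
#' embedding the generating seed/configuration hash as header lines.
#'
#' @param genotypes Genotype tibble (`chrom`, `pos` 0-based, sample
#'   columns).
#' @param path Output path.
#' @param meta Optional named character vector written as `##key=value`
#'   header lines (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, meta = NULL) {
  samples <- setdiff(names(genotypes), c("chrom", "pos"))
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  body <- vapply(samples, function(s) gt_code(genotypes[[s]]),
                 character(nrow(genotypes)))
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(meta)) paste0("##", names(meta), "=", meta),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- cbind(genotypes$chrom, format(genotypes$pos + 1, scientific = FALSE,
                                        trim = TRUE),
                ".", "A", "T", ".", "PASS", ".", "GT", body)
  writeLines(c(header, apply(rows, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a two-column sample-to-population map
#'
#' @param path Whitespace- or tab-delimited file with columns sample,
#'   population (no header).
#' @return Tibble with `sample`, `population`.
#' @export
read_pop_map <- function(path) {
  tb <- readr::read_table(path, col_names = c("sample", "population"),
                          col_types = "cc", progress = FALSE)
  if (nrow(tb) == 0) abort("empty population map.")
  tb
}

#' Read per-marker local-ancestry dosage tables
#'
#' Reads one TSV per replicate run (columns: chromosome, position, one
#' dosage column per individual; dosages on the 0-2 diploid scale or
#' already as fractions) and stacks them with a `replicate` column.
#'
#' @param paths Character vector of TSV paths, one per replicate.
#' @param scale `"auto"` (default: divide by 2 when values exceed 1),
#'   `"dosage"` (always divide by 2) or `"fraction"`.
#' @return Tibble: `replicate`, `chrom`, `position`, individual columns as
#'   p1 fractions.
#' @export
read_dosage_tsv <- function(paths, scale = c("auto", "dosage", "fraction")) {
  scale <- match.arg(scale)
  purrr::map_dfr(seq_along(paths), function(i) {
    tb <- readr::read_tsv(paths[i], show_col_types = FALSE, progress = FALSE)
    names(tb)[1:2] <- c("chrom", "position")
    ind <- setdiff(names(tb), c("chrom", "position"))
    vals <- as.matrix(tb[ind])
    div <- switch(scale,
                  auto = if (max(vals, na.rm = TRUE) > 1) 2 else 1,
                  dosage = 2, fraction = 1)
    tb[ind] <- vals / div
    dplyr::bind_cols(tibble::tibble(replicate = i), tb)
  })
}

#' Read a BED file of site classes or masks
#'
#' @param path BED3+ file (0-based, half-open), optional 4th column used as
#'   the feature name.
#' @return Tibble with `chrom`, `start`, `end` and (if present) `name`.
#' @export
read_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(tb)[1:3] <- c("chrom", "start", "end")
  if (ncol(tb) >= 4) names(tb)[4] <- "name"
  tb[, 1:min(4, ncol(tb))]
}

#' Label sites with the BED feature covering them
#'
#' @param sites Tibble with `chrom`, `pos` (0-based).
#' @param bed Tibble from [read_bed()]; overlapping features take the first
#'   match in file order.
#' @param label Column name to create (default `"site_class"`); uncovered
#'   sites get `"other"`.
#' @return `sites` with the class column added.
#' @export
classify_sites <- function(sites, bed, label = "site_class") {
  sites <- tibble::as_tibble(sites)
  cls <- rep("other", nrow(sites))
  for (ch in unique(sites$chrom)) {
    b <- bed[bed$chrom == ch, ]
    si <- which(sites$chrom == ch)
    if (!nrow(b) || !length(si)) next
    for (k in rev(seq_len(nrow(b)))) {
      hit <- sites$pos[si] >= b$start[k] & sites$pos[si] < b$end[k]
      cls[si[hit]] <- if ("name" %in% names(b)) b$name[k] else "feature"
    }
  }
  sites[[label]] <- cls
  sites
}

#' Write a tab-separated results table with a provenance header
#'
#' Prepends `#`-prefixed comment lines recording the package version, a
#' hash of the generating configuration and the seed, so reruns are
#' byte-identical and self-describing. Missing values are written as "NA".
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param config Optional list hashed into the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, config = NULL, seed = NULL) {
  hdr <- c(paste0("# ratemixr ", as.character(utils::packageVersion("ratemixr"))),
           if (!is.null(config)) paste0("# config_hash=", rlang::hash(config)),
           if (!is.null(seed)) paste0("# seed=", seed))
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(x, path, append = TRUE, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  )
  invisible(path)
}
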