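#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-SNP association statistics for one
#' study and returns a data frame with standardized column names. Rows with
#' missing or non-numeric values in required numeric fields, or with a
#' non-positive standard error, are dropped (a message reports the count).
#'
#' @param path Path to a whitespace- or tab-delimited file with a header row.
#' @param column_map Named character vector mapping internal field names to
#'   column names in the file. Required fields: `snp`, `chr`, `bp`, `a1`
#'   (effect allele), `a2` (other allele), `beta`, `se`. Optional fields:
#'   `freq` (effect-allele frequency) and `n` (per-SNP sample size); drop
#'   them from the map if the file lacks them, in which case the returned
#'   columns are `NA`.
#'
#' @return A data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `freq`, `beta`, `se`, `n`.
#' @export
read_sumstats <- function(path,
                          column_map = c(snp = "SNP", chr = "CHR", bp = "BP",
                                         a1 = "A1", a2 = "A2", freq = "FREQ",
                                         beta = "BETA", se = "SE", n = "N")) {
  if (!file.exists(path)) {
    stop("cannot read summary statistics file: ", path, call. = FALSE)
  }
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  required <- c("snp", "chr", "bp", "a1", "a2", "beta", "se")
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map) > 0) {
    stop("column_map lacks required fields: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  for (f in names(column_map)) {
    if (!column_map[[f]] %in% names(tab)) {
      if (f %in% required) {
        stop("required column not found in ", path, ": '", column_map[[f]],
             "' (field ", f, ")", call. = FALSE)
      }
      column_map <- column_map[names(column_map) != f]
    }
  }
  get_col <- function(f, numeric = FALSE) {
    if (!f %in% names(column_map)) return(rep(NA_real_, nrow(tab)))
    x <- tab[[column_map[[f]]]]
    if (numeric) suppressWarnings(as.numeric(x)) else as.character(x)
  }
  out <- data.frame(
    snp_id = get_col("snp"),
    chrom = normalize_chrom(get_col("chr")),
    pos = get_col("bp", numeric = TRUE),
    effect_allele = toupper(get_col("a1")),
    other_allele = toupper(get_col("a2")),
    freq = get_col("freq", numeric = TRUE),
    beta = get_col("beta", numeric = TRUE),
    se = get_col("se", numeric = TRUE),
    n = get_col("n", numeric = TRUE),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    warning("no data rows in ", path, call. = FALSE)
    return(out)
  }
  ok <- !is.na(out$pos) & !is.na(out$beta) & !is.na(out$se) & out$se > 0 &
    !is.na(out$snp_id) & nzchar(out$snp_id)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message(n_drop, " row(s) dropped for missing/invalid required fields in ",
            path)
  }
  out[ok, , drop = FALSE]
}

normalize_chrom <- function(x) {
  sub("^chr", "", tolower(as.character(x)))
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two studies on SNP id and aligns the outcome study's
#' alleles to the exposure study's effect allele: if the outcome lists the
#' same pair of alleles in swapped orientation, the sign of its effect
#' estimate is flipped and its allele frequency replaced by one minus the
#' frequency. SNPs whose alleles match neither orientation are dropped, as
#' are (by default) strand-ambiguous A/T and C/G SNPs, whose orientation
#' cannot be resolved from allele labels alone.
#'
#' @param x_records,y_records Data frames as returned by [read_sumstats()]
#'   for the exposure and outcome study.
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) SNPs (default
#'   `TRUE`).
#'
#' @return A harmonized data frame with one row per retained SNP and columns
#'   `snp_id`, `chrom`, `pos`, `ea`, `oa`, `maf`, `beta_x`, `se_x`, `n_x`,
#'   `beta_y`, `se_y`, `n_y`, `z_x`, `z_y`.
#' @export
harmonize_pair <- function(x_records, y_records, drop_ambiguous = TRUE) {
  for (nm in c("x", "y")) {
    rec <- if (nm == "x") x_records else y_records
    dup <- unique(rec$snp_id[duplicated(rec$snp_id)])
    if (length(dup) > 0) {
      stop("duplicate snp_id in ", nm, " study: ",
           paste(head(dup, 10), collapse = ", "), call. = FALSE)
    }
  }
  common <- intersect(x_records$snp_id, y_records$snp_id)
  x <- x_records[match(common, x_records$snp_id), , drop = FALSE]
  y <- y_records[match(common, y_records$snp_id), , drop = FALSE]

  same <- y$effect_allele == x$effect_allele &
    y$other_allele == x$other_allele
  swapped <- y$effect_allele == x$other_allele &
    y$other_allele == x$effect_allele
  keep <- same | swapped
  if (drop_ambiguous) {
    keep <- keep & !is_strand_ambiguous(x$effect_allele, x$other_allele)
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " SNP(s) dropped during harmonization ",
            "(incompatible or ambiguous alleles)")
  }
  x <- x[keep, , drop = FALSE]
  y <- y[keep, , drop = FALSE]
  flip <- swapped[keep]
  beta_y <- ifelse(flip, -y$beta, y$beta)

  freq <- x$freq
  out <- data.frame(
    snp_id = x$snp_id, chrom = x$chrom, pos = x$pos,
    ea = x$effect_allele, oa = x$other_allele,
    maf = ifelse(is.na(freq), NA_real_, pmin(freq, 1 - freq)),
    beta_x = x$beta, se_x = x$se, n_x = x$n,
    beta_y = beta_y, se_y = y$se, n_y = y$n,
    stringsAsFactors = FALSE
  )
  out$z_x <- out$beta_x / out$se_x
  out$z_y <- out$beta_y / out$se_y
  rownames(out) <- NULL
  out
}

#' Put effect estimates on the standardized scale
#'
#' Mode `"z_per_sqrt_n"` rescales each study's estimates to
#' \eqn{\hat\beta = z/\sqrt{n}} with standard error \eqn{1/\sqrt{n}}, the
#' standardized scale on which the mixture model's variance components are
#' expressed. Mode `"raw"` returns the input unchanged; the caller then
#' asserts the estimates are already on a comparable standardized scale.
#'
#' @param records Harmonized data frame from [harmonize_pair()].
#' @param mode `"z_per_sqrt_n"` or `"raw"`.
#' @return The records with `beta_x`, `se_x`, `beta_y`, `se_y` rescaled
#'   (z-statistics are unchanged by construction).
#' @export
standardize_effects <- function(records, mode = c("z_per_sqrt_n", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(records)
  if (any(is.na(records$n_x)) || any(is.na(records$n_y))) {
    stop("z_per_sqrt_n standardization requires per-SNP sample sizes",
         call. = FALSE)
  }
  records$beta_x <- records$z_x / sqrt(records$n_x)
  records$se_x <- 1 / sqrt(records$n_x)
  records$beta_y <- records$z_y / sqrt(records$n_y)
  records$se_y <- 1 / sqrt(records$n_y)
  records
}

#' Quality-control configuration
#'
#' Thresholds for [apply_qc_filters()]. Defaults follow common practice for
#' polygenic two-sample MR with HapMap3-type SNP panels: common SNPs only,
#' removal of the extended MHC region, removal of SNPs with extreme z
#' statistics that would unduly influence the mixture fit, and removal of
#' SNPs genotyped in unusually small subsets of each study.
#'
#' @param maf_min Minimum minor-allele frequency; SNPs with `maf <= maf_min`
#'   are dropped. Default 0.05.
#' @param mhc_chrom,mhc_start,mhc_end MHC region (1-based, inclusive);
#'   default chromosome 6, 26--34 Mb.
#' @param z2_max Maximum squared z statistic in either study. Default 80.
#' @param n_fraction SNPs whose per-SNP sample size falls below
#'   `n_fraction` times the 90th percentile of that study's sample-size
#'   distribution are dropped. Default 2/3.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, mhc_chrom = "6", mhc_start = 26e6,
                      mhc_end = 34e6, z2_max = 80, n_fraction = 2 / 3) {
  stopifnot(maf_min > 0, mhc_start > 0, mhc_end >= mhc_start, z2_max > 0,
            n_fraction > 0)
  structure(list(maf_min = maf_min, mhc_chrom = normalize_chrom(mhc_chrom),
                 mhc_start = mhc_start, mhc_end = mhc_end, z2_max = z2_max,
                 n_fraction = n_fraction),
            class = "qc_config")
}

#' Apply quality-control filters to harmonized summary statistics
#'
#' Drops SNPs failing any of: minor-allele frequency at or below the
#' threshold; position inside the MHC region; squared z statistic above the
#' threshold in either study; per-SNP sample size below a fraction of the
#' 90th percentile of that study's sample sizes. Filters are evaluated on
#' the input records independently, so the retained set does not depend on
#' the order of the rules. Per-rule drop counts are reported via `message()`
#' and attached as attribute `"qc_counts"`. SNPs with missing `maf` or `n`
#' pass the corresponding filter.
#'
#' @param records Harmonized data frame from [harmonize_pair()].
#' @param config A [qc_config()] object.
#' @return The filtered records (possibly empty, with a warning).
#' @export
apply_qc_filters <- function(records, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  maf_fail <- !is.na(records$maf) & records$maf <= config$maf_min
  mhc_fail <- records$chrom == config$mhc_chrom &
    records$pos >= config$mhc_start & records$pos <= config$mhc_end
  z2_fail <- records$z_x^2 > config$z2_max | records$z_y^2 > config$z2_max
  n_fail <- rep(FALSE, nrow(records))
  for (col in c("n_x", "n_y")) {
    n <- records[[col]]
    if (all(is.na(n))) next
    cutoff <- config$n_fraction * quantile(n, 0.9, na.rm = TRUE, names = FALSE)
    n_fail <- n_fail | (!is.na(n) & n < cutoff)
  }
  counts <- c(maf = sum(maf_fail), mhc = sum(mhc_fail), z2 = sum(z2_fail),
              sample_size = sum(n_fail))
  if (sum(counts) > 0) {
    message("QC drops - maf: ", counts[["maf"]], ", mhc: ", counts[["mhc"]],
            ", z2: ", counts[["z2"]], ", sample_size: ",
            counts[["sample_size"]])
  }
  out <- records[!(maf_fail | mhc_fail | z2_fail | n_fail), , drop = FALSE]
  if (nrow(out) == 0) warning("all SNPs removed by QC filters", call. = FALSE)
  attr(out, "qc_counts") <- counts
  out
}

#' Select genetic instruments by exposure association p-value
#'
#' Keeps SNPs whose two-sided normal (z-test) p-value for association with
#' the exposure falls below the threshold. When `selection_z` is supplied
#' (a named vector of z statistics from an independent selection study),
#' selection uses those statistics while the retained effect estimates come
#' from the estimation records -- the three-sample design that avoids
#' winner's curse at liberal thresholds.
#'
#' @param records Harmonized (and typically QC-filtered) data frame.
#' @param p_threshold Two-sided p-value threshold, in (0, 1). Default
#'   `5e-8` (genome-wide significance).
#' @param selection_z Optional named numeric vector of selection-study z
#'   statistics, named by `snp_id`; SNPs absent from it are not selected.
#' @return The selected instrument records.
#' @export
select_instruments <- function(records, p_threshold = 5e-8,
                               selection_z = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (is.null(selection_z)) {
    z <- records$z_x
  } else {
    z <- selection_z[match(records$snp_id, names(selection_z))]
  }
  p <- 2 * pnorm(-abs(z))
  keep <- !is.na(p) & p < p_threshold
  records[keep, , drop = FALSE]
}

#' Write a harmonized paired table as TSV
#'
#' Fixed column order: snp_id, chrom, pos, ea, oa, maf, beta_x, se_x, n_x,
#' beta_y, se_y, n_y.
#' @param records Harmonized data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(records, path) {
  cols <- c("snp_id", "chrom", "pos", "ea", "oa", "maf", "beta_x", "se_x",
            "n_x", "beta_y", "se_y", "n_y")
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
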