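test_that("read_sumstats reads well-formed tables and drops bad rows", {
  study <- make_study(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                      se = c(0.01, 0.02, 0.01))
  path <- write_study_file(study)
  rec <- read_sumstats(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(rec$beta, c(0.1, -0.2, 0.05))

  # empty standard-error cell -> row dropped, count reported
  lines <- readLines(path)
  lines[3] <- sub("0.02", "NA", lines[3])
  writeLines(lines, path)
  expect_message(rec2 <- read_sumstats(path), "1 row")
  expect_equal(nrow(rec2), 2)

  # header-only file -> empty with a warning
  writeLines(lines[1], path)
  expect_warning(rec3 <- read_sumstats(path), "no data rows")
  expect_equal(nrow(rec3), 0)
})

test_that("read_sumstats fails loudly on missing files and columns", {
  expect_error(read_sumstats(tempfile()), "cannot read")
  path <- write_study_file(make_study("rs1", 0.1, 0.01))
  expect_error(
    read_sumstats(path, column_map = c(snp = "SNP", chr = "CHR", bp = "BP",
                                       a1 = "A1", a2 = "A2",
                                       beta = "EFFECT", se = "SE")),
    "EFFECT")
})

test_that("harmonize_pair aligns alleles, flipping beta_y when swapped", {
  x <- make_study("rs1", 0.1, 0.01, effect_allele = "A", other_allele = "G")
  y_swapped <- make_study("rs1", 0.3, 0.01, effect_allele = "G",
                          other_allele = "A", freq = 0.7)
  h <- harmonize_pair(x, y_swapped)
  expect_equal(h$beta_y, -0.3)
  expect_equal(h$ea, "A")

  y_same <- make_study("rs1", 0.3, 0.01)
  h2 <- harmonize_pair(x, y_same)
  expect_equal(h2$beta_y, 0.3)
  expect_equal(h2$beta_x, 0.1)

  y_bad <- make_study("rs1", 0.3, 0.01, effect_allele = "C",
                      other_allele = "T")
  expect_message(h3 <- harmonize_pair(x, y_bad), "dropped")
  expect_equal(nrow(h3), 0)
})

test_that("harmonize_pair drops strand-ambiguous SNPs unless kept", {
  x <- make_study(c("rs1", "rs2"), c(0.1, 0.2), 0.01,
                  effect_allele = c("A", "A"), other_allele = c("T", "G"))
  y <- make_study(c("rs1", "rs2"), c(0.3, 0.4), 0.01,
                  effect_allele = c("A", "A"), other_allele = c("T", "G"))
  expect_message(h <- harmonize_pair(x, y), "1 SNP")
  expect_equal(h$snp_id, "rs2")
  h_keep <- harmonize_pair(x, y, drop_ambiguous = FALSE)
  expect_equal(nrow(h_keep), 2)
})

test_that("harmonize_pair rejects duplicate SNP ids", {
  x <- make_study(c("rs1", "rs1"), c(0.1, 0.2), 0.01)
  y <- make_study("rs1", 0.3, 0.01)
  expect_error(harmonize_pair(x, y), "rs1")
})

test_that("harmonization is idempotent and orientation-invariant", {
  set.seed(4)
  K <- 8
  x <- make_study(paste0("rs", 1:K), rnorm(K, 0, 0.1), 0.01,
                  effect_allele = rep(c("A", "C"), 4),
                  other_allele = rep(c("G", "T"), 4))
  y <- x
  flip <- c(2, 5, 7)
  y$effect_allele[flip] <- x$other_allele[flip]
  y$other_allele[flip] <- x$effect_allele[flip]
  y$beta <- rnorm(K, 0, 0.1)
  y$beta[flip] <- -y$beta[flip]
  h1 <- harmonize_pair(x, y)

  # re-harmonizing the harmonized outcome records changes nothing
  y2 <- make_study(h1$snp_id, h1$beta_y, h1$se_y, effect_allele = h1$ea,
                   other_allele = h1$oa, pos = h1$pos)
  h2 <- harmonize_pair(x, y2)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$ea, h1$ea)

  # flipping stored allele labels plus the sign of beta_y in the input
  # yields the identical harmonized output
  y3 <- y
  y3$effect_allele <- y$other_allele
  y3$other_allele <- y$effect_allele
  y3$beta <- -y$beta
  y3$freq <- 1 - y$freq
  h3 <- harmonize_pair(x, y3)
  expect_equal(h3$beta_y, h1$beta_y)
  expect_equal(h3$snp_id, h1$snp_id)
})

test_that("standardize_effects puts estimates on the z/sqrt(n) scale", {
  h <- proportional_instruments(K = 2, slope = 0.5)
  h$n_x <- c(10000, 40000)
  h$z_x <- c(5, 5)
  st <- standardize_effects(h, "z_per_sqrt_n")
  expect_equal(st$beta_x, c(5 / sqrt(10000), 5 / sqrt(40000)))
  expect_equal(st$se_x, c(0.01, 0.005))
  expect_identical(standardize_effects(h, "raw"), h)
  h$n_y <- NA_real_
  expect_error(standardize_effects(h, "z_per_sqrt_n"), "sample sizes")
})

test_that("QC filters drop MHC, extreme-z, rare and under-sampled SNPs", {
  h <- proportional_instruments(K = 10, slope = 0.5, se = 1)
  h$beta_x <- rep(1, 10)
  h$beta_y <- rep(0.5, 10)
  h$z_x <- h$beta_x / h$se_x
  h$z_y <- h$beta_y / h$se_y
  h$n_x <- h$n_y <- rep(300, 10)
  h$maf <- 0.3

  h$chrom[1] <- "6"; h$pos[1] <- 30e6          # inside MHC
  h$chrom[2] <- "6"; h$pos[2] <- 25e6          # chr6 but outside MHC
  h$z_x[3] <- 9                                 # z^2 = 81 > 80
  h$z_x[4] <- 8.8                               # z^2 = 77.4, kept
  h$maf[5] <- 0.04                              # below MAF threshold
  h$maf[6] <- 0.05                              # at threshold -> dropped
  h$n_x[7] <- 100                               # < (2/3) * 300 = 200

  out <- suppressMessages(apply_qc_filters(h))
  kept <- out$snp_id
  expect_false("rs1" %in% kept)
  expect_true("rs2" %in% kept)
  expect_false("rs3" %in% kept)
  expect_true("rs4" %in% kept)
  expect_false("rs5" %in% kept)
  expect_false("rs6" %in% kept)
  expect_false("rs7" %in% kept)
  expect_true(all(kept %in% h$snp_id))
})

test_that("QC result is rule-order independent and a subset of input", {
  set.seed(11)
  h <- proportional_instruments(K = 50, slope = 0.3, se = 0.05)
  h$z_x <- rnorm(50, 0, 6); h$z_y <- rnorm(50, 0, 6)
  h$maf <- runif(50, 0.01, 0.5)
  h$chrom <- as.character(sample(1:22, 50, replace = TRUE))
  h$pos <- sample(1e6:5e7, 50)
  h$n_x <- sample(100:1000, 50)
  h$n_y <- sample(100:1000, 50)

  all_at_once <- suppressMessages(suppressWarnings(apply_qc_filters(h)))
  # sequential application in two different orders; the per-study n
  # percentile is evaluated on the original records in both cases
  cfg <- qc_config()
  one_rule <- function(d, rule) {
    keep <- switch(rule,
      maf = !(!is.na(d$maf) & d$maf <= cfg$maf_min),
      mhc = !(d$chrom == "6" & d$pos >= 26e6 & d$pos <= 34e6),
      z2 = !(d$z_x^2 > 80 | d$z_y^2 > 80),
      n = {
        cut_x <- cfg$n_fraction * quantile(h$n_x, 0.9, names = FALSE)
        cut_y <- cfg$n_fraction * quantile(h$n_y, 0.9, names = FALSE)
        !(d$n_x < cut_x | d$n_y < cut_y)
      })
    d[keep, , drop = FALSE]
  }
  seq1 <- one_rule(one_rule(one_rule(one_rule(h, "maf"), "mhc"), "z2"), "n")
  seq2 <- one_rule(one_rule(one_rule(one_rule(h, "n"), "z2"), "mhc"), "maf")
  expect_equal(all_at_once$snp_id, seq1$snp_id)
  expect_equal(seq1$snp_id, seq2$snp_id)
})

test_that("instrument selection thresholds match an independent quantile", {
  # two-sided p < 5e-8 corresponds to |z| > qnorm(1 - 2.5e-8) ~ 5.451
  zcrit <- qnorm(1 - 2.5e-8)
  expect_true(zcrit > 5.44 && zcrit < 5.46)
  h <- proportional_instruments(K = 2, slope = 0.5)
  h$z_x <- c(5.46, 5.44)
  sel <- select_instruments(h, 5e-8)
  expect_equal(sel$snp_id, "rs1")
})

test_that("selection is monotone in the threshold", {
  set.seed(9)
  h <- proportional_instruments(K = 200, slope = 0.5)
  h$z_x <- rnorm(200, 0, 4)
  strict <- select_instruments(h, 5e-8)
  liberal <- select_instruments(h, 0.005)
  expect_true(all(strict$snp_id %in% liberal$snp_id))
  expect_gte(nrow(liberal), nrow(strict))
})

test_that("three-sample selection keeps estimation-study coefficients", {
  h <- proportional_instruments(K = 3, slope = 0.5)
  h$z_x <- c(2, 10, 3)  # only rs2 significant in the estimation study
  sel_z <- c(rs1 = 10, rs3 = 8)  # rs1, rs3 significant in selection study
  sel <- select_instruments(h, 5e-8, selection_z = sel_z)
  expect_setequal(sel$snp_id, c("rs1", "rs3"))
  # estimation-study values are the ones retained
  expect_equal(sel$beta_x, h$beta_x[match(sel$snp_id, h$snp_id)])
})
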