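# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# Minimal per-study record table in read_sumstats() output format.
make_study <- function(snp_id, beta, se, effect_allele = "A",
                       other_allele = "G", chrom = "1",
                       pos = seq_along(snp_id) * 1000, freq = 0.3,
                       n = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             freq = freq, beta = beta, se = se, n = n,
             stringsAsFactors = FALSE)
}

# Instrument table (harmonized format) with exact proportionality
# beta_y = slope * beta_x and noise-free outcome values.
proportional_instruments <- function(K = 20, slope = 0.5, se = 1e-4,
                                     bx = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(bx)) bx <- runif(K, 0.05, 0.15)
  data.frame(snp_id = paste0("rs", seq_len(K)), chrom = "1",
             pos = seq_len(K) * 1000, ea = "A", oa = "G", maf = 0.3,
             beta_x = bx, se_x = se, n_x = 1 / se^2,
             beta_y = slope * bx, se_y = se, n_y = 1 / se^2,
             z_x = bx / se, z_y = slope * bx / se,
             stringsAsFactors = FALSE)
}

# Seeded Scenario-A replicate: effects, full table and selected instruments.
scenario_a_replicate <- function(n_x = 2e5, theta = 0.2, valid_frac = 0.5,
                                 C = 1, seed = 1, M = 2e5, ...) {
  cfg <- sim_config(M = M, n_x = n_x, theta = theta,
                    valid_frac = valid_frac, C = C, ...)
  set.seed(seed)
  eff <- simulate_true_effects(cfg)
  sim <- simulate_sumstats(eff, cfg)
  c(sim, list(config = cfg, effects = eff))
}

# Write a study table to a temp file in the default column layout.
write_study_file <- function(study, path = tempfile(fileext = ".tsv")) {
  out <- data.frame(SNP = study$snp_id, CHR = study$chrom, BP = study$pos,
                    A1 = study$effect_allele, A2 = study$other_allele,
                    FREQ = study$freq, BETA = study$beta, SE = study$se,
                    N = study$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Dense 2-D likelihood-grid maximizer for the constrained two-component
# mixture: the independent oracle for the EM fit.
brute_force_two_component <- function(residuals, null_var, eps = 1e-6,
                                      pi_step = 0.01, sigma2_max = 400,
                                      n_sigma2 = 400) {
  v <- rep_len(null_var, length(residuals))
  floor_ <- (1 + eps) * max(v)
  pis <- seq(0, 1, by = pi_step)
  s2s <- exp(seq(log(floor_), log(sigma2_max), length.out = n_sigma2))
  lf0 <- dnorm(residuals, 0, sqrt(v), log = TRUE)
  best <- list(ll = -Inf)
  for (s2 in s2s) {
    lf1 <- dnorm(residuals, 0, sqrt(s2), log = TRUE)
    for (p in pis) {
      la <- log(p) + lf0
      lb <- log1p(-p) + lf1
      ll <- if (p == 0) sum(lf1) else if (p == 1) sum(lf0) else
        sum(pmax(la, lb) + log1p(exp(-abs(la - lb))))
      if (ll > best$ll) best <- list(ll = ll, pi0 = p, sigma2 = s2)
    }
  }
  best
}
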