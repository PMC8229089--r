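# Two-sample synthetic cohorts with known causal structure.
#
# Genotypes follow a latent-Gaussian AR(1) LD model: per haplotype a latent
# N(0,1) vector with corr rho^|i-j| across adjacent SNPs is thresholded at
# qnorm(maf); the dosage is the sum of two independent haplotypes, so each
# SNP is marginally Binomial(2, maf) while neighbouring SNPs are correlated.
# Exposure cohort, outcome cohort and LD panel are independent draws from
# the same population (two-sample design).
#
# Trait model (per scenario; all traits scaled to unit variance in
# expectation, SNP effects specified as fractions of trait variance):
#   causal    : M = sum_k beta_k g_k + e;  E = theta_me * M + e;
#               Y = theta_ey * E + theta_my * M + background + e
#   pleiotropy: M as causal; Y = gamma * g_top + background + e  (one SNP
#               affects both M and Y via separate paths)
#   linkage   : SNP A -> M only; SNP B (in LD with A) -> Y only
#   reverse   : Y = sum_k alpha_k g_k + background + e;  M = theta_ym * Y + e
#   null      : M genetic as causal; Y = background + e; no M-Y connection
# "background" is a polygenic score over n_background unlinked SNPs carrying
# h2_background of Y's variance; it gives the outcome trait its own
# genome-wide significant instrument, which the reverse-causation filter
# needs in order to be testable at all.

.SCENARIOS <- c("causal", "pleiotropy", "linkage", "reverse", "null")

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults reflect a desk-scale two-sample design: 20,000 individuals per
#' cohort (so cis-QTL associations comfortably cross 5e-8), a 503-individual
#' LD reference panel, 200 SNPs per cis locus with AR(1)-like LD, and three
#' causal mQTL SNPs explaining 5/3/2\% of methylation variance.
#'
#' @param scenario one of `"causal"`, `"pleiotropy"`, `"linkage"`,
#'   `"reverse"`, `"null"`.
#' @param n_exposure,n_outcome,n_panel cohort sizes (exposure cohort supplies
#'   mQTL/eQTL statistics; outcome cohort supplies the GWAS; panel supplies
#'   LD only).  Cohorts must have >= 100 individuals.
#' @param n_snps SNPs in the cis locus.
#' @param maf_range interval in (0, 0.5] from which per-SNP MAFs are drawn.
#' @param ld_rho latent adjacent-SNP correlation in \[0, 1).
#' @param theta_mx variance fractions of methylation explained by the causal
#'   cis SNPs (one per causal SNP).
#' @param causal_idx column indices of the causal cis SNPs (default: spread
#'   over the locus interior).
#' @param theta_me methylation -> expression path coefficient.
#' @param theta_ey expression -> outcome path coefficient.
#' @param theta_my direct methylation -> outcome path (must be 0 in the
#'   reverse scenario).
#' @param theta_gy pleiotropy scenario: variance fraction of Y explained by
#'   the shared (top mQTL) SNP's direct path.
#' @param theta_by linkage scenario: variance fraction of Y explained by the
#'   linkage partner SNP.
#' @param linkage_sep linkage scenario: index separation between the
#'   M-causal SNP and the Y-causal SNP (controls their LD).
#' @param theta_yx reverse scenario: variance fractions of Y explained by
#'   its cis causal SNPs.
#' @param theta_ym reverse scenario: outcome -> methylation path coefficient.
#' @param h2_background fraction of Y variance carried by the unlinked
#'   polygenic background block.
#' @param n_background number of background SNPs.
#' @param probe_id,probe_chr,probe_pos,gene_id identifiers used when summary
#'   statistics are emitted.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = .SCENARIOS,
                            n_exposure = 20000L, n_outcome = 20000L,
                            n_panel = 503L, n_snps = 200L,
                            maf_range = c(0.05, 0.5), ld_rho = 0.8,
                            theta_mx = c(0.05, 0.03, 0.02),
                            causal_idx = NULL,
                            theta_me = 0.5, theta_ey = 0.1, theta_my = 0,
                            theta_gy = 0.002,
                            theta_by = 0.015, linkage_sep = 3L,
                            theta_yx = c(0.012, 0.008), theta_ym = 0.1,
                            h2_background = 0.2, n_background = 10L,
                            probe_id = "cg00000001", probe_chr = "1",
                            probe_pos = 1e8L, gene_id = "GENE1",
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (min(n_exposure, n_outcome, n_panel) < 100) {
    stop("cohort sizes must be >= 100")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (scenario == "reverse" && theta_my != 0) {
    stop("inconsistent effect specification: reverse scenario with ",
         "nonzero theta_my")
  }
  if (sum(theta_mx) > 1) stop("sum(theta_mx) must be <= 1")
  if (is.null(causal_idx)) {
    k <- length(theta_mx)
    causal_idx <- unique(pmax(1L, pmin(n_snps, as.integer(
      round(stats::quantile(seq_len(n_snps),
                            probs = seq(0.25, 0.75, length.out = k)))))))
    if (length(causal_idx) < k) stop("n_snps too small for causal SNP layout")
  }
  structure(list(scenario = scenario, n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 n_panel = as.integer(n_panel), n_snps = as.integer(n_snps),
                 maf_range = maf_range, ld_rho = ld_rho,
                 theta_mx = theta_mx, causal_idx = as.integer(causal_idx),
                 theta_me = theta_me, theta_ey = theta_ey,
                 theta_my = theta_my, theta_gy = theta_gy,
                 theta_by = theta_by, linkage_sep = as.integer(linkage_sep),
                 theta_yx = theta_yx, theta_ym = theta_ym,
                 h2_background = h2_background,
                 n_background = as.integer(n_background),
                 probe_id = probe_id, probe_chr = as.character(probe_chr),
                 probe_pos = as.integer(probe_pos), gene_id = gene_id,
                 seed = seed),
            class = "scenario_config")
}

# one dosage block: latent AR(1) haplotypes thresholded at qnorm(maf)
.sim_dosage_block <- function(n, maf, rho) {
  m <- length(maf)
  thr <- rep(qnorm(maf), each = n)
  hap <- function() {
    Z <- matrix(rnorm(n * m), n, m)
    if (rho > 0 && m > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
    }
    (Z < thr) + 0
  }
  hap() + hap()
}

# redraw panel columns that came out monomorphic (possible at small n)
.fix_monomorphic <- function(D, maf, rho) {
  bad <- which(apply(D, 2, stats::var) == 0)
  tries <- 0
  while (length(bad) && tries < 20) {
    message("resampling ", length(bad), " monomorphic panel column(s)")
    D[, bad] <- .sim_dosage_block(nrow(D), maf[bad], 0)
    bad <- which(apply(D, 2, stats::var) == 0)
    tries <- tries + 1
  }
  D
}

#' Simulate genotype dosages for the two cohorts and the LD panel
#'
#' See the scenario model description in [scenario_config()].  If
#' `config$seed` is non-`NULL` the RNG is seeded, so equal configs give
#' identical matrices.
#'
#' @param config a [scenario_config()].
#' @param snp_prefix prefix for generated SNP ids.
#' @return list of class `sim_geno` with dosage matrices `exposure`,
#'   `outcome`, `panel`, per-SNP metadata (`snp`, `a1`, `a2`, `chr`, `pos`,
#'   `maf`, `is_bg`) and the config.
#' @export
simulate_genotypes <- function(config, snp_prefix = "rs") {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cfg$n_snps
  nb <- cfg$n_background
  maf_cis <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  maf_bg <- runif(nb, cfg$maf_range[1], cfg$maf_range[2])
  maf <- c(maf_cis, maf_bg)

  gen <- function(n) {
    cis <- .sim_dosage_block(n, maf_cis, cfg$ld_rho)
    bg <- if (nb > 0) .sim_dosage_block(n, maf_bg, 0) else NULL
    cbind(cis, bg)
  }
  exposure <- gen(cfg$n_exposure)
  outcome <- gen(cfg$n_outcome)
  panel <- .fix_monomorphic(gen(cfg$n_panel), maf, cfg$ld_rho)

  # deterministic non-ambiguous allele pairs
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- (seq_len(m + nb) - 1) %% 4 + 1
  spacing <- 2e6 / m
  meta <- data.frame(
    snp = c(paste0(snp_prefix, seq_len(m)),
            if (nb > 0) paste0(snp_prefix, "bg", seq_len(nb))),
    a1 = pairs[pick, 1], a2 = pairs[pick, 2],
    chr = c(rep(cfg$probe_chr, m), rep("0", nb)),
    pos = c(as.integer(cfg$probe_pos - 1e6 + round((seq_len(m) - 0.5) *
                                                     spacing)),
            if (nb > 0) as.integer(seq_len(nb) * 1e6)),
    maf = maf, is_bg = c(rep(FALSE, m), rep(TRUE, nb)),
    stringsAsFactors = FALSE)
  colnames(exposure) <- colnames(outcome) <- colnames(panel) <- meta$snp
  structure(list(exposure = exposure, outcome = outcome, panel = panel,
                 meta = meta, config = cfg),
            class = "sim_geno")
}

# per-allele effect for a variance fraction v at minor allele frequency maf
.beta_from_h2 <- function(v, maf) sqrt(v / (2 * maf * (1 - maf)))

# population effect vectors for one scenario
.scenario_effects <- function(cfg, meta) {
  m <- cfg$n_snps
  beta_m <- numeric(m)     # SNP -> M
  alpha_y <- numeric(m)    # SNP -> Y (direct, cis)
  maf <- meta$maf[!meta$is_bg]
  ci <- cfg$causal_idx
  switch(cfg$scenario,
    causal = , pleiotropy = , null = {
      beta_m[ci] <- .beta_from_h2(cfg$theta_mx, maf[ci])
    },
    linkage = {
      beta_m[ci[1]] <- .beta_from_h2(cfg$theta_mx[1], maf[ci[1]])
    },
    reverse = {
      idx <- ci[seq_along(cfg$theta_yx)]
      alpha_y[idx] <- .beta_from_h2(cfg$theta_yx, maf[idx])
    })
  if (cfg$scenario == "pleiotropy") {
    alpha_y[ci[1]] <- .beta_from_h2(cfg$theta_gy, maf[ci[1]])
  }
  if (cfg$scenario == "linkage") {
    bidx <- ci[1] + cfg$linkage_sep
    if (bidx > m) stop("linkage partner SNP falls outside the locus")
    alpha_y[bidx] <- .beta_from_h2(cfg$theta_by, maf[bidx])
  }
  beta_bg <- if (cfg$n_background > 0) {
    .beta_from_h2(rep(cfg$h2_background / cfg$n_background,
                      cfg$n_background), meta$maf[meta$is_bg])
  } else numeric(0)
  list(beta_m = beta_m, alpha_y = alpha_y, beta_bg = beta_bg)
}

# traits for one cohort's dosage matrix
.cohort_traits <- function(D, cfg, eff) {
  n <- nrow(D)
  m <- cfg$n_snps
  cis <- D[, seq_len(m), drop = FALSE]
  gM <- as.vector(cis %*% eff$beta_m)
  gY <- as.vector(cis %*% eff$alpha_y)
  gB <- if (cfg$n_background > 0) {
    as.vector(D[, m + seq_len(cfg$n_background), drop = FALSE] %*%
                eff$beta_bg)
  } else numeric(n)
  h2b <- if (cfg$n_background > 0) cfg$h2_background else 0
  noise <- function(v) if (v > 1e-12) rnorm(n, sd = sqrt(v)) else numeric(n)

  if (cfg$scenario == "reverse") {
    vres <- 1 - sum(cfg$theta_yx) - h2b
    if (vres < 0) stop("Y variance overspecified in reverse scenario")
    Y <- gY + gB + noise(vres)
    M <- cfg$theta_ym * Y + noise(1 - cfg$theta_ym^2)
    E <- rnorm(n)
    return(list(M = M, E = E, Y = Y))
  }

  M <- gM + noise(1 - sum(eff$beta_m^2 *
                            (2 * cfg$maf_cis_used * (1 - cfg$maf_cis_used))))
  E <- if (cfg$scenario == "causal") {
    cfg$theta_me * M + noise(1 - cfg$theta_me^2)
  } else rnorm(n)
  Y <- switch(cfg$scenario,
    causal = {
      vpath <- cfg$theta_ey^2 + cfg$theta_my^2 +
        2 * cfg$theta_ey * cfg$theta_my * cfg$theta_me
      vres <- 1 - vpath - h2b
      if (vres < 0) stop("Y variance overspecified in causal scenario")
      cfg$theta_ey * E + cfg$theta_my * M + gB + noise(vres)
    },
    pleiotropy = gY + gB + noise(1 - cfg$theta_gy - h2b),
    linkage = gY + gB + noise(1 - cfg$theta_by - h2b),
    null = gB + noise(1 - h2b))
  list(M = M, E = E, Y = Y)
}

#' Simulate methylation, expression and outcome values for both cohorts
#'
#' @param geno a `sim_geno` from [simulate_genotypes()].
#' @param config the same [scenario_config()] (defaults to the one stored in
#'   `geno`).
#' @return list of class `sim_traits` with per-cohort trait vectors
#'   (`exposure$M/E/Y`, `outcome$M/E/Y`), the population effect vectors, and
#'   a ground-truth list.
#' @export
simulate_traits <- function(geno, config = geno$config) {
  cfg <- config
  if (cfg$scenario == "reverse" && cfg$theta_my != 0) {
    stop("inconsistent effect specification: reverse scenario with ",
         "nonzero theta_my")
  }
  eff <- .scenario_effects(cfg, geno$meta)
  # empirical maf actually used when scaling M's residual variance
  cfg$maf_cis_used <- geno$meta$maf[!geno$meta$is_bg]
  exposure <- .cohort_traits(geno$exposure, cfg, eff)
  outcome <- .cohort_traits(geno$outcome, cfg, eff)
  b_xy_true <- if (cfg$scenario == "causal") {
    cfg$theta_me * cfg$theta_ey + cfg$theta_my
  } else 0
  truth <- list(
    probe_id = cfg$probe_id, gene_id = cfg$gene_id,
    scenario = cfg$scenario, b_xy_true = b_xy_true,
    theta_me = if (cfg$scenario == "causal") cfg$theta_me else 0,
    theta_ey = if (cfg$scenario == "causal") cfg$theta_ey else 0,
    causal_snps = geno$meta$snp[!geno$meta$is_bg][cfg$causal_idx])
  structure(list(exposure = exposure, outcome = outcome, effects = eff,
                 truth = truth, config = cfg),
            class = "sim_traits")
}

#' Marginal per-SNP association statistics
#'
#' Simple linear regression of a trait on each dosage column; `p` is the
#' two-sided normal p-value of `b/se` (the convention of GWAS summary
#' files), floored at the smallest positive double.
#'
#' @param D dosage matrix (individuals x SNPs).
#' @param y trait vector.
#' @return data frame with `b`, `se`, `p`, `freq` (effect-allele frequency)
#'   and `n` per SNP.
#' @export
marginal_assoc <- function(D, y) {
  n <- nrow(D)
  Dc <- scale(D, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(Dc^2)
  sxy <- as.vector(crossprod(Dc, yc))
  b <- sxy / sxx
  syy <- sum(yc^2)
  rss <- pmax(syy - b * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  z <- b / se
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  data.frame(b = b, se = se, p = p, freq = colMeans(D) / 2, n = n)
}

# assemble a records data frame from meta + marginal stats
.records_from_assoc <- function(meta, st) {
  data.frame(snp = meta$snp, chr = meta$chr, pos = meta$pos, a1 = meta$a1,
             a2 = meta$a2, freq = st$freq, b = st$b, se = st$se, p = st$p,
             n = st$n, stringsAsFactors = FALSE)
}

#' Simulate a complete single-probe study in memory
#'
#' Runs [simulate_genotypes()] and [simulate_traits()] and computes summary
#' statistics under two-sample discipline: mQTL and eQTL statistics from the
#' exposure cohort, GWAS statistics from the outcome cohort, LD from the
#' panel.
#'
#' @param config a [scenario_config()].
#' @return list of class `sim_study` with components `mqtl` (cis
#'   [qtl_table()]), `m_stats` (genome-wide [sumstat_set()] for methylation,
#'   cis + background SNPs), `eqtl`, `e_stats` (ditto for expression),
#'   `gwas` ([sumstat_set()] for the outcome), `panel` ([ld_panel()]),
#'   `truth` and the config.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  tr <- simulate_traits(geno, config)
  cfg <- config
  meta <- geno$meta
  cis <- !meta$is_bg

  m_st <- marginal_assoc(geno$exposure, tr$exposure$M)
  e_st <- marginal_assoc(geno$exposure, tr$exposure$E)
  g_st <- marginal_assoc(geno$outcome, tr$outcome$Y)

  m_rec <- .records_from_assoc(meta, m_st)
  e_rec <- .records_from_assoc(meta, e_st)
  g_rec <- .records_from_assoc(meta, g_st)

  panel <- ld_panel(geno$panel, meta$snp, meta$a1, meta$a2)
  structure(list(
    mqtl = qtl_table(cfg$probe_id, cfg$probe_chr, cfg$probe_pos,
                     m_rec[cis, , drop = FALSE], validate = FALSE),
    m_stats = sumstat_set(cfg$probe_id, m_rec, validate = FALSE),
    eqtl = qtl_table(cfg$gene_id, cfg$probe_chr, cfg$probe_pos,
                     e_rec[cis, , drop = FALSE], validate = FALSE),
    e_stats = sumstat_set(cfg$gene_id, e_rec, validate = FALSE),
    gwas = sumstat_set("outcome", g_rec, validate = FALSE),
    panel = panel, truth = tr$truth, config = cfg),
    class = "sim_study")
}

#' Write a simulated study to disk in the package's text formats
#'
#' Emits `gwas.ma` (outcome GWAS), `methylation.ma` (genome-wide methylation
#' statistics, used by the reverse-causation filter), `mqtl.qtl.txt` /
#' `eqtl.qtl.txt` (cis tables), `panel.tsv` (LD panel dosages) and
#' `truth.tsv` (ground-truth table).
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
emit_sumstats <- function(study, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(gwas = file.path(out_dir, "gwas.ma"),
             methylation = file.path(out_dir, "methylation.ma"),
             mqtl = file.path(out_dir, "mqtl.qtl.txt"),
             eqtl = file.path(out_dir, "eqtl.qtl.txt"),
             panel = file.path(out_dir, "panel.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_sumstats(study$gwas, paths["gwas"], "ma")
  write_sumstats(study$m_stats, paths["methylation"], "ma")
  write_sumstats(study$mqtl, paths["mqtl"], "qtl")
  write_sumstats(study$eqtl, paths["eqtl"], "qtl")
  write_ld_panel(study$panel, paths["panel"])
  tru <- study$truth
  write_report(data.frame(probe_id = tru$probe_id, gene_id = tru$gene_id,
                          scenario = tru$scenario,
                          b_xy_true = tru$b_xy_true,
                          theta_me = tru$theta_me, theta_ey = tru$theta_ey,
                          causal_snps = paste(tru$causal_snps,
                                              collapse = ","),
                          stringsAsFactors = FALSE),
               paths["truth"])
  invisible(paths)
}

#' Simulate a multi-probe discovery study with planted scenarios
#'
#' Builds the standard discovery fixture: `n_probes` methylation probes on
#' independent cis loci, of which `n_causal` carry a genuine
#' methylation -> expression -> outcome chain and the remainder are decoys
#' (pleiotropy, linkage, reverse causation, null).  All probes share one
#' polygenic background block that gives the outcome trait its own
#' instrument.  Planted causal effects default to `theta_me = 0.5`,
#' `theta_ey = 0.4` (total effect 0.2) so that forward MR clears the
#' genome-wide threshold at the default cohort size; decoy effects are sized
#' so that each decoy is caught by the stage that targets it.
#'
#' Because loci are simulated independently, each locus's GWAS statistics
#' use an outcome realization in which the other loci's contributions are
#' absorbed into noise; with unlinked loci this leaves the joint
#' distribution of the emitted statistics essentially unchanged.
#'
#' @param n_probes total number of probes.
#' @param n_causal,n_pleiotropy,n_linkage,n_reverse scenario counts; the
#'   remaining probes are null.
#' @param seed integer seed for the whole study.
#' @param overrides named list of [scenario_config()] fields to override in
#'   every per-probe config (e.g. smaller `n_exposure` for quick tests).
#' @param n_decoy_genes decoy (null-effect) genes added per causal probe for
#'   mediator scanning.
#' @return list of class `sim_discovery` with `probes` (per-probe lists:
#'   `probe_id`, `scenario`, `mqtl`, `m_stats`, `eqtls`, `gene_id`),
#'   `gwas`, `panel`, `truth` (data frame) and `seed`.
#' @export
simulate_discovery_study <- function(n_probes = 50, n_causal = 3,
                                     n_pleiotropy = 3, n_linkage = 3,
                                     n_reverse = 3, seed = 1,
                                     overrides = list(),
                                     n_decoy_genes = 2) {
  stopifnot(n_causal + n_pleiotropy + n_linkage + n_reverse <= n_probes)
  set.seed(seed)
  scen <- c(rep("causal", n_causal), rep("pleiotropy", n_pleiotropy),
            rep("linkage", n_linkage), rep("reverse", n_reverse))
  scen <- c(scen, rep("null", n_probes - length(scen)))

  # decoy effects sized so each decoy reaches (and is caught by) the stage
  # that targets it: pleiotropy z_gwas ~ 12.6 (outlier removed surely),
  # reverse-probe mQTLs strong enough (z ~ 25 at the top) to pass SMR/HEIDI
  # and fall to the reverse filter
  # planted causal total effect 0.3: the top-SNP GWAS z is then ~9.5, so
  # P_SMR clears 5e-8 with ~4 sigma of margin (at total 0.2, z ~ 6.3, a
  # quarter of causal probes would miss the SMR threshold by chance)
  fixture_defaults <- list(theta_ey = 0.6, theta_gy = 0.008,
                           theta_yx = c(0.05, 0.03), theta_ym = 0.8,
                           seed = NULL)
  mk_cfg <- function(scenario, i) {
    args <- modifyList(fixture_defaults, overrides)
    args$scenario <- scenario
    args$probe_id <- sprintf("cg%08d", i)
    args$gene_id <- sprintf("GENE%03d", i)
    args$probe_chr <- as.character((i - 1) %% 22 + 1)
    args$probe_pos <- as.integer(1.5e7 + ((i - 1) %/% 22) * 1.2e7)
    do.call(scenario_config, args)
  }
  cfg1 <- mk_cfg("null", 1)

  # shared polygenic background block
  nb <- cfg1$n_background
  maf_bg <- runif(nb, cfg1$maf_range[1], cfg1$maf_range[2])
  beta_bg <- .beta_from_h2(rep(cfg1$h2_background / nb, nb), maf_bg)
  Dbg_exp <- .sim_dosage_block(cfg1$n_exposure, maf_bg, 0)
  Dbg_out <- .sim_dosage_block(cfg1$n_outcome, maf_bg, 0)
  Dbg_pan <- .fix_monomorphic(.sim_dosage_block(cfg1$n_panel, maf_bg, 0),
                              maf_bg, 0)
  gB_exp <- as.vector(Dbg_exp %*% beta_bg)
  gB_out <- as.vector(Dbg_out %*% beta_bg)
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- (seq_len(nb) - 1) %% 4 + 1
  bg_meta <- data.frame(snp = paste0("rsbg", seq_len(nb)),
                        a1 = pairs[pick, 1], a2 = pairs[pick, 2],
                        chr = "0", pos = as.integer(seq_len(nb) * 1e6),
                        maf = maf_bg, is_bg = TRUE, stringsAsFactors = FALSE)
  # background GWAS statistics from a background-only outcome realization
  Y_bg <- gB_out + rnorm(cfg1$n_outcome,
                         sd = sqrt(1 - cfg1$h2_background))
  gwas_bg <- .records_from_assoc(bg_meta, marginal_assoc(Dbg_out, Y_bg))

  probes <- vector("list", n_probes)
  gwas_rec <- list(gwas_bg)
  panel_cols <- list(Dbg_pan)
  panel_meta <- list(bg_meta)
  truth_rows <- list()

  for (i in seq_len(n_probes)) {
    cfg <- mk_cfg(scen[i], i)
    cfg$n_background <- 0L  # background handled at study level
    geno <- simulate_genotypes(cfg, snp_prefix = sprintf("rs%d_", i))
    eff <- .scenario_effects(cfg, geno$meta)
    cfgu <- cfg
    cfgu$maf_cis_used <- geno$meta$maf
    h2b <- cfg1$h2_background

    make_traits <- function(D, gB, n) {
      gM <- as.vector(D %*% eff$beta_m)
      gY <- as.vector(D %*% eff$alpha_y)
      noise <- function(v) if (v > 1e-12) rnorm(n, sd = sqrt(v)) else 0
      if (cfg$scenario == "reverse") {
        Y <- gY + gB + noise(1 - sum(cfg$theta_yx) - h2b)
        M <- cfg$theta_ym * Y + noise(1 - cfg$theta_ym^2)
        return(list(M = M, Y = Y))
      }
      M <- gM + noise(1 - sum(cfg$theta_mx[seq_len(sum(eff$beta_m != 0))]))
      Y <- switch(cfg$scenario,
        causal = {
          E <- cfg$theta_me * M + noise(1 - cfg$theta_me^2)
          vpath <- cfg$theta_ey^2 + cfg$theta_my^2 +
            2 * cfg$theta_ey * cfg$theta_my * cfg$theta_me
          cfg$theta_ey * E + cfg$theta_my * M + gB +
            noise(1 - vpath - h2b)
        },
        pleiotropy = gY + gB + noise(1 - cfg$theta_gy - h2b),
        linkage = gY + gB + noise(1 - cfg$theta_by - h2b),
        null = gB + noise(1 - h2b))
      list(M = M, Y = Y)
    }
    tr_exp <- make_traits(geno$exposure, gB_exp, cfg$n_exposure)
    tr_out <- make_traits(geno$outcome, gB_out, cfg$n_outcome)

    m_cis <- .records_from_assoc(geno$meta,
                                 marginal_assoc(geno$exposure, tr_exp$M))
    m_bg <- .records_from_assoc(bg_meta, marginal_assoc(Dbg_exp, tr_exp$M))
    g_cis <- .records_from_assoc(geno$meta,
                                 marginal_assoc(geno$outcome, tr_out$Y))

    eqtls <- list()
    if (cfg$scenario == "causal") {
      E <- cfg$theta_me * tr_exp$M +
        rnorm(cfg$n_exposure, sd = sqrt(1 - cfg$theta_me^2))
      e_rec <- .records_from_assoc(geno$meta,
                                   marginal_assoc(geno$exposure, E))
      eqtls[[cfg$gene_id]] <- qtl_table(cfg$gene_id, cfg$probe_chr,
                                        cfg$probe_pos, e_rec,
                                        validate = FALSE)
      for (d in seq_len(n_decoy_genes)) {
        gid <- sprintf("%s_DECOY%d", cfg$gene_id, d)
        Ed <- rnorm(cfg$n_exposure)
        ed_rec <- .records_from_assoc(geno$meta,
                                      marginal_assoc(geno$exposure, Ed))
        eqtls[[gid]] <- qtl_table(gid, cfg$probe_chr, cfg$probe_pos, ed_rec,
                                  validate = FALSE)
      }
    }

    probes[[i]] <- list(
      probe_id = cfg$probe_id, scenario = cfg$scenario,
      gene_id = if (cfg$scenario == "causal") cfg$gene_id else NA_character_,
      mqtl = qtl_table(cfg$probe_id, cfg$probe_chr, cfg$probe_pos, m_cis,
                       validate = FALSE),
      m_stats = sumstat_set(cfg$probe_id, rbind(m_cis, m_bg),
                            validate = FALSE),
      eqtls = eqtls)
    gwas_rec[[i + 1]] <- g_cis
    panel_cols[[i + 1]] <- geno$panel
    panel_meta[[i + 1]] <- geno$meta
    truth_rows[[i]] <- data.frame(
      probe_id = cfg$probe_id, scenario = cfg$scenario,
      b_xy_true = if (cfg$scenario == "causal") {
        cfg$theta_me * cfg$theta_ey + cfg$theta_my
      } else 0,
      theta_me = if (cfg$scenario == "causal") cfg$theta_me else 0,
      theta_ey = if (cfg$scenario == "causal") cfg$theta_ey else 0,
      causal_snps = paste(geno$meta$snp[cfg$causal_idx], collapse = ","),
      stringsAsFactors = FALSE)
  }

  meta_all <- do.call(rbind, panel_meta)
  panel <- ld_panel(do.call(cbind, panel_cols), meta_all$snp, meta_all$a1,
                    meta_all$a2)
  gwas <- sumstat_set("outcome", do.call(rbind, gwas_rec), validate = FALSE)
  structure(list(probes = probes, gwas = gwas, panel = panel,
                 truth = do.call(rbind, truth_rows), seed = seed),
            class = "sim_discovery")
}
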