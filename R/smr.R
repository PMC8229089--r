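# Single-variant colocalization: SMR statistic and the HEIDI heterogeneity
# test that separates one shared causal variant (pleiotropy, the HEIDI null)
# from distinct variants in LD (linkage).

#' Upper tail of a weighted sum of independent 1-df chi-square variables
#'
#' Evaluates `P(sum_i lambda_i * chisq_1 > q)` by numerical integration of
#' the Imhof inversion formula; falls back to a Satterthwaite moment
#' approximation (scaled chi-square matched to mean and variance) when the
#' integration fails or leaves \[0, 1\].
#'
#' @param q observed statistic (scalar).
#' @param lambda non-negative weights.
#' @param rel.tol starting relative tolerance of the integration; when the
#'   oscillatory quadrature does not converge the tolerance is relaxed in
#'   steps (to 1e-4) before falling back to Satterthwaite.
#' @return p-value in (0, 1].
#' @export
psumchisq_upper <- function(q, lambda, rel.tol = 1e-9) {
  lambda <- lambda[lambda > 1e-10]
  if (!length(lambda) || q <= 0) return(1)
  if (length(lambda) == 1) {  # exact single-component tail
    return(min(max(pchisq(q / lambda, df = 1, lower.tail = FALSE),
                   .Machine$double.xmin), 1))
  }
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  p <- NA_real_
  for (tol in unique(pmax(c(rel.tol, 1e-8, 1e-6, 1e-4), rel.tol))) {
    p <- tryCatch({
      it <- stats::integrate(imhof, 0, Inf, rel.tol = tol,
                             abs.tol = tol / 100, subdivisions = 50000L)
      0.5 + it$value / pi
    }, error = function(e) NA_real_)
    if (is.finite(p) && p >= 1e-12 && p <= 1) break
  }
  if (!is.finite(p) || p < 1e-12 || p > 1) {
    # moment-matched scaled chi-square (Satterthwaite)
    s1 <- sum(lambda)
    s2 <- sum(lambda^2)
    p <- pchisq(q * s1 / s2, df = s1^2 / s2, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

# merge exposure-side and outcome-side records on shared SNPs
.merge_pair <- function(x_rec, y_rec) {
  common <- intersect(x_rec$snp, y_rec$snp)
  xi <- x_rec[match(common, x_rec$snp), , drop = FALSE]
  yi <- y_rec[match(common, y_rec$snp), , drop = FALSE]
  data.frame(snp = common, b_x = xi$b, se_x = xi$se, p_x = xi$p,
             b_y = yi$b, se_y = yi$se, p_y = yi$p,
             stringsAsFactors = FALSE)
}

.probe_skip <- function(reason) {
  structure(list(reason = reason), class = "probe_skip")
}

#' Is this result a per-probe skip marker?
#' @param x object to test.
#' @return logical.
#' @export
is_probe_skip <- function(x) inherits(x, "probe_skip")

#' SMR colocalization test at the top cis-QTL SNP
#'
#' With `z1 = b_qtl/se_qtl` and `z2 = b_gwas/se_gwas` at the SNP with the
#' largest QTL z-square, the statistic is
#' `T = z1^2 * z2^2 / (z1^2 + z2^2)`, referred to the upper tail of a 1-df
#' chi-square.  The effect of exposure on outcome at the top SNP is the
#' Wald ratio `b_smr = b_gwas / b_qtl` with delta-method standard error.
#' Inputs are assumed harmonized (see [harmonize()]).
#'
#' @param qtl cis-QTL statistics ([qtl_table()] or [sumstat_set()]) for the
#'   probe (exposure side).
#' @param gwas outcome GWAS [sumstat_set()].
#' @param p_qtl_max eligibility threshold: the top QTL SNP must reach this
#'   p-value (default genome-wide, 5e-8).
#' @return list of class `smr_result` (`top_snp`, `b_smr`, `se_smr`,
#'   `p_smr`, `z_qtl`, `z_gwas`) or a `probe_skip` with a reason.
#' @export
smr_test <- function(qtl, gwas, p_qtl_max = 5e-8) {
  q_rec <- ss_records(qtl)
  g_rec <- ss_records(gwas)
  if (!nrow(q_rec)) return(.probe_skip("no QTL records"))
  top_i <- which.max((q_rec$b / q_rec$se)^2)
  top <- q_rec[top_i, ]
  if (top$p >= p_qtl_max) {
    return(.probe_skip(sprintf("top QTL SNP %s not significant (p = %.3g)",
                               top$snp, top$p)))
  }
  gi <- match(top$snp, g_rec$snp)
  if (is.na(gi)) {
    return(.probe_skip(sprintf("top QTL SNP %s absent from GWAS set",
                               top$snp)))
  }
  g <- g_rec[gi, ]
  z1 <- top$b / top$se
  z2 <- g$b / g$se
  t_smr <- (z1^2 * z2^2) / (z1^2 + z2^2)
  p_smr <- min(max(pchisq(t_smr, df = 1, lower.tail = FALSE),
                   .Machine$double.xmin), 1)
  b_smr <- g$b / top$b
  se_smr <- sqrt((g$se^2 + b_smr^2 * top$se^2) / top$b^2)
  structure(list(probe_id = trait_of(qtl), top_snp = top$snp,
                 b_smr = b_smr, se_smr = se_smr, p_smr = p_smr,
                 t_smr = t_smr, z_qtl = z1, z_gwas = z2),
            class = "smr_result")
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Tests whether the per-SNP exposure-on-outcome ratios across the cis
#' region are compatible with a single shared causal variant (the null,
#' pleiotropy) or indicate distinct variants in LD (linkage).  Eligible
#' SNPs have QTL `z^2 > 10` (p below `p_incl`) and r-square with the top
#' SNP inside `r2_range`, capped at `max_snps` by descending QTL z-square.
#' For each eligible SNP `i`, `d_i = b_smr(i) - b_smr(top)`; the covariance
#' of the `d` vector follows from the delta method with the panel LD, the
#' statistic is `Q = sum (d_i / sd(d_i))^2`, and the p-value is the upper
#' tail of the matching weighted chi-square mixture (weights = eigenvalues
#' of the correlation matrix of the standardized `d`), via
#' [psumchisq_upper()].
#'
#' @param qtl,gwas harmonized cis-QTL and GWAS statistics.
#' @param panel [ld_panel()] covering the cis SNPs.
#' @param top_snp top SNP id; defaults to the largest QTL z-square.
#' @param p_incl QTL p-value ceiling for eligibility (z^2 > 10).
#' @param r2_range admissible r-square window with the top SNP.
#' @param max_snps cap on the number of eligible SNPs.
#' @param min_snps minimum eligible SNPs besides the top; below this the
#'   p-value is `NA` and the probe is flagged, never passed.
#' @param ridge regularization added to a singular correlation matrix.
#' @return list of class `heidi_result`: `p_heidi`, `n_heidi_snps`, `Q`,
#'   `flag` (`"ok"`, `"too_few_snps"`, or `"ridge_regularized"`).
#' @export
heidi_test <- function(qtl, gwas, panel, top_snp = NULL,
                       p_incl = pchisq(10, 1, lower.tail = FALSE),
                       r2_range = c(0.05, 0.9), max_snps = 20,
                       min_snps = 3, ridge = 1e-8) {
  mg <- .merge_pair(ss_records(qtl), ss_records(gwas))
  mg <- mg[mg$snp %in% panel$snp_index$snp, , drop = FALSE]
  if (!nrow(mg)) return(structure(list(p_heidi = NA_real_, n_heidi_snps = 0L,
                                       Q = NA_real_, flag = "too_few_snps"),
                                  class = "heidi_result"))
  z_q2 <- (mg$b_x / mg$se_x)^2
  if (is.null(top_snp)) top_snp <- mg$snp[which.max(z_q2)]
  ti <- match(top_snp, mg$snp)
  if (is.na(ti)) stop("top SNP not present in merged records: ", top_snp)

  R <- ld_matrix(panel, mg$snp)
  r_top <- R[, ti]
  elig <- which(mg$p_x < p_incl & r_top^2 >= r2_range[1] &
                  r_top^2 <= r2_range[2] & seq_len(nrow(mg)) != ti)
  if (length(elig) > max_snps) {
    elig <- elig[order(z_q2[elig], decreasing = TRUE)][seq_len(max_snps)]
  }
  if (length(elig) < min_snps) {
    return(structure(list(p_heidi = NA_real_,
                          n_heidi_snps = length(elig), Q = NA_real_,
                          flag = "too_few_snps"), class = "heidi_result"))
  }

  idx <- c(ti, elig)  # index 1 = top
  bx <- mg$b_x[idx]; sx <- mg$se_x[idx]
  by <- mg$b_y[idx]; sy <- mg$se_y[idx]
  r <- R[idx, idx, drop = FALSE]
  bxy <- by / bx
  k <- length(idx)
  # delta-method covariance of the Wald ratios (two independent samples)
  Vb <- (r * outer(sy, sy) + outer(bxy, bxy) * r * outer(sx, sx)) /
    outer(bx, bx)
  # d_i = bxy_i - bxy_top for i = 2..k
  e <- seq(2, k)
  Vd <- Vb[e, e, drop = FALSE] -
    matrix(Vb[e, 1], k - 1, k - 1) -
    t(matrix(Vb[e, 1], k - 1, k - 1)) + Vb[1, 1]
  d <- bxy[e] - bxy[1]
  sdd <- sqrt(pmax(diag(Vd), .Machine$double.eps))
  z <- d / sdd
  Q <- sum(z^2)
  Cd <- Vd / outer(sdd, sdd)
  flag <- "ok"
  ev <- tryCatch(eigen(Cd, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || !all(is.finite(ev))) {
    Cd <- Cd + ridge * diag(k - 1)
    ev <- eigen(Cd, symmetric = TRUE, only.values = TRUE)$values
    flag <- "ridge_regularized"
  }
  ev <- pmax(ev, 0)
  p <- psumchisq_upper(Q, ev)
  structure(list(p_heidi = p, n_heidi_snps = length(elig), Q = Q,
                 flag = flag), class = "heidi_result")
}

#' Scan probes for colocalization with the outcome GWAS
#'
#' Runs [smr_test()] and [heidi_test()] for every probe after harmonizing
#' each cis table with the GWAS against the panel allele frame.  A probe
#' passes when `p_smr < p_smr_max` and `p_heidi > p_heidi_min`; an
#' undefined HEIDI (too few eligible SNPs) never passes.
#'
#' @param qtls list of [qtl_table()].
#' @param gwas outcome GWAS [sumstat_set()].
#' @param panel [ld_panel()].
#' @param p_smr_max,p_heidi_min pass thresholds (defaults 5e-8 and 0.05).
#' @param p_qtl_max top-SNP eligibility threshold for the SMR test.
#' @param ... further arguments passed to [heidi_test()].
#' @return data frame (one row per probe, ordered by probe id):
#'   `probe_id`, `probe_chr`, `probe_pos`, `top_snp`, `b_smr`, `se_smr`,
#'   `p_smr`, `p_heidi`, `n_heidi_snps`, `passed`, `note`.
#' @export
coloc_scan <- function(qtls, gwas, panel, p_smr_max = 5e-8,
                       p_heidi_min = 0.05, p_qtl_max = 5e-8, ...) {
  rows <- lapply(qtls, function(q) {
    out <- data.frame(probe_id = q$probe_id, probe_chr = q$probe_chr,
                      probe_pos = q$probe_pos, top_snp = NA_character_,
                      b_smr = NA_real_, se_smr = NA_real_, p_smr = NA_real_,
                      p_heidi = NA_real_, n_heidi_snps = 0L, passed = FALSE,
                      note = "", stringsAsFactors = FALSE)
    hq <- tryCatch(harmonize(q, gwas, panel), error = function(e) NULL)
    if (is.null(hq)) {
      out$note <- "no shared SNPs after harmonization"
      return(out)
    }
    sm <- smr_test(hq$a, hq$b, p_qtl_max = p_qtl_max)
    if (is_probe_skip(sm)) {
      out$note <- sm$reason
      return(out)
    }
    out$top_snp <- sm$top_snp
    out$b_smr <- sm$b_smr
    out$se_smr <- sm$se_smr
    out$p_smr <- sm$p_smr
    hd <- heidi_test(hq$a, hq$b, panel, top_snp = sm$top_snp, ...)
    out$p_heidi <- hd$p_heidi
    out$n_heidi_snps <- hd$n_heidi_snps
    if (hd$flag != "ok") out$note <- hd$flag
    out$passed <- isTRUE(sm$p_smr < p_smr_max && !is.na(hd$p_heidi) &&
                           hd$p_heidi > p_heidi_min)
    out
  })
  res <- do.call(rbind, rows)
  res[order(res$probe_id), , drop = FALSE]
}
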