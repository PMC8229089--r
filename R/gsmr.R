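# LD-aware multi-SNP Mendelian randomization: instrument selection under
# the three criteria (exposure-significant, linkage equilibrium, not
# pleiotropic), GLS combination of per-SNP Wald ratios, single-pass
# pleiotropic-outlier removal, and the reverse-direction filter.

.no_instrument <- function(reason, exposure_id = NA_character_,
                           outcome_id = NA_character_,
                           direction = "forward") {
  structure(list(reason = reason, exposure_id = exposure_id,
                 outcome_id = outcome_id, direction = direction),
            class = "no_instrument")
}

#' Is this a typed "no instrument" outcome?
#' @param x object to test.
#' @return logical.
#' @export
is_no_instrument <- function(x) inherits(x, "no_instrument")

#' Select an MR instrument from harmonized summary statistics
#'
#' The instrument is built from the exposure dataset only: SNPs with
#' exposure p below `p_instrument` are sorted by ascending p and greedily
#' accepted when their r-square with every already-accepted SNP is below
#' `r2_prune` (clumping-style pruning).  Outcome effects are looked up
#' afterwards; SNPs absent from the outcome set (or the panel) are dropped
#' and counted in the provenance.
#'
#' @param exposure,outcome harmonized [sumstat_set()]/[qtl_table()] objects.
#' @param panel [ld_panel()] covering the candidate SNPs.
#' @param p_instrument exposure significance threshold (default 5e-8).
#' @param r2_prune LD pruning threshold on r-square (default 0.05).
#' @return object of class `mr_instrument` (`snps` data frame with
#'   `b_zx`, `se_zx`, `b_zy`, `se_zy`; `ld` matrix; `provenance` counts) or
#'   a `no_instrument` outcome.
#' @export
select_instrument <- function(exposure, outcome, panel,
                              p_instrument = 5e-8, r2_prune = 0.05) {
  ex <- ss_records(exposure)
  out <- ss_records(outcome)
  exposure_id <- trait_of(exposure)
  outcome_id <- trait_of(outcome)
  prov <- list(n_exposure_snps = nrow(ex))

  cand <- ex[ex$p < p_instrument, , drop = FALSE]
  prov$n_significant <- nrow(cand)
  if (!nrow(cand)) {
    return(.no_instrument(sprintf("no SNP at p < %g", p_instrument),
                          exposure_id, outcome_id))
  }
  in_panel <- cand$snp %in% panel$snp_index$snp
  prov$n_missing_panel <- sum(!in_panel)
  cand <- cand[in_panel, , drop = FALSE]
  if (!nrow(cand)) {
    return(.no_instrument("no significant SNP present in LD panel",
                          exposure_id, outcome_id))
  }
  cand <- cand[order(cand$p), , drop = FALSE]
  R <- ld_matrix(panel, cand$snp)
  keep <- 1L
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      if (all(R[i, keep]^2 < r2_prune)) keep <- c(keep, i)
    }
  }
  prov$n_after_prune <- length(keep)
  sel <- cand[keep, , drop = FALSE]

  oi <- match(sel$snp, out$snp)
  prov$n_missing_outcome <- sum(is.na(oi))
  ok <- !is.na(oi)
  sel <- sel[ok, , drop = FALSE]
  oi <- oi[ok]
  if (!nrow(sel)) {
    return(.no_instrument("no instrument SNP present in outcome set",
                          exposure_id, outcome_id))
  }
  snps <- data.frame(snp = sel$snp, b_zx = sel$b, se_zx = sel$se,
                     p_zx = sel$p, b_zy = out$b[oi], se_zy = out$se[oi],
                     stringsAsFactors = FALSE)
  ld <- ld_matrix(panel, snps$snp)
  prov$removed_pleiotropic <- character(0)
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snps = snps, ld = ld, provenance = prov,
                 flags = character(0)),
            class = "mr_instrument")
}

# solve V x = b with escalating ridge if the Cholesky fails
.solve_psd <- function(V, B) {
  eps <- 0
  scale <- mean(diag(V))
  for (try in 0:6) {
    Vr <- V + eps * diag(nrow(V))
    ch <- tryCatch(chol(Vr), error = function(e) NULL)
    if (!is.null(ch)) {
      x <- backsolve(ch, forwardsolve(t(ch), B))
      return(list(x = x, ridge = eps))
    }
    eps <- if (eps == 0) 1e-10 * scale else eps * 100
  }
  stop("covariance matrix numerically singular beyond ridge repair")
}

#' GLS Mendelian randomization over per-SNP Wald ratios
#'
#' Per SNP `i` the ratio estimate is `b_i = b_zy_i / b_zx_i` with
#' delta-method variance `v_i = (se_zy_i^2 + b_i^2 se_zx_i^2) / b_zx_i^2`;
#' the covariance between ratios is
#' `cov(b_i, b_j) = r_ij (se_zy_i se_zy_j + b_i b_j se_zx_i se_zx_j) /
#' (b_zx_i b_zx_j)` with `r_ij` the panel LD.  The causal effect is the
#' GLS mean `b_xy = (1' V^-1 b) / (1' V^-1 1)` with
#' `se = (1' V^-1 1)^{-1/2}` and a two-sided normal p-value.  A single SNP
#' reduces to the Wald ratio with the delta-method SE.
#'
#' @param instr an `mr_instrument`.
#' @param direction `"forward"` or `"reverse"` (recorded in the result).
#' @return list of class `mr_result`: `b_xy`, `se_xy`, `p_xy`,
#'   `n_snps_used`, `removed_snps`, `direction`, `method`, `ridge`.
#' @export
gls_mr <- function(instr, direction = "forward") {
  if (is_no_instrument(instr)) return(instr)
  s <- instr$snps
  k <- nrow(s)
  if (k < 1) stop("empty instrument")
  b <- s$b_zy / s$b_zx
  v <- (s$se_zy^2 + b^2 * s$se_zx^2) / s$b_zx^2
  removed <- instr$provenance$removed_pleiotropic
  if (k == 1) {
    b_xy <- b
    se_xy <- sqrt(v)
    ridge <- 0
    method <- "wald_ratio"
  } else {
    r <- instr$ld
    V <- (r * (outer(s$se_zy, s$se_zy) +
                 outer(b, b) * outer(s$se_zx, s$se_zx))) /
      outer(s$b_zx, s$b_zx)
    diag(V) <- v
    sol <- .solve_psd(V, cbind(rep(1, k), b))
    ones <- sol$x[, 1]
    denom <- sum(ones)
    b_xy <- sum(ones * b) / denom
    se_xy <- sqrt(1 / denom)
    ridge <- sol$ridge
    method <- "gls"
  }
  p_xy <- min(max(2 * pnorm(-abs(b_xy / se_xy)), .Machine$double.xmin), 1)
  structure(list(exposure_id = instr$exposure_id,
                 outcome_id = instr$outcome_id, b_xy = b_xy, se_xy = se_xy,
                 p_xy = p_xy, n_snps_used = k,
                 removed_snps = removed, direction = direction,
                 method = method, ridge = ridge, flags = instr$flags,
                 instrument = instr),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result %s> %s -> %s: b_xy = %.4g (se %.3g, p %.3g), %d SNP(s)\n",
              x$direction, x$exposure_id, x$outcome_id, x$b_xy, x$se_xy,
              x$p_xy, x$n_snps_used))
  invisible(x)
}

#' Remove pleiotropic outlier SNPs from an instrument (single pass)
#'
#' Fits a provisional GLS estimate, computes for every SNP
#' `d_i = b_i - b_xy` with delta-method standard deviation
#' `sqrt(v_i - se_xy^2)`, refers `(d_i / sd_i)^2` to a 1-df chi-square and
#' drops SNPs with outlier p below `p_outlier`.  One pass only: the
#' instrument is refit once downstream.  With fewer than 3 SNPs the test is
#' skipped and the instrument flagged.
#'
#' @param instr an `mr_instrument`.
#' @param p_outlier outlier threshold (default 0.01).
#' @return pruned `mr_instrument` (removed SNPs recorded in provenance) or
#'   a `no_instrument` outcome when nothing survives.
#' @export
remove_pleiotropic <- function(instr, p_outlier = 0.01) {
  if (is_no_instrument(instr)) return(instr)
  s <- instr$snps
  k <- nrow(s)
  if (k < 3) {
    instr$flags <- union(instr$flags, "outlier test skipped")
    return(instr)
  }
  fit <- gls_mr(instr)
  b <- s$b_zy / s$b_zx
  v <- (s$se_zy^2 + b^2 * s$se_zx^2) / s$b_zx^2
  vd <- pmax(v - fit$se_xy^2, 0.05 * v)
  p_out <- pchisq((b - fit$b_xy)^2 / vd, df = 1, lower.tail = FALSE)
  drop <- p_out < p_outlier
  if (all(drop)) {
    return(.no_instrument("all SNPs removed as pleiotropic outliers",
                          instr$exposure_id, instr$outcome_id))
  }
  if (any(drop)) {
    instr$provenance$removed_pleiotropic <-
      c(instr$provenance$removed_pleiotropic, s$snp[drop])
    instr$provenance$outlier_p <- stats::setNames(p_out[drop], s$snp[drop])
    instr$snps <- s[!drop, , drop = FALSE]
    instr$ld <- instr$ld[!drop, !drop, drop = FALSE]
  }
  instr
}

#' Run a full MR analysis between two summary-statistic sets
#'
#' Convenience wrapper: [select_instrument()], [remove_pleiotropic()],
#' [gls_mr()].
#'
#' @param exposure,outcome harmonized sets; the instrument comes from
#'   `exposure`.
#' @param panel [ld_panel()].
#' @param params list of thresholds: `p_instrument` (5e-8), `r2_prune`
#'   (0.05), `p_outlier` (0.01).
#' @param direction label recorded in the result.
#' @return `mr_result` or `no_instrument`.
#' @export
run_mr <- function(exposure, outcome, panel, params = list(),
                   direction = "forward") {
  p <- modifyList(list(p_instrument = 5e-8, r2_prune = 0.05,
                       p_outlier = 0.01), params)
  instr <- select_instrument(exposure, outcome, panel,
                             p_instrument = p$p_instrument,
                             r2_prune = p$r2_prune)
  if (is_no_instrument(instr)) {
    instr$direction <- direction
    return(instr)
  }
  instr <- remove_pleiotropic(instr, p_outlier = p$p_outlier)
  if (is_no_instrument(instr)) {
    instr$direction <- direction
    return(instr)
  }
  gls_mr(instr, direction = direction)
}

#' Reverse-direction MR (outcome instrumented, exposure as outcome)
#'
#' Identical machinery to [run_mr()] with the roles swapped: the outcome
#' GWAS provides the instrument and the exposure set is looked up.  Used by
#' the reverse-causation filter.
#'
#' @inheritParams run_mr
#' @return `mr_result` with `direction = "reverse"`, or `no_instrument`.
#' @export
reverse_mr <- function(exposure, outcome, panel, params = list()) {
  run_mr(outcome, exposure, panel, params = params, direction = "reverse")
}

#' Bidirectional decision for one exposure-outcome pair
#'
#' A pair is retained iff the forward MR p-value is below `p_forward`
#' (default genome-wide, 5e-8) and the reverse MR shows no significant
#' evidence of reverse causation (reverse p at or above `p_reverse`,
#' default 0.05).  A missing reverse instrument means reverse causation is
#' untestable and does not exclude the pair; a missing forward instrument
#' excludes it.
#'
#' @param forward,reverse `mr_result`/`no_instrument` objects for the same
#'   pair.
#' @param p_forward,p_reverse decision thresholds.
#' @return list: `retained`, `reason`, `p_forward`, `p_reverse`.
#' @export
bidirectional_filter <- function(forward, reverse, p_forward = 5e-8,
                                 p_reverse = 0.05) {
  pf <- if (is_no_instrument(forward)) NA_real_ else forward$p_xy
  pr <- if (is_no_instrument(reverse)) NA_real_ else reverse$p_xy
  if (is_no_instrument(forward)) {
    return(list(retained = FALSE, reason = "no forward instrument",
                p_forward = pf, p_reverse = pr))
  }
  if (pf >= p_forward) {
    return(list(retained = FALSE, reason = "below forward threshold",
                p_forward = pf, p_reverse = pr))
  }
  if (!is.na(pr) && pr < p_reverse) {
    return(list(retained = FALSE, reason = "reverse causation",
                p_forward = pf, p_reverse = pr))
  }
  list(retained = TRUE,
       reason = if (is.na(pr)) "retained (reverse untestable)" else "retained",
       p_forward = pf, p_reverse = pr)
}
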