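# Shared fixture builders.  Everything is generated in code at test time;
# no binary fixtures on disk.

# write a .ma file from a plain data frame with columns SNP A1 A2 freq b se p N
write_ma_file <- function(df, path = tempfile(fileext = ".ma")) {
  writeLines(c(paste(names(df), collapse = "\t"),
               apply(df, 1, paste, collapse = "\t")), path)
  path
}

# small deterministic LD panel built from explicit dosage columns
panel_from_cols <- function(..., snp = NULL, a1 = "A", a2 = "G") {
  cols <- list(...)
  D <- do.call(cbind, cols)
  if (is.null(snp)) snp <- paste0("rs", seq_len(ncol(D)))
  ld_panel(D, snp, a1, a2)
}

# scenario config scaled for unit tests (fast, still well-powered cis QTLs)
small_cfg <- function(scenario = "causal", ...) {
  args <- list(scenario = scenario, n_exposure = 2000, n_outcome = 2000,
               n_panel = 503, n_snps = 40)
  args <- utils::modifyList(args, list(...))
  do.call(scenario_config, args)
}

# instrument object assembled by hand (for direct gls_mr tests)
make_instrument <- function(b_zx, se_zx, b_zy, se_zy, ld = NULL,
                            snp = NULL) {
  k <- length(b_zx)
  if (is.null(snp)) snp <- paste0("rs", seq_len(k))
  if (is.null(ld)) ld <- diag(k)
  dimnames(ld) <- list(snp, snp)
  structure(list(exposure_id = "x", outcome_id = "y",
                 snps = data.frame(snp = snp, b_zx = b_zx, se_zx = se_zx,
                                   p_zx = 2 * pnorm(-abs(b_zx / se_zx)),
                                   b_zy = b_zy, se_zy = se_zy,
                                   stringsAsFactors = FALSE),
                 ld = ld,
                 provenance = list(removed_pleiotropic = character(0)),
                 flags = character(0)),
            class = "mr_instrument")
}

# independent IVW oracle: fixed-effect meta-analysis of Wald ratios
ivw_oracle <- function(b_zx, se_zx, b_zy, se_zy) {
  b <- b_zy / b_zx
  v <- (se_zy^2 + b^2 * se_zx^2) / b_zx^2
  w <- 1 / v
  est <- sum(w * b) / sum(w)
  se <- sqrt(1 / sum(w))
  list(b = est, se = se, p = 2 * pnorm(-abs(est / se)))
}
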