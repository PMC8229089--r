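# Expression-mediation chains (methylation -> expression -> trait) and
# positional matching of rare variants to mQTLs.  Mediation is assessed by
# sign consistency of the chain against the direct methylation -> trait
# effect, not by a formal mediation-proportion model.

.mr_num <- function(res, field) {
  if (is.null(res) || is_no_instrument(res)) NA_real_ else res[[field]]
}

#' MR chain through gene expression for one probe-gene pair
#'
#' Runs the MR machinery three times: methylation -> expression (instrument
#' from the probe's mQTLs), expression -> trait (instrument from the gene's
#' eQTLs), and the direct methylation -> trait analysis.  The implied sign
#' of the chain, `sign(b_me * b_ey)`, is compared with the sign of the
#' direct effect; consistency is only defined when both chain links pass
#' their significance thresholds (otherwise `consistent` is `NA`,
#' indeterminate).
#'
#' @param probe_qtl cis mQTL [qtl_table()] for the methylation probe.
#' @param gene_eqtl cis eQTL [qtl_table()] for the candidate gene.
#' @param gwas outcome GWAS [sumstat_set()].
#' @param panel [ld_panel()].
#' @param params MR thresholds, see [run_mr()].
#' @param p_me significance threshold for the methylation -> expression
#'   link (default genome-wide, 5e-8).
#' @param p_ey significance threshold for the expression -> trait link
#'   (default 0.05; [scan_mediators()] divides it by the number of genes).
#' @return list of class `mediation_result`.
#' @export
mediation_chain <- function(probe_qtl, gene_eqtl, gwas, panel,
                            params = list(), p_me = 5e-8, p_ey = 0.05) {
  me <- run_mr(probe_qtl, gene_eqtl, panel, params = params)
  ey <- run_mr(gene_eqtl, gwas, panel, params = params)
  my <- run_mr(probe_qtl, gwas, panel, params = params)

  b_me <- .mr_num(me, "b_xy"); p_me_obs <- .mr_num(me, "p_xy")
  b_ey <- .mr_num(ey, "b_xy"); p_ey_obs <- .mr_num(ey, "p_xy")
  b_my <- .mr_num(my, "b_xy")

  links_ok <- !is.na(p_me_obs) && !is.na(p_ey_obs) &&
    p_me_obs < p_me && p_ey_obs < p_ey
  implied <- if (is.na(b_me) || is.na(b_ey)) NA_real_ else sign(b_me * b_ey)
  consistent <- if (links_ok && !is.na(b_my)) {
    implied == sign(b_my)
  } else NA
  structure(list(probe_id = probe_qtl$probe_id,
                 gene_id = gene_eqtl$probe_id,
                 b_me = b_me, se_me = .mr_num(me, "se_xy"), p_me = p_me_obs,
                 b_ey = b_ey, se_ey = .mr_num(ey, "se_xy"), p_ey = p_ey_obs,
                 b_my_direct = b_my, se_my = .mr_num(my, "se_xy"),
                 p_my = .mr_num(my, "p_xy"),
                 implied_sign = implied, consistent = consistent,
                 links_significant = links_ok),
            class = "mediation_result")
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(probe_id = x$probe_id, gene_id = x$gene_id, b_me = x$b_me,
             se_me = x$se_me, p_me = x$p_me, b_ey = x$b_ey, se_ey = x$se_ey,
             p_ey = x$p_ey, b_my_direct = x$b_my_direct, se_my = x$se_my,
             p_my = x$p_my, implied_sign = x$implied_sign,
             consistent = x$consistent,
             links_significant = x$links_significant,
             stringsAsFactors = FALSE)
}

#' Scan candidate genes for expression mediation of a probe's effect
#'
#' Runs [mediation_chain()] against every gene in the band; genes whose
#' methylation -> expression link fails the chain threshold are reported as
#' non-mediators.  The expression -> trait threshold is Bonferroni-adjusted
#' by the number of candidate genes.
#'
#' @param probe_qtl cis mQTL [qtl_table()].
#' @param eqtls list of cis eQTL [qtl_table()], one per candidate gene.
#' @param gwas outcome GWAS [sumstat_set()].
#' @param panel [ld_panel()].
#' @param params MR thresholds, see [run_mr()].
#' @param p_me methylation -> expression threshold (default 5e-8).
#' @param p_ey_family family-wise expression -> trait level (default 0.05,
#'   divided by `length(eqtls)`).
#' @return data frame with one row per gene plus an `is_mediator` flag.
#' @export
scan_mediators <- function(probe_qtl, eqtls, gwas, panel, params = list(),
                           p_me = 5e-8, p_ey_family = 0.05) {
  if (!length(eqtls)) {
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      b_me = numeric(0), se_me = numeric(0),
                      p_me = numeric(0), b_ey = numeric(0),
                      se_ey = numeric(0), p_ey = numeric(0),
                      b_my_direct = numeric(0), se_my = numeric(0),
                      p_my = numeric(0), implied_sign = numeric(0),
                      consistent = logical(0),
                      links_significant = logical(0),
                      is_mediator = logical(0), stringsAsFactors = FALSE))
  }
  p_ey <- p_ey_family / length(eqtls)
  rows <- lapply(eqtls, function(eq) {
    as.data.frame(mediation_chain(probe_qtl, eq, gwas, panel,
                                  params = params, p_me = p_me,
                                  p_ey = p_ey))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$is_mediator <- out$links_significant
  out[order(out$gene_id), , drop = FALSE]
}

#' Match rare variants to mQTL positions
#'
#' A variant matches a probe when its position equals an mQTL SNP position
#' on the same chromosome (`exact_position`) or lies within `window_bp` of
#' any mQTL SNP for that probe (`within_window`).  Matches can only grow as
#' the window grows.  Coordinates are 1-based and must share one assembly
#' (caller's responsibility).
#'
#' @param rares rare-variant table (see [read_rare_variants()]).
#' @param qtls list of mQTL [qtl_table()].
#' @param window_bp window half-width in bp (default 1000).
#' @param p_max optional: only consider mQTL SNPs with p below this.
#' @return data frame: `variant_id`, `chrom`, `pos`, `probe_id`,
#'   `match_type`, `window_bp`, `mqtl_snp_ids`, `min_distance`; exact
#'   matches sorted first.
#' @export
rare_variant_overlap <- function(rares, qtls, window_bp = 1000,
                                 p_max = NULL) {
  rows <- list()
  for (vi in seq_len(nrow(rares))) {
    v <- rares[vi, ]
    for (q in qtls) {
      rec <- q$records
      if (!is.null(p_max)) rec <- rec[rec$p < p_max, , drop = FALSE]
      rec <- rec[rec$chr == as.character(v$chrom), , drop = FALSE]
      if (!nrow(rec)) next
      dist <- abs(rec$pos - v$pos)
      hit <- dist <= window_bp
      if (!any(hit)) next
      exact <- dist == 0
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = v$variant_id, chrom = as.character(v$chrom),
        pos = v$pos, probe_id = q$probe_id,
        match_type = if (any(exact)) "exact_position" else "within_window",
        window_bp = window_bp,
        mqtl_snp_ids = paste(rec$snp[hit], collapse = ","),
        min_distance = min(dist[hit]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), probe_id = character(0),
                      match_type = character(0), window_bp = integer(0),
                      mqtl_snp_ids = character(0),
                      min_distance = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$match_type != "exact_position", out$variant_id,
            out$probe_id), , drop = FALSE]
}
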