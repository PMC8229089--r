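# Discovery / replication orchestration: coloc scan -> forward MR ->
# reverse-causation filter, with a per-probe audit trail.  All stage
# statistics are computed for every probe and the final status is derived
# by a pure threshold-classification step, so that threshold grids
# (monotonicity checks) can be evaluated without re-running the analyses.

#' Pipeline configuration
#'
#' Thresholds follow the analysis cascade: colocalization requires
#' `p_smr < p_smr_max` and `p_heidi > p_heidi_keep`; instruments need
#' exposure `p < p_instrument` and pairwise `r^2 < r2_prune`; pleiotropic
#' outliers are removed at `p_outlier`; a pair is retained when the forward
#' MR p is below `p_forward` and the reverse MR p is at or above
#' `p_reverse`.
#'
#' @param p_smr_max,p_heidi_keep,p_instrument,r2_prune,p_outlier,p_forward,p_reverse
#'   thresholds (see above for defaults).
#' @param cis_window cis-window half-width in bp.
#' @param rare_window_bp rare-variant matching window in bp.
#' @param seed integer seed (only simulation / Monte-Carlo fallbacks consume
#'   randomness; analytic stages are seed-free).
#' @param paths optional named list of input file paths (`mqtl`, `gwas`,
#'   `panel`, `eqtl`, `variants`) for file-driven runs.
#' @param out_dir output directory for report files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_smr_max = 5e-8, p_heidi_keep = 0.05,
                            p_instrument = 5e-8, r2_prune = 0.05,
                            p_outlier = 0.01, p_forward = 5e-8,
                            p_reverse = 0.05, cis_window = 1e6,
                            rare_window_bp = 1000, seed = 1,
                            paths = list(), out_dir = NULL) {
  thr <- c(p_smr_max = p_smr_max, p_heidi_keep = p_heidi_keep,
           p_instrument = p_instrument, p_outlier = p_outlier,
           p_forward = p_forward, p_reverse = p_reverse)
  if (any(thr <= 0 | thr >= 1)) {
    stop("all p-value thresholds must lie in (0, 1)")
  }
  if (r2_prune <= 0 || r2_prune >= 1) stop("r2_prune must be in (0, 1)")
  structure(list(p_smr_max = p_smr_max, p_heidi_keep = p_heidi_keep,
                 p_instrument = p_instrument, r2_prune = r2_prune,
                 p_outlier = p_outlier, p_forward = p_forward,
                 p_reverse = p_reverse, cis_window = cis_window,
                 rare_window_bp = rare_window_bp, seed = seed,
                 paths = paths, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; file paths
#' go under `paths`.  YAML is used when the file ends in `.yaml`/`.yml` and
#' the `yaml` package is installed, JSON otherwise.
#'
#' @param path config file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path) &&
              requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, vals[intersect(names(vals), known)])
}

#' Classify per-probe stage statistics into a final status
#'
#' Pure function over the stage statistics recorded by [run_discovery()]:
#' given a row per probe with `p_smr`, `p_heidi`, `p_xy` (forward MR) and
#' `p_reverse`, assigns one of `failed_coloc`, `failed_heidi`,
#' `no_instrument`, `failed_forward_mr`, `failed_reverse`, `passed`.
#' Useful for evaluating threshold grids without re-running the analyses.
#'
#' @param stats data frame of per-probe statistics.
#' @param config a [pipeline_config()].
#' @return character vector of statuses, one per row.
#' @export
classify_discovery <- function(stats, config) {
  status <- character(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    s <- stats[i, ]
    status[i] <- if (is.na(s$p_smr) || s$p_smr >= config$p_smr_max) {
      "failed_coloc"
    } else if (is.na(s$p_heidi) || s$p_heidi <= config$p_heidi_keep) {
      "failed_heidi"
    } else if (is.na(s$p_xy)) {
      "no_instrument"
    } else if (s$p_xy >= config$p_forward) {
      "failed_forward_mr"
    } else if (!is.na(s$p_reverse) && s$p_reverse < config$p_reverse) {
      "failed_reverse"
    } else {
      "passed"
    }
  }
  status
}

#' Run the discovery stage over a simulated or file-based study
#'
#' Stage order: colocalization (SMR + HEIDI), forward MR (instrument from
#' the probe's cis mQTLs), reverse MR (instrument from the outcome GWAS,
#' probe methylation as outcome).  All stage statistics are recorded for
#' every probe regardless of where it falls, and the `final_status` is
#' assigned by threshold classification, giving a complete audit trail.
#' Deterministic given the study and config.
#'
#' @param study a `sim_discovery` from [simulate_discovery_study()], or
#'   `NULL` to read inputs from `config$paths` (`mqtl`, `gwas`, `panel`;
#'   file-driven runs use the cis records as the methylation set for the
#'   reverse direction).
#' @param config a [pipeline_config()].
#' @return list of class `discovery_result`: `records` (one row per probe),
#'   `log` (per-probe stage decisions), `config`.
#' @export
run_discovery <- function(study = NULL, config = pipeline_config()) {
  if (is.null(study)) {
    pp <- config$paths
    if (is.null(pp$mqtl) || is.null(pp$gwas) || is.null(pp$panel)) {
      stop("config$paths must name mqtl, gwas and panel files")
    }
    for (f in unlist(pp)) {
      if (!file.exists(f)) stop("unreadable input: ", f)
    }
    qtls <- read_sumstats(pp$mqtl, "qtl", cis_window = config$cis_window)
    gwas <- read_sumstats(pp$gwas, "ma", trait_id = "outcome")
    panel <- read_ld_panel(pp$panel)
    probes <- lapply(qtls, function(q) {
      list(probe_id = q$probe_id, scenario = NA_character_, mqtl = q,
           m_stats = sumstat_set(q$probe_id, q$records, validate = FALSE))
    })
    study <- list(probes = probes, gwas = gwas, panel = panel)
  }

  params <- list(p_instrument = config$p_instrument,
                 r2_prune = config$r2_prune,
                 p_outlier = config$p_outlier)
  log_lines <- character(0)
  note <- function(probe, stage, decision, reason = "") {
    log_lines <<- c(log_lines,
                    sprintf("%s\t%s\t%s\t%s", probe, stage, decision,
                            reason))
  }

  rows <- lapply(study$probes, function(pr) {
    pid <- pr$probe_id
    out <- data.frame(probe_id = pid,
                      probe_chr = pr$mqtl$probe_chr,
                      probe_pos = pr$mqtl$probe_pos,
                      scenario = if (is.null(pr$scenario)) NA_character_
                                 else pr$scenario,
                      top_snp = NA_character_, b_smr = NA_real_,
                      se_smr = NA_real_, p_smr = NA_real_,
                      p_heidi = NA_real_, n_heidi_snps = 0L,
                      b_xy = NA_real_, se_xy = NA_real_, p_xy = NA_real_,
                      n_snps = NA_integer_, n_removed = 0L,
                      b_reverse = NA_real_, p_reverse = NA_real_,
                      final_status = NA_character_,
                      stringsAsFactors = FALSE)

    hq <- tryCatch(harmonize(pr$mqtl, study$gwas, study$panel),
                   error = function(e) NULL)
    if (is.null(hq)) {
      note(pid, "coloc", "skip", "no shared SNPs after harmonization")
      return(out)
    }
    sm <- smr_test(hq$a, hq$b, p_qtl_max = config$p_instrument)
    if (is_probe_skip(sm)) {
      note(pid, "coloc", "skip", sm$reason)
    } else {
      out$top_snp <- sm$top_snp
      out$b_smr <- sm$b_smr
      out$se_smr <- sm$se_smr
      out$p_smr <- sm$p_smr
      hd <- heidi_test(hq$a, hq$b, study$panel, top_snp = sm$top_snp)
      out$p_heidi <- hd$p_heidi
      out$n_heidi_snps <- hd$n_heidi_snps
      note(pid, "coloc", "done",
           sprintf("p_smr=%.3g p_heidi=%.3g", sm$p_smr, hd$p_heidi))
    }

    fwd <- run_mr(pr$mqtl, study$gwas, study$panel, params = params)
    if (is_no_instrument(fwd)) {
      note(pid, "forward_mr", "no_instrument", fwd$reason)
    } else {
      out$b_xy <- fwd$b_xy
      out$se_xy <- fwd$se_xy
      out$p_xy <- fwd$p_xy
      out$n_snps <- fwd$n_snps_used
      out$n_removed <- length(fwd$removed_snps)
      note(pid, "forward_mr", "done",
           sprintf("b=%.3g p=%.3g n=%d", fwd$b_xy, fwd$p_xy,
                   fwd$n_snps_used))
    }

    m_out <- if (!is.null(pr$m_stats)) pr$m_stats else pr$mqtl
    rev <- reverse_mr(m_out, study$gwas, study$panel, params = params)
    if (is_no_instrument(rev)) {
      note(pid, "reverse_mr", "no_instrument", rev$reason)
    } else {
      out$b_reverse <- rev$b_xy
      out$p_reverse <- rev$p_xy
      note(pid, "reverse_mr", "done",
           sprintf("b=%.3g p=%.3g", rev$b_xy, rev$p_xy))
    }
    out
  })
  records <- do.call(rbind, rows)
  records <- records[order(records$probe_id), , drop = FALSE]
  rownames(records) <- NULL
  records$final_status <- classify_discovery(records, config)
  structure(list(records = records, log = log_lines, config = config),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result>", nrow(x$records), "probes\n")
  print(table(x$records$final_status))
  invisible(x)
}

#' Re-run the replication stage for discovery-passed probes
#'
#' For each probe with `final_status == "passed"` the forward MR is
#' repeated on the replication study; a probe replicates when the effect
#' has the same sign and p below `0.05 / n_passed` (Bonferroni over the
#' passed set).  Probes absent from the replication data are `untestable`.
#'
#' @param discovery a `discovery_result`.
#' @param rep_study replication `sim_discovery` (or compatible list).
#' @param config a [pipeline_config()].
#' @param alpha family-wise replication level before division (default
#'   0.05).
#' @return the `discovery_result` with replication columns added to
#'   `records`.
#' @export
run_replication <- function(discovery, rep_study,
                            config = discovery$config, alpha = 0.05) {
  rec <- discovery$records
  rec$b_replication <- NA_real_
  rec$p_replication <- NA_real_
  rec$replication_status <- NA_character_
  passed <- which(rec$final_status == "passed")
  if (!length(passed)) {
    discovery$records <- rec
    return(discovery)
  }
  p_thresh <- alpha / length(passed)
  params <- list(p_instrument = config$p_instrument,
                 r2_prune = config$r2_prune,
                 p_outlier = config$p_outlier)
  rep_ids <- vapply(rep_study$probes, function(p) p$probe_id, "")
  for (i in passed) {
    j <- match(rec$probe_id[i], rep_ids)
    if (is.na(j)) {
      rec$replication_status[i] <- "untestable"
      next
    }
    fit <- run_mr(rep_study$probes[[j]]$mqtl, rep_study$gwas,
                  rep_study$panel, params = params)
    if (is_no_instrument(fit)) {
      rec$replication_status[i] <- "untestable"
      next
    }
    rec$b_replication[i] <- fit$b_xy
    rec$p_replication[i] <- fit$p_xy
    same_sign <- sign(fit$b_xy) == sign(rec$b_xy[i])
    rec$replication_status[i] <- if (same_sign && fit$p_xy < p_thresh) {
      "replicated"
    } else "failed_replication"
  }
  discovery$records <- rec
  discovery
}

#' Write discovery records to a TSV report
#'
#' @param discovery a `discovery_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_discovery <- function(discovery, path) {
  write_report(discovery$records, path)
}

#' Effect-versus-effect MR scatter plot
#'
#' One point per instrument SNP at (effect on exposure, effect on outcome)
#' with horizontal/vertical standard-error bars and a dashed line through
#' the origin with slope `b_xy`.  The device is chosen by file extension
#' (`.pdf` or `.png`).
#'
#' @param instr an `mr_instrument` (must be non-empty).
#' @param result the matching `mr_result`.
#' @param path output image path.
#' @return `path`, invisibly.
#' @export
plot_mr <- function(instr, result, path) {
  if (is_no_instrument(instr) || is.null(instr$snps) ||
      nrow(instr$snps) < 1) {
    stop("cannot plot an empty instrument")
  }
  s <- instr$snps
  open_dev <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    function(p) grDevices::png(p, width = 640, height = 640)
  } else {
    function(p) grDevices::pdf(p, width = 6, height = 6)
  }
  tryCatch(open_dev(path),
           error = function(e) stop("cannot open device for '", path, "': ",
                                    conditionMessage(e)))
  on.exit(grDevices::dev.off())
  xlim <- range(c(s$b_zx - s$se_zx, s$b_zx + s$se_zx, 0))
  ylim <- range(c(s$b_zy - s$se_zy, s$b_zy + s$se_zy, 0))
  graphics::plot(s$b_zx, s$b_zy, xlim = xlim, ylim = ylim, pch = 19,
                 xlab = sprintf("SNP effect on %s", result$exposure_id),
                 ylab = sprintf("SNP effect on %s", result$outcome_id),
                 main = sprintf("b_xy = %.3g (p = %.2g)", result$b_xy,
                                result$p_xy))
  suppressWarnings({
    graphics::arrows(s$b_zx - s$se_zx, s$b_zy, s$b_zx + s$se_zx, s$b_zy,
                     angle = 90, code = 3, length = 0.02)
    graphics::arrows(s$b_zx, s$b_zy - s$se_zy, s$b_zx, s$b_zy + s$se_zy,
                     angle = 90, code = 3, length = 0.02)
  })
  graphics::abline(a = 0, b = result$b_xy, lty = 2)
  invisible(path)
}
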