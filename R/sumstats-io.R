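# Summary-statistic containers and plain-text I/O.
#
# File dialects are whitespace- or tab-delimited with a mandatory header and
# are gzip-transparent:
#   .ma  : SNP A1 A2 freq b se p N
#   qtl  : Probe ProbeChr ProbePos SNP Chr Pos A1 A2 freq b se p N
#   panel: IID then one column per SNP, named "snp:A1:A2" (dosage of A1,
#          values in [0, 2]); a bare "snp" header is accepted but then the
#          panel carries no allele information.
#   rare : variant_id chrom pos ref alt condition

.MA_COLS <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
.QTL_COLS <- c("Probe", "ProbeChr", "ProbePos", "SNP", "Chr", "Pos",
               "A1", "A2", "freq", "b", "se", "p", "N")
.REC_COLS <- c("snp", "chr", "pos", "a1", "a2", "freq", "b", "se", "p", "n")

.AMBIGUOUS <- c("AT", "TA", "CG", "GC")

is_ambiguous_pair <- function(a1, a2) paste0(a1, a2) %in% .AMBIGUOUS

#' Canonicalize a data frame of per-SNP association records
#'
#' Ensures the canonical column set (`snp`, `chr`, `pos`, `a1`, `a2`, `freq`,
#' `b`, `se`, `p`, `n`), coerces types, and (optionally) enforces the record
#' invariants: `se > 0`, `p` in (0, 1], `freq` in \[0, 1\] or `NA`,
#' `n >= 2`, `a1 != a2`, and consistency of `p` with `|b/se|` under the
#' two-sided normal approximation (20\% relative tolerance on the z scale,
#' only checked where the implied z exceeds 1).
#'
#' @param df data frame with at least `snp`, `a1`, `a2`, `b`, `se`, `p`, `n`.
#' @param validate logical; run invariant checks.
#' @param lines optional integer vector of originating file line numbers used
#'   in error messages.
#' @return data frame with canonical columns.
#' @keywords internal
as_sumstat_records <- function(df, validate = TRUE, lines = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"chr" %in% names(df)) df$chr <- NA_character_
  if (!"pos" %in% names(df)) df$pos <- NA_integer_
  need <- setdiff(c("snp", "a1", "a2", "b", "se", "p", "n"), names(df))
  if (length(need)) {
    stop("format error: missing column(s): ", paste(need, collapse = ", "))
  }
  if (!"freq" %in% names(df)) df$freq <- NA_real_
  if (is.null(lines)) lines <- seq_len(nrow(df))

  num <- function(x) suppressWarnings(as.numeric(x))
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$pos <- as.integer(num(df$pos))
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  missing_tok <- function(x) is.na(x) | x %in% c("NA", ".", "")
  freq_raw <- as.character(df$freq)
  df$freq <- ifelse(missing_tok(freq_raw), NA_real_, num(freq_raw))
  for (cc in c("b", "se", "p")) {
    raw <- as.character(df[[cc]])
    df[[cc]] <- num(raw)
    bad <- which(is.na(df[[cc]]))
    if (length(bad)) {
      stop("row error: non-numeric '", cc, "' at line(s) ",
           paste(lines[bad], collapse = ", "))
    }
  }
  df$n <- num(df$n)

  if (validate) {
    probs <- character(0)
    add <- function(idx, what) {
      if (length(idx)) {
        probs <<- c(probs, paste0(what, " at line(s) ",
                                  paste(lines[idx], collapse = ", ")))
      }
    }
    add(which(!(df$se > 0)), "se must be > 0")
    add(which(!(df$p > 0 & df$p <= 1)), "p must be in (0, 1]")
    add(which(!is.na(df$freq) & (df$freq < 0 | df$freq > 1)),
        "freq must be in [0, 1]")
    add(which(!(df$n >= 2)), "N must be >= 2")
    add(which(df$a1 == df$a2), "A1 must differ from A2")
    ok <- df$se > 0 & df$p > 0 & df$p <= 1
    z_rep <- ifelse(ok, abs(df$b / df$se), NA_real_)
    z_imp <- ifelse(ok, qnorm(df$p / 2, lower.tail = FALSE), NA_real_)
    chk <- which(ok & z_imp > 1 &
                   abs(z_imp - z_rep) > 0.2 * pmax(z_imp, .Machine$double.eps))
    add(chk, "p inconsistent with |b/se| (two-sided normal, 20% tolerance)")
    if (length(probs)) stop("invalid summary statistics:\n  ",
                            paste(probs, collapse = "\n  "))
  }
  df[, .REC_COLS]
}

#' Construct a set of summary statistics for one trait or molecular probe
#'
#' @param trait_id character scalar identifying the trait/probe.
#' @param records data frame of per-SNP records (see [as_sumstat_records()]).
#' @param validate logical; enforce record invariants.
#' @return object of class `sumstat_set`.
#' @export
sumstat_set <- function(trait_id, records, validate = TRUE) {
  records <- as_sumstat_records(records, validate = validate)
  dup <- unique(records$snp[duplicated(records$snp)])
  if (length(dup)) {
    stop("duplicate snp_id in set '", trait_id, "': ",
         paste(head(dup, 5), collapse = ", "))
  }
  structure(list(trait_id = trait_id, records = records),
            class = "sumstat_set")
}

#' Construct a cis-QTL table for one probe/gene
#'
#' All records must lie within `cis_window` of `probe_pos` on `probe_chr`.
#'
#' @param probe_id,probe_chr,probe_pos probe identifier and position.
#' @param records data frame of per-SNP records with `chr` and `pos` set.
#' @param cis_window half-width of the cis window in bp (default 1 Mb).
#' @param validate logical; enforce invariants.
#' @return object of class `qtl_table`.
#' @export
qtl_table <- function(probe_id, probe_chr, probe_pos, records,
                      cis_window = 1e6, validate = TRUE) {
  records <- as_sumstat_records(records, validate = validate)
  if (validate) {
    bad <- which(records$chr != as.character(probe_chr) |
                   abs(records$pos - as.integer(probe_pos)) > cis_window)
    if (length(bad)) {
      stop("probe '", probe_id, "': ", length(bad),
           " record(s) outside the cis window (", cis_window, " bp), e.g. ",
           records$snp[bad[1]])
    }
  }
  structure(list(probe_id = probe_id, probe_chr = as.character(probe_chr),
                 probe_pos = as.integer(probe_pos), records = records,
                 cis_window = cis_window),
            class = "qtl_table")
}

# Accessors shared by sumstat_set / qtl_table ------------------------------

ss_records <- function(x) {
  if (inherits(x, c("sumstat_set", "qtl_table"))) return(x$records)
  if (is.data.frame(x)) return(x)
  stop("expected a sumstat_set, qtl_table or data frame")
}

trait_of <- function(x) {
  if (inherits(x, "qtl_table")) return(x$probe_id)
  if (inherits(x, "sumstat_set")) return(x$trait_id)
  "trait"
}

with_records <- function(x, records) {
  x$records <- records
  x
}

#' @export
print.sumstat_set <- function(x, ...) {
  cat("<sumstat_set> trait:", x$trait_id, "-", nrow(x$records), "SNPs\n")
  invisible(x)
}

#' @export
print.qtl_table <- function(x, ...) {
  cat("<qtl_table> probe:", x$probe_id, "at", x$probe_chr, ":", x$probe_pos,
      "-", nrow(x$records), "cis SNPs\n")
  invisible(x)
}

# Readers / writers --------------------------------------------------------

.read_table_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    comment.char = "#")
}

#' Read summary statistics from a text file
#'
#' Two dialects are supported.  `"ma"` is the COJO-style layout
#' `SNP A1 A2 freq b se p N` and yields a single [sumstat_set()].  `"qtl"`
#' adds probe columns (`Probe ProbeChr ProbePos`) and per-SNP coordinates
#' (`Chr Pos`) and yields a list of [qtl_table()], one per probe, ordered by
#' probe id.  Files may be gzip-compressed.
#'
#' @param path file path.
#' @param format `"ma"` or `"qtl"`.
#' @param trait_id trait identifier for `"ma"` (default: file base name).
#' @param validate logical; enforce record invariants (malformed rows are
#'   reported with their line numbers).
#' @param cis_window cis-window half-width used to validate `"qtl"` input.
#' @return a `sumstat_set` or a list of `qtl_table`.
#' @export
read_sumstats <- function(path, format = c("ma", "qtl"), trait_id = NULL,
                          validate = TRUE, cis_window = 1e6) {
  format <- match.arg(format)
  raw <- .read_table_chr(path)
  req <- if (format == "ma") .MA_COLS else .QTL_COLS
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("format error in '", path, "': missing column(s): ",
         paste(miss, collapse = ", "))
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (format == "ma") {
    rec <- data.frame(snp = raw$SNP, a1 = raw$A1, a2 = raw$A2,
                      freq = raw$freq, b = raw$b, se = raw$se, p = raw$p,
                      n = raw$N, stringsAsFactors = FALSE)
    rec <- as_sumstat_records(rec, validate = validate, lines = lines)
    if (is.null(trait_id)) {
      trait_id <- sub("\\.(ma|txt|tsv)(\\.gz)?$", "", basename(path))
    }
    return(sumstat_set(trait_id, rec, validate = FALSE))
  }
  rec <- data.frame(snp = raw$SNP, chr = raw$Chr, pos = raw$Pos,
                    a1 = raw$A1, a2 = raw$A2, freq = raw$freq, b = raw$b,
                    se = raw$se, p = raw$p, n = raw$N,
                    stringsAsFactors = FALSE)
  rec <- as_sumstat_records(rec, validate = validate, lines = lines)
  probes <- split(seq_len(nrow(rec)), raw$Probe)
  out <- lapply(names(probes), function(pr) {
    idx <- probes[[pr]]
    qtl_table(pr, raw$ProbeChr[idx[1]], as.integer(raw$ProbePos[idx[1]]),
              rec[idx, , drop = FALSE], cis_window = cis_window,
              validate = validate)
  })
  names(out) <- names(probes)
  out[order(names(out))]
}

#' Write summary statistics to a text file
#'
#' Inverse of [read_sumstats()]; values round-trip to at least 10
#' significant digits.
#'
#' @param x a `sumstat_set`, a `qtl_table`, or a list of `qtl_table`.
#' @param path output path.
#' @param format `"ma"` or `"qtl"`.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, format = c("ma", "qtl")) {
  format <- match.arg(format)
  fmt_num <- function(v) ifelse(is.na(v), "NA", format(v, digits = 15,
                                                      scientific = NA,
                                                      trim = TRUE))
  if (format == "ma") {
    rec <- ss_records(x)
    out <- data.frame(SNP = rec$snp, A1 = rec$a1, A2 = rec$a2,
                      freq = fmt_num(rec$freq), b = fmt_num(rec$b),
                      se = fmt_num(rec$se), p = fmt_num(rec$p),
                      N = fmt_num(rec$n), stringsAsFactors = FALSE)
  } else {
    tabs <- if (inherits(x, "qtl_table")) list(x) else x
    out <- do.call(rbind, lapply(tabs, function(q) {
      rec <- q$records
      data.frame(Probe = q$probe_id, ProbeChr = q$probe_chr,
                 ProbePos = q$probe_pos, SNP = rec$snp, Chr = rec$chr,
                 Pos = rec$pos, A1 = rec$a1, A2 = rec$a2,
                 freq = fmt_num(rec$freq), b = fmt_num(rec$b),
                 se = fmt_num(rec$se), p = fmt_num(rec$p),
                 N = fmt_num(rec$n), stringsAsFactors = FALSE)
    }))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an LD reference panel from a dosage matrix
#'
#' @param dosages numeric matrix, rows = individuals, columns = SNPs, values
#'   in \[0, 2\] (count of the effect allele `a1`).
#' @param snp character vector of SNP ids (column order).
#' @param a1,a2 effect / other allele per SNP (may be `NA`).
#' @param iid optional individual ids.
#' @return object of class `ld_panel`.
#' @export
ld_panel <- function(dosages, snp, a1 = NA_character_, a2 = NA_character_,
                     iid = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(snp)) stop("ncol(dosages) != length(snp)")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosage values must lie in [0, 2]")
  }
  a1 <- rep_len(toupper(as.character(a1)), length(snp))
  a2 <- rep_len(toupper(as.character(a2)), length(snp))
  if (is.null(iid)) iid <- paste0("id", seq_len(nrow(dosages)))
  colnames(dosages) <- snp
  structure(list(snp_index = data.frame(snp = as.character(snp), a1 = a1,
                                        a2 = a2, stringsAsFactors = FALSE),
                 dosages = dosages, n_individuals = nrow(dosages),
                 iid = iid),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("<ld_panel>", x$n_individuals, "individuals x",
      nrow(x$snp_index), "SNPs\n")
  invisible(x)
}

#' Read an LD panel from a dosage TSV
#'
#' First column is the individual id; remaining column names are either
#' `snp:A1:A2` or bare SNP ids (alleles then unknown).
#'
#' @param path file path.
#' @return an [ld_panel()].
#' @export
read_ld_panel <- function(path) {
  raw <- .read_table_chr(path)
  if (ncol(raw) < 2) stop("LD panel needs an IID column plus >= 1 SNP")
  iid <- raw[[1]]
  cols <- names(raw)[-1]
  parts <- strsplit(cols, ":", fixed = TRUE)
  snp <- vapply(parts, `[`, "", 1L)
  a1 <- vapply(parts, function(p) if (length(p) == 3) p[2] else NA_character_, "")
  a2 <- vapply(parts, function(p) if (length(p) == 3) p[3] else NA_character_, "")
  d <- vapply(raw[-1], function(col) suppressWarnings(as.numeric(col)),
              numeric(nrow(raw)))
  d <- matrix(d, nrow = nrow(raw))
  if (anyNA(d)) stop("non-numeric dosage values in '", path, "'")
  ld_panel(d, snp, a1, a2, iid = iid)
}

#' Write an LD panel to a dosage TSV
#'
#' @param panel an [ld_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_panel <- function(panel, path) {
  si <- panel$snp_index
  nm <- ifelse(is.na(si$a1) | is.na(si$a2), si$snp,
               paste(si$snp, si$a1, si$a2, sep = ":"))
  out <- data.frame(IID = panel$iid, stringsAsFactors = FALSE)
  d <- as.data.frame(panel$dosages)
  names(d) <- nm
  utils::write.table(cbind(out, d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rare-variant position table
#'
#' Columns: `variant_id chrom pos ref alt condition`.
#'
#' @param path file path.
#' @return data frame of class `rare_variant_table`.
#' @export
read_rare_variants <- function(path) {
  raw <- .read_table_chr(path)
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "condition")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("format error: missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(variant_id = raw$variant_id, chrom = raw$chrom,
                    pos = suppressWarnings(as.integer(raw$pos)),
                    ref = raw$ref, alt = raw$alt, condition = raw$condition,
                    stringsAsFactors = FALSE)
  if (anyNA(out$pos) || any(out$pos < 1)) {
    stop("rare-variant positions must be integers >= 1")
  }
  class(out) <- c("rare_variant_table", "data.frame")
  out
}

# Harmonization ------------------------------------------------------------

#' Harmonize two summary-statistic sets to a common allele frame
#'
#' Restricts both sets to their shared SNPs and aligns effect alleles to the
#' reference frame (the LD panel's alleles when available, otherwise set
#' `a`'s alleles).  Where a set's A1/A2 are swapped relative to the
#' reference, `b` is negated and `freq` replaced by `1 - freq`.
#' Strand-ambiguous SNPs (A/T, C/G) are dropped by default; with
#' `ambiguous = "freq"` they are kept when both the record and the panel are
#' clearly away from 50\% frequency (`|eaf - 0.5| > freq_margin`) and
#' oriented by frequency.  Records whose alleles match neither orientation
#' are dropped and logged.  The operation is idempotent.
#'
#' @param a,b `sumstat_set` or `qtl_table` objects sharing >= 1 SNP.
#' @param panel optional [ld_panel()] providing the reference allele frame
#'   (and reference frequencies for `ambiguous = "freq"`).
#' @param ambiguous `"drop"` (default) or `"freq"`.
#' @param freq_margin minimum distance of eaf from 0.5 required to orient an
#'   ambiguous SNP by frequency.
#' @return list with elements `a`, `b` (aligned objects of the same classes)
#'   and `dropped` (data frame of snp/reason).
#' @export
harmonize <- function(a, b, panel = NULL, ambiguous = c("drop", "freq"),
                      freq_margin = 0.08) {
  ambiguous <- match.arg(ambiguous)
  ra <- ss_records(a)
  rb <- ss_records(b)
  common <- intersect(ra$snp, rb$snp)
  if (!length(common)) stop("no SNPs shared between the two sets")

  use_panel <- !is.null(panel) && !all(is.na(panel$snp_index$a1))
  if (use_panel) {
    ref <- panel$snp_index[match(common, panel$snp_index$snp), ]
    keep <- !is.na(ref$snp) & !is.na(ref$a1)
    ref <- ref[keep, , drop = FALSE]
    common <- ref$snp
    panel_eaf <- colMeans(panel$dosages[, match(common,
                                                panel$snp_index$snp),
                                        drop = FALSE]) / 2
  } else {
    ref <- ra[match(common, ra$snp), c("snp", "a1", "a2")]
    panel_eaf <- rep(NA_real_, length(common))
  }

  dropped <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_snp <- function(snp, reason) {
    dropped <<- rbind(dropped, data.frame(snp = snp, reason = reason,
                                          stringsAsFactors = FALSE))
  }

  amb <- is_ambiguous_pair(ref$a1, ref$a2)
  if (ambiguous == "drop" && any(amb)) {
    drop_snp(ref$snp[amb], "strand-ambiguous")
    ref <- ref[!amb, , drop = FALSE]
    panel_eaf <- panel_eaf[!amb]
    common <- ref$snp
  }

  align_one <- function(rec) {
    idx <- match(common, rec$snp)
    rec <- rec[idx, , drop = FALSE]
    same <- rec$a1 == ref$a1 & rec$a2 == ref$a2
    swap <- rec$a1 == ref$a2 & rec$a2 == ref$a1
    amb_i <- is_ambiguous_pair(ref$a1, ref$a2)
    ok <- same | swap
    if (ambiguous == "freq") {
      # orient ambiguous SNPs by allele frequency against the panel
      resolv <- amb_i & ok & !is.na(rec$freq) & !is.na(panel_eaf) &
        abs(rec$freq - 0.5) > freq_margin & abs(panel_eaf - 0.5) > freq_margin
      flip_freq <- resolv & (sign(rec$freq - 0.5) != sign(panel_eaf - 0.5))
      keep_freq <- resolv & !flip_freq
      same[resolv] <- keep_freq[resolv]
      swap[resolv] <- flip_freq[resolv]
      ok[amb_i] <- resolv[amb_i]
    } else {
      ok[amb_i] <- FALSE
    }
    rec$b[swap] <- -rec$b[swap]
    rec$freq[swap] <- 1 - rec$freq[swap]
    rec$a1[swap | same] <- ref$a1[swap | same]
    rec$a2[swap | same] <- ref$a2[swap | same]
    list(rec = rec, ok = ok)
  }

  aa <- align_one(ra)
  bb <- align_one(rb)
  keep <- aa$ok & bb$ok
  bad <- common[!keep]
  if (length(bad)) drop_snp(bad, "allele mismatch or unresolvable")
  if (!any(keep)) stop("no SNPs left after harmonization")

  out_a <- with_records(a, aa$rec[keep, , drop = FALSE])
  out_b <- with_records(b, bb$rec[keep, , drop = FALSE])
  list(a = out_a, b = out_b, dropped = dropped)
}

#' Pairwise allelic correlation from an LD reference panel
#'
#' Pearson correlation of dosage columns, sign-aligned to each SNP's effect
#' allele (dosages count the effect allele).  Optional shrinkage toward the
#' identity guarantees positive definiteness downstream.
#'
#' @param panel an [ld_panel()].
#' @param snps ordered character vector of SNP ids (all must be present).
#' @param shrinkage shrinkage weight `lambda` in \[0, 1); the returned matrix
#'   is `(1 - lambda) * R + lambda * I`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(panel, snps, shrinkage = 0) {
  idx <- match(snps, panel$snp_index$snp)
  if (anyNA(idx)) {
    stop("SNP(s) absent from panel: ",
         paste(head(snps[is.na(idx)], 5), collapse = ", "))
  }
  if (panel$n_individuals < 30) {
    warning("LD panel has fewer than 30 individuals; r estimates are noisy")
  }
  D <- panel$dosages[, idx, drop = FALSE]
  v <- apply(D, 2, stats::var)
  if (any(v == 0)) {
    stop("monomorphic SNP(s) in panel: ",
         paste(snps[v == 0], collapse = ", "))
  }
  R <- stats::cor(D)
  diag(R) <- 1
  if (shrinkage > 0) {
    R <- (1 - shrinkage) * R + shrinkage * diag(nrow(R))
  }
  dimnames(R) <- list(snps, snps)
  R
}

# Generic TSV report I/O ----------------------------------------------------

#' Write a result table as TSV
#'
#' Deterministic column order (the data frame's own order); an empty table
#' yields a header-only file.  Round-trips through [read_report()] to at
#' least 10 significant digits.
#'
#' @param x data frame (or object with an `as.data.frame` method).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}
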