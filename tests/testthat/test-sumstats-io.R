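# I/O, validation, harmonization and LD computation.

test_that("a .ma file parses into a sumstat_set", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), A1 = c("A", "T", "C"),
                   A2 = c("G", "C", "T"), freq = c(0.3, 0.5, 0.12),
                   b = c(0.02, -0.01, 0.005), se = c(0.01, 0.012, 0.011),
                   p = c(0.0455, 0.4047, 0.6494), N = c(1000, 1000, 1000))
  path <- write_ma_file(df)
  ss <- read_sumstats(path, "ma", trait_id = "bmi")
  expect_s3_class(ss, "sumstat_set")
  expect_identical(nrow(ss$records), 3L)
  expect_identical(ss$records$snp, c("rs1", "rs2", "rs3"))
  expect_equal(ss$records$b, df$b)
  # gzip transparency
  gz <- tempfile(fileext = ".ma.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(path), con)
  close(con)
  expect_equal(read_sumstats(gz, "ma")$records$b, df$b)
})

test_that("malformed rows are rejected with line numbers", {
  df <- data.frame(SNP = c("rs1", "rs2"), A1 = c("A", "T"),
                   A2 = c("G", "C"), freq = c(0.3, 0.5),
                   b = c(0.02, -0.01), se = c(0, 0.012),
                   p = c(0.0455, 0.4047), N = c(1000, 1000))
  expect_error(read_sumstats(write_ma_file(df), "ma"), "se.*line\\(s\\) 2")
  df$se <- c("oops", "0.012")
  expect_error(read_sumstats(write_ma_file(df), "ma"), "non-numeric 'se'")
  df$se <- c("0.01", "0.012")
  df$SNP <- c("rs1", "rs1")
  expect_error(read_sumstats(write_ma_file(df), "ma"), "duplicate snp_id")
})

test_that("a missing column is reported by name", {
  df <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", b = 0.1, se = 0.05,
                   p = 0.0455, N = 500)
  expect_error(read_sumstats(write_ma_file(df), "ma"), "freq")
})

test_that("p consistent with b/se is accepted at 20% z tolerance", {
  # printed p = 3e-10 (z = 6.3) against b/se = 6.25: accepted
  df <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", freq = 0.3,
                   b = 0.01, se = 0.0016, p = 3e-10, N = 300000)
  expect_s3_class(read_sumstats(write_ma_file(df), "ma"), "sumstat_set")
  # grossly inconsistent p: z implied 6.3 vs reported 2 -> rejected
  df$b <- 0.0032
  expect_error(read_sumstats(write_ma_file(df), "ma"), "inconsistent")
})

test_that("qtl dialect round-trips probe tables and enforces cis windows", {
  rec <- data.frame(snp = c("rs1", "rs2"), chr = "3", pos = c(1.0e8, 1.005e8),
                    a1 = c("A", "T"), a2 = c("G", "C"), freq = c(0.2, 0.4),
                    b = c(0.5, 0.1), se = c(0.05, 0.04),
                    p = 2 * pnorm(-abs(c(10, 2.5))), n = 5000)
  q <- qtl_table("cg1", "3", 1.0e8, rec)
  path <- tempfile(fileext = ".qtl.txt")
  write_sumstats(q, path, "qtl")
  back <- read_sumstats(path, "qtl")
  expect_length(back, 1)
  expect_equal(back[["cg1"]]$records$b, rec$b, tolerance = 1e-10)
  expect_equal(back[["cg1"]]$probe_pos, 1.0e8)
  # record outside the cis window
  rec$pos[2] <- 1.2e8
  expect_error(qtl_table("cg1", "3", 1.0e8, rec), "cis window")
})

test_that("harmonize flips swapped alleles and drops mismatches", {
  panel <- panel_from_cols(rbinom(200, 2, 0.7), rbinom(200, 2, 0.4),
                           rbinom(200, 2, 0.3),
                           snp = c("rs1", "rs2", "rs3"),
                           a1 = c("C", "A", "A"), a2 = c("T", "G", "G"))
  a <- sumstat_set("x", data.frame(
    snp = c("rs1", "rs2", "rs3"), a1 = c("T", "A", "A"),
    a2 = c("C", "G", "G"), freq = c(0.3, 0.5, 0.2),
    b = c(0.2, 0.1, -0.3), se = c(0.05, 0.05, 0.05),
    p = 2 * pnorm(-abs(c(0.2, 0.1, -0.3) / 0.05)), n = 1000))
  b <- sumstat_set("y", data.frame(
    snp = c("rs1", "rs2", "rs3"), a1 = c("C", "A", "C"),
    a2 = c("T", "G", "T"), freq = c(0.7, 0.5, 0.2),
    b = c(0.1, 0.2, 0.3), se = c(0.05, 0.05, 0.05),
    p = 2 * pnorm(-abs(c(0.1, 0.2, 0.3) / 0.05)), n = 1000))
  h <- harmonize(a, b, panel)
  # rs1 in set a was swapped relative to the panel: flip
  ra <- h$a$records
  expect_equal(ra$b[ra$snp == "rs1"], -0.2)
  expect_equal(ra$freq[ra$snp == "rs1"], 0.7)
  expect_equal(ra$a1[ra$snp == "rs1"], "C")
  # rs3 alleles in set b (C/T) match neither orientation of panel A/G: gone
  expect_false("rs3" %in% ra$snp)
  expect_true("rs3" %in% h$dropped$snp)
  # idempotent
  h2 <- harmonize(h$a, h$b, panel)
  expect_equal(h2$a$records, h$a$records)
  expect_equal(h2$b$records, h$b$records)
})

test_that("strand-ambiguous SNPs are dropped by default, kept by frequency", {
  set.seed(1)
  d1 <- rbinom(400, 2, 0.9)
  panel <- panel_from_cols(d1, rbinom(400, 2, 0.4),
                           snp = c("rs1", "rs2"),
                           a1 = c("A", "A"), a2 = c("T", "G"))
  mk <- function(freq1) sumstat_set("t", data.frame(
    snp = c("rs1", "rs2"), a1 = c("A", "A"), a2 = c("T", "G"),
    freq = c(freq1, 0.4), b = c(0.1, 0.1), se = 0.05,
    p = 2 * pnorm(-2), n = 1000))
  h <- harmonize(mk(0.9), mk(0.9), panel)
  expect_false("rs1" %in% h$a$records$snp)   # A/T dropped
  hf <- harmonize(mk(0.9), mk(0.9), panel, ambiguous = "freq")
  expect_true("rs1" %in% hf$a$records$snp)   # freq 0.9 matches panel ~0.9
  expect_equal(hf$a$records$b[hf$a$records$snp == "rs1"], 0.1)
  # frequency on the other side of 0.5: orientation flip
  hg <- harmonize(mk(0.1), mk(0.1), panel, ambiguous = "freq")
  expect_equal(hg$a$records$b[hg$a$records$snp == "rs1"], -0.1)
  # near 0.5 cannot be resolved: dropped even in freq mode
  hh <- harmonize(mk(0.52), mk(0.52), panel, ambiguous = "freq")
  expect_false("rs1" %in% hh$a$records$snp)
})

test_that("harmonize errors on an empty intersection", {
  a <- sumstat_set("x", data.frame(snp = "rs1", a1 = "A", a2 = "G",
                                   freq = 0.2, b = 0.1, se = 0.05,
                                   p = 0.0455, n = 100))
  b <- sumstat_set("y", data.frame(snp = "rs9", a1 = "A", a2 = "G",
                                   freq = 0.2, b = 0.1, se = 0.05,
                                   p = 0.0455, n = 100))
  expect_error(harmonize(a, b), "shared")
})

test_that("ld_matrix: diagonal, perfect LD, monomorphic error, PSD", {
  set.seed(42)
  g1 <- rbinom(503, 2, 0.3)
  g2 <- rbinom(503, 2, 0.4)
  panel <- panel_from_cols(g1, g2, g1, rep(1, 503),
                           snp = c("a", "b", "dup_a", "mono"))
  R <- ld_matrix(panel, c("a", "b", "dup_a"))
  expect_equal(diag(R), c(a = 1, b = 1, dup_a = 1))
  expect_equal(R["a", "dup_a"], 1)              # duplicated column
  expect_true(all(abs(R) <= 1 + 1e-12))
  expect_error(ld_matrix(panel, c("a", "mono")), "mono")
  expect_error(ld_matrix(panel, c("a", "nope")), "absent")
  # symmetric PSD up to tolerance; exactly PSD after shrinkage
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8)
  Rs <- ld_matrix(panel, c("a", "b", "dup_a"), shrinkage = 0.1)
  expect_true(min(eigen(Rs, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)
})

test_that("independent SNPs at n = 503 show |r| < 0.15", {
  set.seed(7)
  cols <- lapply(1:8, function(i) rbinom(503, 2, runif(1, 0.2, 0.5)))
  panel <- do.call(panel_from_cols, cols)
  R <- ld_matrix(panel, paste0("rs", 1:8))
  expect_true(max(abs(R[upper.tri(R)])) < 0.15)
})

test_that("small-panel warning fires below 30 individuals", {
  panel <- panel_from_cols(rbinom(20, 2, 0.4), rbinom(20, 2, 0.4))
  expect_warning(ld_matrix(panel, c("rs1", "rs2")), "fewer than 30")
})

test_that("LD panel round-trips through its TSV format", {
  set.seed(3)
  panel <- panel_from_cols(rbinom(50, 2, 0.3), rbinom(50, 2, 0.45),
                           snp = c("rs1", "rs2"), a1 = c("A", "T"),
                           a2 = c("G", "C"))
  path <- tempfile(fileext = ".tsv")
  write_ld_panel(panel, path)
  back <- read_ld_panel(path)
  expect_equal(back$dosages, panel$dosages, ignore_attr = TRUE)
  expect_equal(back$snp_index, panel$snp_index)
})

test_that("write_report produces deterministic header-only and round-trips", {
  empty <- data.frame(probe_id = character(0), b_smr = numeric(0))
  p1 <- tempfile(fileext = ".tsv")
  write_report(empty, p1)
  expect_identical(readLines(p1), "probe_id\tb_smr")
  df <- data.frame(probe_id = "cg1", top_snp = "rs3",
                   b_smr = -0.0208333333333, p_smr = 4.1e-10,
                   p_heidi = 0.5, n_snps = 18L)
  p2 <- tempfile(fileext = ".tsv")
  write_report(df, p2)
  back <- read_report(p2)
  expect_equal(back$b_smr, df$b_smr, tolerance = 1e-10)
  expect_equal(back$p_smr, df$p_smr, tolerance = 1e-10)
  expect_error(write_report(df, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})

test_that("rare-variant tables validate positions", {
  path <- tempfile()
  writeLines(c("variant_id\tchrom\tpos\tref\talt\tcondition",
               "v1\t2\t25400100\tC\tT\tobesity"), path)
  rv <- read_rare_variants(path)
  expect_s3_class(rv, "rare_variant_table")
  expect_identical(rv$pos, 25400100L)
  writeLines(c("variant_id\tchrom\tpos\tref\talt\tcondition",
               "v1\t2\t0\tC\tT\tobesity"), path)
  expect_error(read_rare_variants(path), ">= 1")
})
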