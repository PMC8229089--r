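# Instrument selection, GLS MR, outlier removal, reverse filter.

test_that("greedy LD pruning keeps {A, C} in the three-SNP example", {
  set.seed(31)
  gA <- rbinom(800, 2, 0.4)
  keepmask <- rbinom(800, 1, 0.95)
  gB <- ifelse(keepmask == 1, gA, rbinom(800, 2, 0.4))  # r^2 ~ 0.8 with A
  gC <- rbinom(800, 2, 0.3)                             # independent
  panel <- panel_from_cols(gA, gB, gC, snp = c("A", "B", "C"))
  R <- ld_matrix(panel, c("A", "B", "C"))
  expect_gt(R["A", "B"]^2, 0.05)
  expect_lt(R["A", "C"]^2, 0.05)
  expect_lt(R["B", "C"]^2, 0.05)
  mk <- function(p, id) sumstat_set(id, data.frame(
    snp = c("A", "B", "C"), a1 = "A", a2 = "G", freq = 0.3,
    b = qnorm(p / 2, lower.tail = FALSE) * 0.05, se = 0.05, p = p,
    n = 50000), validate = FALSE)
  instr <- select_instrument(mk(c(1e-20, 1e-15, 1e-9), "x"),
                             mk(c(0.5, 0.5, 0.5), "y"), panel)
  # oracle: brute-force greedy on the observed R, sorted by p
  greedy <- function(ord, R2, thr) {
    keep <- ord[1]
    for (i in ord[-1]) if (all(R2[i, keep] < thr)) keep <- c(keep, i)
    keep
  }
  expect_identical(sort(instr$snps$snp),
                   sort(c("A", "B", "C")[greedy(1:3, R^2, 0.05)]))
  expect_identical(sort(instr$snps$snp), c("A", "C"))
})

test_that("mutually linked SNPs collapse to the single best one", {
  g <- rbinom(600, 2, 0.4)
  panel <- panel_from_cols(g, g, g, snp = c("s1", "s2", "s3"))
  mk <- function(p, id) sumstat_set(id, data.frame(
    snp = c("s1", "s2", "s3"), a1 = "A", a2 = "G", freq = 0.3,
    b = qnorm(p / 2, lower.tail = FALSE) * 0.05, se = 0.05, p = p,
    n = 50000), validate = FALSE)
  instr <- select_instrument(mk(c(1e-10, 1e-30, 1e-12), "x"),
                             mk(rep(0.5, 3), "y"), panel)
  expect_identical(instr$snps$snp, "s2")
  expect_identical(instr$provenance$n_after_prune, 1L)
})

test_that("no exposure-significant SNP yields a typed no-instrument outcome", {
  g <- rbinom(600, 2, 0.4)
  panel <- panel_from_cols(g, snp = "s1")
  mk <- function(p, id) sumstat_set(id, data.frame(
    snp = "s1", a1 = "A", a2 = "G", freq = 0.3, b = 0.01, se = 0.05,
    p = p, n = 1000), validate = FALSE)
  out <- select_instrument(mk(1e-4, "x"), mk(0.5, "y"), panel)
  expect_true(is_no_instrument(out))
  expect_match(out$reason, "no SNP at p")
})

test_that("single-SNP MR is the Wald ratio with the delta-method SE", {
  instr <- make_instrument(b_zx = 0.5, se_zx = 0.05, b_zy = 0.1,
                           se_zy = 0.02)
  res <- gls_mr(instr)
  expect_equal(res$b_xy, 0.2, tolerance = 1e-12)
  # hand evaluation: sqrt((0.02^2 + 0.2^2 * 0.05^2) / 0.5^2)
  expect_equal(res$se_xy, 0.04472136, tolerance = 1e-6)
  expect_identical(res$method, "wald_ratio")
})

test_that("k identical independent SNPs shrink the SE by sqrt(k)", {
  one <- gls_mr(make_instrument(0.5, 0.05, 0.1, 0.02))
  four <- gls_mr(make_instrument(rep(0.5, 4), rep(0.05, 4), rep(0.1, 4),
                                 rep(0.02, 4)))
  expect_equal(four$b_xy, one$b_xy, tolerance = 1e-12)
  expect_equal(four$se_xy, one$se_xy / 2, tolerance = 1e-12)
})

test_that("with diagonal covariance GLS equals the IVW oracle to 1e-10", {
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    b_zx <- runif(k, 0.2, 0.8) * sample(c(-1, 1), k, TRUE)
    se_zx <- runif(k, 0.02, 0.08)
    b_zy <- runif(k, -0.1, 0.1)
    se_zy <- runif(k, 0.01, 0.04)
    res <- gls_mr(make_instrument(b_zx, se_zx, b_zy, se_zy))
    orc <- ivw_oracle(b_zx, se_zx, b_zy, se_zy)
    expect_equal(res$b_xy, orc$b, tolerance = 1e-10)
    expect_equal(res$se_xy, orc$se, tolerance = 1e-10)
    expect_equal(res$p_xy, orc$p, tolerance = 1e-10)
  }
})

test_that("with full covariance GLS matches an independent solve to 1e-8", {
  set.seed(34)
  for (i in 1:10) {
    k <- sample(3:7, 1)
    A <- matrix(runif(k * k, -0.3, 0.3), k)
    R <- cov2cor(crossprod(A) + diag(k))
    b_zx <- runif(k, 0.2, 0.8)
    se_zx <- runif(k, 0.02, 0.08)
    b_zy <- runif(k, -0.1, 0.1)
    se_zy <- runif(k, 0.01, 0.04)
    res <- gls_mr(make_instrument(b_zx, se_zx, b_zy, se_zy, ld = R))
    # independent algebraic path: build V explicitly, invert with solve()
    b <- b_zy / b_zx
    V <- (R * (outer(se_zy, se_zy) + outer(b, b) * outer(se_zx, se_zx))) /
      outer(b_zx, b_zx)
    diag(V) <- (se_zy^2 + b^2 * se_zx^2) / b_zx^2
    Vi <- solve(V)
    ones <- rep(1, k)
    b_hat <- as.numeric((ones %*% Vi %*% b) / (ones %*% Vi %*% ones))
    se_hat <- as.numeric(1 / sqrt(ones %*% Vi %*% ones))
    expect_equal(res$b_xy, b_hat, tolerance = 1e-8)
    expect_equal(res$se_xy, se_hat, tolerance = 1e-8)
  }
})

test_that("scale equivariance: rescaling the exposure rescales b_xy only", {
  set.seed(35)
  b_zx <- runif(5, 0.3, 0.7)
  se_zx <- runif(5, 0.02, 0.06)
  b_zy <- runif(5, -0.05, 0.08)
  se_zy <- runif(5, 0.01, 0.03)
  A <- matrix(runif(25, -0.2, 0.2), 5)
  R <- cov2cor(crossprod(A) + diag(5))
  base <- gls_mr(make_instrument(b_zx, se_zx, b_zy, se_zy, ld = R))
  for (cc in c(3.7, -0.4)) {
    sc <- gls_mr(make_instrument(cc * b_zx, abs(cc) * se_zx, b_zy, se_zy,
                                 ld = R))
    expect_equal(sc$b_xy, base$b_xy / cc, tolerance = 1e-10)
    expect_equal(sc$p_xy, base$p_xy, tolerance = 1e-10)
  }
})

test_that("outlier removal: exact shared ratio removes nothing; k < 3 skips", {
  instr <- make_instrument(c(0.5, 0.4, 0.6), rep(0.02, 3),
                           c(0.05, 0.04, 0.06), rep(0.002, 3))
  out <- remove_pleiotropic(instr)
  expect_identical(nrow(out$snps), 3L)
  expect_length(out$provenance$removed_pleiotropic, 0)
  two <- make_instrument(c(0.5, 0.4), c(0.02, 0.02), c(0.05, 0.2),
                         c(0.002, 0.002))
  out2 <- remove_pleiotropic(two)
  expect_identical(nrow(out2$snps), 2L)
  expect_true("outlier test skipped" %in% out2$flags)
})

test_that("a gross pleiotropic outlier is removed and recorded", {
  # five concordant SNPs (ratio 0.1) plus one deviating SNP (ratio 0.16);
  # the provisional fit stays near 0.1, so only the deviant is flagged
  instr <- make_instrument(rep(0.5, 6), rep(0.02, 6),
                           c(rep(0.05, 5), 0.08), rep(0.005, 6))
  out <- remove_pleiotropic(instr)
  expect_identical(out$provenance$removed_pleiotropic, "rs6")
  expect_identical(nrow(out$snps), 5L)
  # all removed -> typed outcome
  far <- make_instrument(c(0.5, 0.5, 0.5), rep(1e-4, 3),
                         c(0.9, -0.9, 0.4), rep(1e-4, 3))
  expect_true(is_no_instrument(remove_pleiotropic(far)))
})

test_that("planted pleiotropic SNP is the one removed in simulation", {
  set.seed(36)
  # scaled world: n = 10000, theta_gy = 0.004 keeps the planted GWAS z ~ 6.3
  cfg <- scenario_config("pleiotropy", n_exposure = 10000,
                         n_outcome = 10000, n_snps = 100,
                         theta_gy = 0.004)
  hits <- replicate(25, {
    st <- simulate_study(cfg)
    planted <- st$truth$causal_snps[1]
    h <- harmonize(st$mqtl, st$gwas, st$panel)
    instr <- select_instrument(h$a, h$b, st$panel)
    if (is_no_instrument(instr) || nrow(instr$snps) < 3) return(NA)
    out <- remove_pleiotropic(instr)
    rem <- if (is_no_instrument(out)) character(0) else
      out$provenance$removed_pleiotropic
    c(removed = length(rem) > 0, planted = planted %in% rem)
  })
  hits <- hits[, !is.na(hits[1, ]), drop = FALSE]
  expect_gt(mean(hits["removed", ]), 0.5)
  # conditional on a removal, it is (or includes) the planted SNP
  expect_gt(mean(hits["planted", hits["removed", ] == 1]), 0.9)
})

test_that("swapping exposure and outcome twice reproduces the forward run", {
  set.seed(37)
  st <- simulate_study(small_cfg("causal", n_exposure = 5000,
                                 n_outcome = 5000, theta_ey = 0.8))
  fwd <- run_mr(st$mqtl, st$gwas, st$panel)
  rev2 <- reverse_mr(st$gwas, st$mqtl, st$panel)  # roles swapped at call
  expect_equal(rev2$b_xy, fwd$b_xy, tolerance = 1e-15)
  expect_equal(rev2$se_xy, fwd$se_xy, tolerance = 1e-15)
  expect_equal(rev2$p_xy, fwd$p_xy, tolerance = 1e-15)
  expect_identical(rev2$direction, "reverse")
  expect_identical(fwd$direction, "forward")
})

test_that("bidirectional filter applies the retention rules", {
  mk <- function(p, dir = "forward") structure(
    list(b_xy = 0.1, se_xy = 0.02, p_xy = p, direction = dir,
         exposure_id = "x", outcome_id = "y"), class = "mr_result")
  d1 <- bidirectional_filter(mk(1e-9), mk(0.4, "reverse"))
  expect_true(d1$retained)
  d2 <- bidirectional_filter(mk(1e-9), mk(0.01, "reverse"))
  expect_false(d2$retained)
  expect_identical(d2$reason, "reverse causation")
  d3 <- bidirectional_filter(mk(1e-6), mk(0.4, "reverse"))
  expect_false(d3$retained)
  expect_identical(d3$reason, "below forward threshold")
  d4 <- bidirectional_filter(mk(1e-9),
                             structure(list(reason = "none"),
                                       class = "no_instrument"))
  expect_true(d4$retained)
  expect_match(d4$reason, "untestable")
})
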