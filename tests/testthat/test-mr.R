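# MR estimators, heterogeneity, sensitivity analyses, power, FDR and the
# discovery-replication rule.

test_that("Wald ratio matches the delta-method closed form", {
  p <- make_pairs(0.5, -0.10, sx = 0.05, sy = 0.02)
  r <- mr_wald_ratio(p)
  expect_equal(r$beta_mr, -0.2)
  expect_equal(r$se_mr, 0.04)
  expect_equal(r$or_, exp(-0.2))
  expect_equal(r$or_lci, exp(-0.2 - qnorm(0.975) * 0.04))
  # null outcome
  r0 <- mr_wald_ratio(make_pairs(1, 0, sy = 0.1))
  expect_equal(r0$beta_mr, 0)
  expect_equal(r0$pval, 1)
  expect_equal(r0$se_mr, 0.1)  # unit exposure: ratio se equals outcome se
  expect_error(mr_wald_ratio(make_pairs(0, 0.1)), "beta_exp")
})

test_that("IVW with one instrument equals the Wald ratio exactly", {
  p <- make_pairs(0.31, -0.07, sx = 0.03, sy = 0.015)
  expect_equal(mr_ivw(p), mr_wald_ratio(p))
})

test_that("IVW of two identical pairs keeps beta and shrinks the fixed se", {
  p1 <- make_pairs(0.4, -0.08, sy = 0.02)
  p2 <- rbind(p1, p1); p2$snp_id <- c("s1", "s2")
  w <- mr_wald_ratio(p1)
  r <- mr_ivw(p2, "fixed")
  expect_equal(r$beta_mr, w$beta_mr)
  expect_equal(r$se_mr, w$se_mr / sqrt(2))
  expect_equal(r$q_stat, 0)
  expect_equal(r$q_pval, 1)
})

test_that("multiplicative random-effects se never falls below fixed", {
  set.seed(3)
  for (i in 1:20) {
    p <- make_pairs(runif(10, 0.1, 0.5), rnorm(10, 0, 0.1), sy = 0.03)
    fe <- mr_ivw(p, "fixed"); mre <- mr_ivw(p, "multiplicative")
    expect_equal(fe$beta_mr, mre$beta_mr)
    expect_gte(mre$se_mr, fe$se_mr)
  }
})

test_that("heterogeneity triggers the multiplicative model in auto mode", {
  bx <- rep(0.3, 6)
  by_hom <- 0.3 * -0.2 + c(-1, 1, -1, 1, -1, 1) * 1e-4
  by_het <- by_hom + c(0, 0, 0, 0, 0, 0.5)
  expect_equal(mr_ivw(make_pairs(bx, by_hom, sy = 0.02), "auto")$method, "ivw_fe")
  expect_equal(mr_ivw(make_pairs(bx, by_het, sy = 0.02), "auto")$method, "ivw_mre")
})

test_that("Cochran Q is zero for identical ratios and catches an outlier", {
  p <- make_pairs(c(0.2, 0.4, 0.3), c(0.2, 0.4, 0.3) * -0.2, sy = 0.02)
  r <- mr_ivw(p, "fixed")
  expect_equal(r$q_stat, 0, tolerance = 1e-20)
  expect_equal(r$q_pval, 1)
  p$beta_out[3] <- 0.5
  expect_lt(mr_ivw(p, "fixed")$q_pval, 0.05)
})

test_that("Q p-values are approximately uniform under a homogeneous null", {
  qp <- vapply(1:300, function(i) {
    s <- simulate_mr_instruments(sim_config(seed = 9000 + i, true_theta = -0.2))
    mr_ivw(s$discovery, "fixed")$q_pval
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(qp, "punif"))$p.value, 0.01)
})

test_that("Egger recovers slope and a planted intercept", {
  set.seed(5)
  bx <- runif(50, 0.1, 0.5)
  by <- 0.05 - 0.2 * bx + rnorm(50, 0, 0.01)
  r <- mr_egger(make_pairs(bx, by, sy = 0.01))
  expect_lt(abs(r$beta_mr - -0.2), 3 * r$se_mr)
  expect_lt(abs(r$egger_intercept - 0.05), 0.015)
  expect_lt(r$egger_intercept_p, 0.05)
  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0, 0))), "at least 3")
})

test_that("weighted median interpolates the cumulative weights", {
  # equal weights, ratios {1,2,3} -> plain median 2
  p <- make_pairs(c(1, 1, 1), c(1, 2, 3), sy = 1)
  expect_equal(mr_weighted_median(p, n_boot = 50, seed = 1)$beta_mr, 2)
  # weights {0.45, 0.45, 0.10}: cumulative midpoints 0.225/0.675/0.95 ->
  # interpolate between ratios 1 and 2 at 0.5: 1 + 0.275/0.45
  p2 <- make_pairs(c(1, 1, 1), c(1, 2, 100),
                   sy = 1 / sqrt(c(0.45, 0.45, 0.10)))
  wm <- mr_weighted_median(p2, n_boot = 50, seed = 1)$beta_mr
  expect_equal(wm, 1 + 0.275 / 0.45, tolerance = 1e-10)
  expect_gt(wm, 1); expect_lt(wm, 2)
})

test_that("weighted median resists up to half invalid instrument weight", {
  set.seed(8)
  bias_wm <- bias_ivw <- numeric(60)
  for (i in 1:60) {
    cfg <- sim_config(seed = 7000 + i, true_theta = -0.2,
                      pleiotropy_frac = 0.45, pleiotropy_shift = 0.05)
    d <- simulate_mr_instruments(cfg)$discovery
    bias_wm[i] <- mr_weighted_median(d, n_boot = 20, seed = i)$beta_mr + 0.2
    bias_ivw[i] <- mr_ivw(d, "fixed")$beta_mr + 0.2
  }
  expect_lt(abs(mean(bias_wm)), abs(mean(bias_ivw)))
})

test_that("estimators are equivariant under joint sign flips", {
  set.seed(2)
  d <- simulate_mr_instruments(sim_config(seed = 77, true_theta = -0.2))$discovery
  flip <- sample(c(-1, 1), nrow(d), replace = TRUE)
  d2 <- d
  d2$beta_exp <- d$beta_exp * flip
  d2$beta_out <- d$beta_out * flip
  expect_equal(mr_ivw(d2, "fixed")$beta_mr, mr_ivw(d, "fixed")$beta_mr)
  expect_equal(mr_egger(d2)$beta_mr, mr_egger(d)$beta_mr)
  expect_equal(mr_weighted_median(d2, n_boot = 30, seed = 3)$beta_mr,
               mr_weighted_median(d, n_boot = 30, seed = 3)$beta_mr)
})

test_that("leave-one-out reduces correctly and exposes a planted outlier", {
  p <- make_pairs(rep(0.3, 4), rep(0.3 * -0.2, 4), sy = 0.02)
  loo <- mr_leave_one_out(p)
  expect_equal(nrow(loo), 4L)
  expect_true(all(abs(loo$beta_mr - -0.2) < 1e-12))
  # L = 2 reduces to single-SNP Wald ratios
  p2 <- make_pairs(c(0.3, 0.4), c(-0.06, -0.08), sy = 0.02)
  loo2 <- mr_leave_one_out(p2)
  expect_equal(loo2$method, c("wald_ratio", "wald_ratio"))
  expect_equal(loo2$beta_mr[1], mr_wald_ratio(p2[2, ])$beta_mr)
  # planted outlier: exactly the fit dropping it moves to the truth
  p3 <- make_pairs(rep(0.3, 5), c(rep(-0.06, 4), 0.3), sy = 0.02)
  loo3 <- mr_leave_one_out(p3, mode = "fixed")
  shifts <- abs(loo3$beta_mr - -0.2)
  expect_equal(which.min(shifts), 5L)
  expect_lt(shifts[5], 1e-12)
})

test_that("Steiger orders variance explained and handles the boundary", {
  p <- make_pairs(0.5, 0.01, sx = 0.01, sy = 0.01)
  st <- mr_steiger(p, n_exp = 10000, n_out = 10000)
  expect_true(st$steiger_correct)
  expect_lt(st$steiger_p, 1e-10)
  # equal correlations: p = 1, direction flag false
  p2 <- make_pairs(0.1, 0.1, sx = 0.01, sy = 0.01)
  st2 <- mr_steiger(p2, n_exp = 5000, n_out = 5000)
  expect_false(st2$steiger_correct)
  expect_equal(st2$steiger_p, 1)
  # simulated exposure -> outcome data give the right direction
  ok <- vapply(1:50, function(i) {
    d <- simulate_mr_instruments(sim_config(seed = 300 + i))$discovery
    mr_steiger(d)$steiger_correct
  }, logical(1))
  expect_gte(mean(ok), 0.98)
})

test_that("MR-PRESSO is seed-deterministic and flags a gross outlier", {
  d <- simulate_mr_instruments(sim_config(seed = 55, true_theta = -0.2))$discovery
  a <- mr_presso(d, n_sim = 999, seed = 42)
  b <- mr_presso(d, n_sim = 999, seed = 42)
  expect_identical(a$global_p, b$global_p)
  expect_identical(a$outlier_p, b$outlier_p)
  expect_true(a$global_p >= 1 / 1000 && a$global_p <= 1)

  # plant a pleiotropic offset of 10 outcome-se on one SNP; with 50
  # instruments the Bonferroni-corrected outlier p can only clear 0.05 when
  # n_sim is comfortably above 20 * L
  d2 <- d
  d2$beta_out[7] <- d2$beta_out[7] + 10 * d2$se_out[7]
  r <- mr_presso(d2, n_sim = 1999, seed = 42)
  expect_lt(r$global_p, 0.05)
  expect_true(d2$snp_id[7] %in% r$outlier_snps)
  expect_message(expect_null(mr_presso(d[1:3, ])), "fewer than 4")
})

test_that("planted pleiotropic outliers are flagged in most replicates", {
  hits <- vapply(1:30, function(i) {
    d <- simulate_mr_instruments(sim_config(seed = 880 + i,
                                            true_theta = -0.2))$discovery
    d$beta_out[1] <- d$beta_out[1] + 10 * d$se_out[1]
    d$snp_id[1] %in% mr_presso(d, n_sim = 1999, seed = i)$outlier_snps
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("binary-outcome power is monotone and correct at the null", {
  expect_equal(mr_power_binary(0.1, 1, 24510, 0.33), 0.05, tolerance = 1e-12)
  r2s <- seq(0.02, 0.4, by = 0.02)
  pw <- vapply(r2s, mr_power_binary, numeric(1), or_alt = 0.85, n = 24510,
               case_fraction = 0.33)
  expect_true(all(diff(pw) >= 0))
  ns <- seq(2000, 50000, by = 2000)
  pw_n <- vapply(ns, function(n) mr_power_binary(0.1, 0.85, n, 0.33),
                 numeric(1))
  expect_true(all(diff(pw_n) >= 0))
  ors <- exp(seq(0.01, 0.5, by = 0.01))
  pw_or <- vapply(ors, function(o) mr_power_binary(0.1, o, 24510, 0.33),
                  numeric(1))
  expect_true(all(diff(pw_or) >= 0))
})

test_that("bh_fdr matches the worked example and the brute-force reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(6)
  for (i in 1:30) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bf_bh(p))
    expect_true(all(adj >= p))
    # adjustment preserves the p-value ordering
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("discover_replicate applies FDR, replication and direction rules", {
  disc <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                     beta_mr = c(-0.2, -0.2, -0.2, 0.3),
                     pval = c(1e-4, 1e-4, 2e-3, 1e-4),
                     fdr = c(0.03, 0.03, 0.06, 0.03))
  repl <- data.frame(protein_id = c("p1", "p2", "p3"),
                     beta_mr = c(-0.15, 0.10, -0.2),
                     pval = c(0.01, 0.01, 0.001))
  out <- discover_replicate(disc, repl)
  expect_equal(as.character(out), "p1")       # p2 flips direction, p3 fails FDR
  expect_equal(attr(out, "untestable"), "p4") # p4 absent from replication
})
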