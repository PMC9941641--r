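# Instrument filters, cis/trans assignment, sentinel selection, clumping,
# conditional analysis and group construction.

make_pqtl <- function(ids, pval, chrom = "1", pos = seq_along(ids) * 1e5,
                      f_stat = 100, n = 10000,
                      consequence = "intron_variant", protein_id = "p1") {
  z <- qnorm(pval / 2, lower.tail = FALSE)
  se <- 0.02
  data.frame(
    snp_id = ids, chrom = chrom, pos = pos, effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = z * se, se = se, pval = pval,
    n = n, n_cases = NA_real_, protein_id = protein_id,
    consequence = consequence, f_stat = f_stat, stringsAsFactors = FALSE
  )
}

test_that("filter_instruments applies each exclusion rule", {
  rec <- make_pqtl(
    ids = c("sig", "weak", "mhc", "pleio", "coding", "nonsig"),
    pval = c(1e-10, 1e-9, 1e-20, 1e-12, 1e-12, 1e-6),
    chrom = c("1", "1", "6", "1", "1", "1"),
    pos = c(1e6, 2e6, 30000000, 4e6, 5e6, 6e6),
    f_stat = c(200, 9.9, 200, 200, 200, 200),
    consequence = c("intron_variant", "intron_variant", "intron_variant",
                    "intron_variant", "missense_variant", "intron_variant")
  )
  counts <- c(sig = 1L, weak = 1L, mhc = 1L, pleio = 6L, coding = 1L,
              nonsig = 1L)
  out <- filter_instruments(rec, counts)
  expect_equal(out$snp_id, "sig")
  rem <- attr(out, "removed")
  expect_equal(unname(rem[c("not_significant", "weak_instrument", "mhc",
                            "pleiotropic", "coding")]),
               c(1L, 1L, 1L, 1L, 1L))
})

test_that("MHC boundaries are inclusive and chromosome-specific", {
  rec <- make_pqtl(c("a", "b", "c"), 1e-12, chrom = c("6", "6", "5"),
                   pos = c(27477797, 34448355, 30000000))
  out <- filter_instruments(rec)
  expect_setequal(out$snp_id, c("b", "c"))
})

test_that("filter_instruments only removes rows, never edits them", {
  set.seed(4)
  rec <- make_pqtl(sprintf("s%d", 1:30), runif(30, 1e-30, 1e-3),
                   pos = sample(1:1e8, 30), f_stat = runif(30, 5, 500))
  out <- filter_instruments(rec)
  expect_true(all(out$snp_id %in% rec$snp_id))
  expect_identical(out, rec[rec$snp_id %in% out$snp_id, ],
                   ignore_attr = TRUE)
})

test_that("assign_cis_trans uses an inclusive window on the gene chromosome", {
  rec <- make_pqtl(c("near", "boundary", "far", "other_chr"), 1e-10,
                   chrom = c("2", "2", "2", "3"),
                   pos = c(10.5e6, 11e6, 12e6, 10e6))
  out <- assign_cis_trans(rec, gene_chrom = "2", gene_tss = 10e6,
                          window = 1e6)
  expect_equal(out$is_cis, c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(out2 <- assign_cis_trans(rec, NA, NA), "trans")
  expect_false(any(out2$is_cis))
})

test_that("select_sentinel keeps one SNP per region with tie-breaks", {
  # three SNPs within 100 kb: only the smallest p survives
  rec <- make_pqtl(c("a", "b", "c"), c(1e-12, 1e-10, 1e-9),
                   pos = c(1e6, 1.05e6, 1.1e6))
  expect_equal(select_sentinel(rec)$snp_id, "a")
  # two SNPs 5 Mb apart are sentinels of separate regions
  rec2 <- make_pqtl(c("a", "b"), c(1e-12, 1e-10), pos = c(1e6, 6e6))
  expect_setequal(select_sentinel(rec2)$snp_id, c("a", "b"))
  # equal p: larger F wins
  rec3 <- make_pqtl(c("a", "b"), c(1e-10, 1e-10), pos = c(1e6, 1.1e6),
                    f_stat = c(40, 50))
  expect_equal(select_sentinel(rec3)$snp_id, "b")
  expect_equal(nrow(select_sentinel(rec3[integer(0), ])), 0L)
})

test_that("ld_clump follows the greedy rule and prunes at the boundary", {
  ids <- c("A", "B", "C")
  r <- diag(3); dimnames(r) <- list(ids, ids)
  r["A", "B"] <- r["B", "A"] <- sqrt(0.5)
  r["A", "C"] <- r["C", "A"] <- sqrt(0.05)
  r["B", "C"] <- r["C", "B"] <- sqrt(0.5)
  rec <- make_pqtl(ids, c(1e-10, 1e-8, 1e-9))
  out <- ld_clump(rec, r, 0.1)
  expect_setequal(out$snp_id, c("A", "C"))

  # r^2 exactly at the threshold is pruned
  r2 <- diag(2); dimnames(r2) <- list(c("A", "B"), c("A", "B"))
  r2["A", "B"] <- r2["B", "A"] <- sqrt(0.1)
  rec2 <- make_pqtl(c("A", "B"), c(1e-10, 1e-9), pos = c(1e6, 1.2e6))
  expect_equal(ld_clump(rec2, r2, 0.1)$snp_id, "A")

  # independent SNPs are all retained
  r3 <- diag(3); dimnames(r3) <- list(ids, ids)
  expect_equal(nrow(ld_clump(rec, r3, 0.1)), 3L)

  expect_error(ld_clump(rec, r3[1:2, 1:2], 0.1), "missing from LD")
})

test_that("ld_clump agrees with a brute-force reference on random instances", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(2:12, 1)
    ids <- sprintf("v%02d", 1:m)
    R <- make_ld(m, "ar1", runif(1, 0, 0.98), ids = ids)
    pv <- 10^runif(m, -20, -8)
    rec <- make_pqtl(ids, pv, pos = 1:m * 1e4)
    thr <- runif(1, 0.05, 0.6)
    got <- ld_clump(rec, R, thr)$snp_id
    want <- bf_clump(pv, ids, R, thr)
    expect_equal(sort(got), sort(want))
    # output is pairwise below threshold
    if (length(got) > 1) {
      r2 <- (R[got, got])^2
      expect_true(all(r2[upper.tri(r2)] < thr))
    }
  }
})

test_that("conditional_select recovers orthogonal signals exactly", {
  n <- 40000
  z <- c(8, 7)
  se <- 0.02
  rec <- make_pqtl(c("a", "b"), 2 * pnorm(-z), pos = c(1e6, 2e6), n = n)
  rec$beta <- z * se; rec$se <- se
  R <- diag(2); dimnames(R) <- list(c("a", "b"), c("a", "b"))
  out <- conditional_select(rec, R)
  expect_setequal(out$snp_id, c("a", "b"))
  # with r = 0 the conditional (standardized) betas equal the marginals
  expect_equal(out$beta_cond, (rec$beta / rec$se)[match(out$snp_id, rec$snp_id)] / sqrt(n),
               tolerance = 1e-12)
})

test_that("conditional_select skips collinear SNPs and LD shadows", {
  n <- 40000; se <- 0.02
  # SNP b's marginal signal is exactly r times the sentinel's: conditional
  # beta is 0 by the two-SNP closed form, so b is not selected
  r <- 0.5
  z1 <- 20
  rec <- make_pqtl(c("a", "b"), 2 * pnorm(-c(z1, r * z1)),
                   pos = c(1e6, 1.2e6), n = n)
  rec$beta <- c(z1, r * z1) * se; rec$se <- se
  R <- matrix(c(1, r, r, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  out <- conditional_select(rec, R)
  expect_equal(out$snp_id, "a")

  # nearly perfect LD is skipped as collinear even with a huge marginal z
  r <- 0.99
  rec2 <- make_pqtl(c("a", "b"), 2 * pnorm(-c(30, 29)),
                    pos = c(1e6, 1.1e6), n = n)
  rec2$beta <- c(30, 29) * se; rec2$se <- se
  R2 <- matrix(c(1, r, r, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(conditional_select(rec2, R2)$snp_id, "a")
})

test_that("for orthogonal LD conditional_select returns the marginally significant set", {
  set.seed(11)
  m <- 8; n <- 30000
  z <- runif(m, 3, 12)
  se <- 0.02
  ids <- sprintf("s%d", 1:m)
  rec <- make_pqtl(ids, 2 * pnorm(-z), pos = 1:m * 2e6, n = n)
  rec$beta <- z * se; rec$se <- se
  R <- diag(m); dimnames(R) <- list(ids, ids)
  out <- conditional_select(rec, R, p_threshold = 5e-8)
  expect_setequal(out$snp_id, ids[2 * pnorm(-z) < 5e-8])
})

test_that("build_groups nests correctly on a simulated protein", {
  cfg <- sim_config(seed = 21, n_snps_per_region = 60)
  b <- simulate_proteome(cfg, n_proteins = 12, n_causal = 2, n_confounded = 0)
  pid <- b$truth$protein_id[b$truth$architecture == "cis_trans"][1]
  skip_if(is.na(pid))
  ex <- b$exposure[[pid]]
  sig <- ex[ex$pval < 5e-8, ]
  sig$protein_id <- pid
  sig$consequence <- "intron_variant"
  sig$f_stat <- f_statistic(sig$beta, sig$se)
  i <- match(pid, b$proteins$protein_id)
  sig <- assign_cis_trans(sig, b$proteins$gene_chrom[i], b$proteins$gene_tss[i])
  R <- protmr:::assemble_ld(sig$snp_id, sig$region_id, b$ld)
  g <- build_groups(sig, R)

  expect_true(all(g$A$snp_id %in% g$B$snp_id))
  expect_true(all(g$B$snp_id %in% g$D$snp_id))
  expect_true(all(g$C$snp_id %in% g$D$snp_id))
  expect_length(intersect(g$B$snp_id, g$C$snp_id), 0)
  expect_true(all(g$A$is_cis))
  expect_false(any(g$C$is_cis))
  for (gr in c("B", "C", "D")) {
    ids <- g[[gr]]$snp_id
    if (length(ids) > 1) {
      r2 <- R[ids, ids]^2
      expect_true(all(r2[upper.tri(r2)] < 0.1))
    }
  }
  # degenerate protein: single cis region, no trans
  pid2 <- b$truth$protein_id[b$truth$architecture == "cis"][1]
  ex2 <- b$exposure[[pid2]]
  sig2 <- ex2[ex2$pval < 5e-8, ]
  sig2$protein_id <- pid2; sig2$consequence <- "intron_variant"
  sig2$f_stat <- f_statistic(sig2$beta, sig2$se)
  j <- match(pid2, b$proteins$protein_id)
  sig2 <- assign_cis_trans(sig2, b$proteins$gene_chrom[j], b$proteins$gene_tss[j])
  R2 <- protmr:::assemble_ld(sig2$snp_id, sig2$region_id, b$ld)
  g2 <- build_groups(sig2, R2)
  expect_gte(nrow(g2$A), 1L)
  expect_equal(nrow(g2$C), 0L)
  expect_true(all(g2$A$snp_id %in% g2$B$snp_id))
  expect_true(all(g2$A$snp_id %in% g2$D$snp_id))
})

test_that("f_stat / r2 relationship holds", {
  f <- f_statistic(0.1, 0.02)
  expect_equal(f, 25)
  expect_equal(snp_r2(f, 1000), 25 / (25 + 998))
})
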