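# Independent brute-force references and small fixture builders used across
# the suite. The oracles deliberately avoid the package's own code paths.

# Step-up BH adjustment written out directly from the definition:
# adj for the i-th smallest p is min over j >= i of p_(j) * m / j, capped.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sp <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(sp[i:m] * m / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Naive clumping: repeatedly scan the full list for the best remaining SNP
# and mark correlated ones, without vector tricks.
bf_clump <- function(pvals, ids, r, r2_threshold) {
  status <- rep("alive", length(pvals))
  keep <- character(0)
  repeat {
    alive <- which(status == "alive")
    if (!length(alive)) break
    o <- alive[order(pvals[alive], ids[alive])][1]
    keep <- c(keep, ids[o])
    status[o] <- "kept"
    for (j in which(status == "alive"))
      if (r[o, j]^2 >= r2_threshold) status[j] <- "pruned"
  }
  keep
}

# Direct-summation coloc posteriors (safe only for small regions / modest z).
bf_coloc_pp <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  s1 <- sum(exp(l1)); s2 <- sum(exp(l2)); s12 <- sum(exp(l1 + l2))
  cross <- 0
  for (i in seq_along(l1))
    for (j in seq_along(l2))
      if (i != j) cross <- cross + exp(l1[i] + l2[j])
  w <- c(1, p1 * s1, p2 * s2, p1 * p2 * cross, p12 * s12)
  w / sum(w)
}

# Quick harmonized-pair fixture from raw vectors.
make_pairs <- function(bx, by, sx = rep(0.01, length(bx)),
                       sy = rep(0.01, length(bx))) {
  L <- length(bx)
  data.frame(
    snp_id = sprintf("s%02d", seq_len(L)), chrom = "1", pos = seq_len(L) * 1e5,
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = sx, pval_exp = 2 * pnorm(-abs(bx / sx)),
    eaf_exp = 0.3,
    beta_out = by, se_out = sy, pval_out = 2 * pnorm(-abs(by / sy)),
    eaf_out = 0.3, n_exp = 10000, n_out = 20000,
    palindromic = FALSE, action = "none", stringsAsFactors = FALSE
  )
}

# Canonical summary-statistic rows with consistent z/p.
make_sumstats <- function(ids, beta, se, chrom = "1",
                          pos = seq_along(ids) * 1e5,
                          ea = "A", oa = "G", eaf = 0.3, n = 10000) {
  data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)),
    n = n, n_cases = NA_real_, stringsAsFactors = FALSE
  )
}
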