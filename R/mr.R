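# Two-sample MR estimators and sensitivity analyses on harmonized
# exposure-outcome pairs (the data frame produced by harmonize()).
#
# Causal estimates are on the log-OR (outcome) per SD (exposure) scale;
# odds ratios and 95% CIs are exp-transformed.

#' @noRd
new_mr_result <- function(method, n_snps, beta, se, pval = NULL,
                          q_stat = NA_real_, q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_p = NA_real_) {
  z975 <- stats::qnorm(0.975)
  pval <- pval %||% z_to_p(beta / se)
  data.frame(
    method = method, n_snps = as.integer(n_snps),
    beta_mr = beta, se_mr = se, pval = pval,
    or_ = exp(beta), or_lci = exp(beta - z975 * se),
    or_uci = exp(beta + z975 * se),
    q_stat = q_stat, q_pval = q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_p = egger_intercept_p,
    stringsAsFactors = FALSE
  )
}

#' Wald ratio estimate from a single instrument
#'
#' beta = beta_out/beta_exp with first-order (delta-method) standard error
#' se_out/|beta_exp|; p from the normal z statistic.
#'
#' @param pair One-row harmonized pair data frame.
#' @return One-row MR result data frame.
#' @export
mr_wald_ratio <- function(pair) {
  stopifnot(nrow(pair) == 1L)
  if (pair$beta_exp == 0) stop("Wald ratio undefined: beta_exp = 0")
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  new_mr_result("wald_ratio", 1L, beta, se)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum_i w_i (theta_i - beta)^2 with theta_i the per-SNP Wald ratios and
#' w_i = (beta_exp_i/se_out_i)^2; p from chi-square with L-1 df.
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @param beta_mr Pooled estimate the per-SNP ratios are compared against.
#' @return List with `q_stat` and `q_pval`.
#' @export
mr_cochran_q <- function(pairs, beta_mr) {
  theta <- pairs$beta_out / pairs$beta_exp
  w <- (pairs$beta_exp / pairs$se_out)^2
  q <- sum(w * (theta - beta_mr)^2)
  list(q_stat = q,
       q_pval = stats::pchisq(q, df = nrow(pairs) - 1L, lower.tail = FALSE))
}

#' Inverse-variance-weighted MR estimate
#'
#' beta = sum(bx by/sy^2)/sum(bx^2/sy^2). The fixed-effect standard error is
#' sqrt(1/sum(bx^2/sy^2)); the multiplicative-random-effects standard error
#' inflates it by max(1, sqrt(Q/(L-1))). `mode = "auto"` reports the
#' multiplicative model when Cochran's Q p < `het_alpha`, the fixed-effect
#' model otherwise. A single pair delegates to [mr_wald_ratio()].
#'
#' @param pairs Harmonized pairs.
#' @param mode `"auto"`, `"fixed"` or `"multiplicative"`.
#' @param het_alpha Heterogeneity trigger for auto mode (default 0.05).
#' @return One-row MR result data frame (method `ivw_fe` or `ivw_mre`).
#' @export
mr_ivw <- function(pairs, mode = c("auto", "fixed", "multiplicative"),
                   het_alpha = 0.05) {
  mode <- match.arg(mode)
  L <- nrow(pairs)
  if (L < 1L) stop("no instruments")
  if (L == 1L) return(mr_wald_ratio(pairs))
  w <- pairs$beta_exp^2 / pairs$se_out^2
  beta <- sum(pairs$beta_exp * pairs$beta_out / pairs$se_out^2) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  q <- mr_cochran_q(pairs, beta)
  se_mre <- se_fe * max(1, sqrt(q$q_stat / (L - 1L)))
  use_mre <- switch(mode, fixed = FALSE, multiplicative = TRUE,
                    auto = q$q_pval < het_alpha)
  se <- if (use_mre) se_mre else se_fe
  new_mr_result(if (use_mre) "ivw_mre" else "ivw_fe", L, beta, se,
                q_stat = q$q_stat, q_pval = q$q_pval)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept
#' (weights 1/se_out^2), after orienting all exposure effects positive. The
#' slope is the causal estimate; a nonzero intercept indicates directional
#' pleiotropy. Standard errors follow the usual Egger convention of not
#' allowing underdispersion (residual sd floored at 1); p-values use the
#' t distribution with L-2 df.
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @return One-row MR result data frame with intercept diagnostics.
#' @export
mr_egger <- function(pairs) {
  L <- nrow(pairs)
  if (L < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  bx <- pairs$beta_exp * flip
  by <- pairs$beta_out * flip
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  co <- summary(fit)$coefficients
  scale_ <- min(1, summary(fit)$sigma)
  slope <- co["bx", "Estimate"]
  slope_se <- co["bx", "Std. Error"] / scale_
  inter <- co["(Intercept)", "Estimate"]
  inter_se <- co["(Intercept)", "Std. Error"] / scale_
  pt2 <- function(t) 2 * stats::pt(-abs(t), df = L - 2L)
  new_mr_result("egger", L, slope, slope_se, pval = pt2(slope / slope_se),
                egger_intercept = inter,
                egger_intercept_p = pt2(inter / inter_se))
}

#' Weighted-median MR estimate
#'
#' Orders per-SNP Wald ratios and takes the inverse-variance-weighted median
#' by linear interpolation of the cumulative weight midpoints at 0.5;
#' consistent when up to half the instrument weight is invalid. The standard
#' error comes from a parametric bootstrap (exposure and outcome effects
#' redrawn from their sampling normals).
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return One-row MR result data frame.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000L, seed = 1L) {
  L <- nrow(pairs)
  if (L < 3L) stop("weighted median requires at least 3 instruments")
  wm <- function(bx, by, sy) {
    theta <- by / bx
    w <- bx^2 / sy^2
    ord <- order(theta)
    theta <- theta[ord]
    w <- w[ord] / sum(w)
    s <- cumsum(w) - w / 2
    stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
  }
  est <- wm(pairs$beta_exp, pairs$beta_out, pairs$se_out)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bx_star <- matrix(stats::rnorm(n_boot * L, pairs$beta_exp, pairs$se_exp),
                    n_boot, L, byrow = TRUE)
  by_star <- matrix(stats::rnorm(n_boot * L, pairs$beta_out, pairs$se_out),
                    n_boot, L, byrow = TRUE)
  boots <- vapply(seq_len(n_boot), function(i)
    wm(bx_star[i, ], by_star[i, ], pairs$se_out), numeric(1))
  new_mr_result("weighted_median", L, est, stats::sd(boots))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-fits the IVW estimate excluding each instrument in turn (a single
#' remaining instrument reduces to its Wald ratio).
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @param mode Passed to [mr_ivw()].
#' @return Data frame with one row per dropped SNP: snp_id, method, beta_mr,
#'   se_mr, pval.
#' @export
mr_leave_one_out <- function(pairs, mode = "auto") {
  stopifnot(nrow(pairs) >= 2L)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- mr_ivw(pairs[-i, , drop = FALSE], mode = mode)
    cbind(snp_id = pairs$snp_id[i],
          r[, c("method", "n_snps", "beta_mr", "se_mr", "pval")])
  })
  do.call(rbind, out)
}

#' MR Steiger directionality test
#'
#' Compares the variance each instrument set explains in the exposure versus
#' the outcome, using the large-sample approximation r2 = z^2/(z^2 + n) per
#' SNP (summed over instruments). The causal direction is supported when
#' r2_exposure > r2_outcome; the p-value compares the implied correlations
#' via Fisher's z transform.
#'
#' @param pairs Harmonized pairs.
#' @param n_exp,n_out Sample sizes (defaults taken from the pairs).
#' @return List with `r2_exp`, `r2_out`, `steiger_correct`, `steiger_p`.
#' @export
mr_steiger <- function(pairs, n_exp = NULL, n_out = NULL) {
  n_exp <- n_exp %||% pairs$n_exp[1]
  n_out <- n_out %||% pairs$n_out[1]
  zx <- pairs$beta_exp / pairs$se_exp
  zy <- pairs$beta_out / pairs$se_out
  r2_exp <- sum(zx^2 / (zx^2 + n_exp))
  r2_out <- sum(zy^2 / (zy^2 + n_out))
  r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
  r_out <- sqrt(min(r2_out, 1 - 1e-12))
  if (isTRUE(all.equal(r_exp, r_out))) {
    return(list(r2_exp = r2_exp, r2_out = r2_out,
                steiger_correct = FALSE, steiger_p = 1))
  }
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(r2_exp = r2_exp, r2_out = r2_out,
       steiger_correct = r2_exp > r2_out, steiger_p = z_to_p(z))
}

#' MR-PRESSO global and outlier test
#'
#' Parametric-simulation test for horizontal pleiotropy. The observed
#' statistic is the weighted residual sum of squares
#' RSS = sum_i (by_i - bhat_(-i) bx_i)^2 / se_out_i^2, where bhat_(-i) is
#' the leave-one-out fixed-effect IVW estimate. The null distribution is
#' obtained by redrawing bx_i ~ N(bx_i, se_exp_i^2) and
#' by_i ~ N(bhat_(-i) bx_i, se_out_i^2) `n_sim` times and recomputing the
#' statistic on each draw; the global p is (1 + #{RSS* >= RSS})/(n_sim + 1).
#' Per-SNP outlier p-values compare each observed weighted residual with its
#' simulated distribution and are Bonferroni-corrected; SNPs below
#' `outlier_alpha` are flagged for removal before the final MR fit.
#'
#' @param pairs Harmonized pairs (>= 4 rows; fewer returns NULL with a
#'   message, the test being too weakly identified to run).
#' @param n_sim Simulation replicates (default 1000).
#' @param seed RNG seed (recorded in the result).
#' @param outlier_alpha Outlier flagging threshold on the Bonferroni-adjusted
#'   per-SNP p (default 0.05).
#' @return List with `global_rss_obs`, `global_p`, `outlier_p` (adjusted,
#'   named by snp_id), `outlier_snps`, `n_sim`, `seed`; or NULL when fewer
#'   than 4 instruments are supplied.
#' @export
mr_presso <- function(pairs, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05) {
  L <- nrow(pairs)
  if (L < 4L) {
    message("MR-PRESSO skipped: fewer than 4 instruments")
    return(NULL)
  }
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out

  loo_ivw <- function(bx, by, sy) {
    num <- bx * by / sy^2; den <- bx^2 / sy^2
    (sum(num) - num) / (sum(den) - den)
  }
  b_loo <- loo_ivw(bx, by, sy)
  res_obs <- (by - b_loo * bx)^2 / sy^2
  rss_obs <- sum(res_obs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bx_star <- matrix(stats::rnorm(n_sim * L, rep(bx, each = n_sim),
                                 rep(sx, each = n_sim)), n_sim, L)
  by_star <- matrix(stats::rnorm(n_sim * L, rep(b_loo * bx, each = n_sim),
                                 rep(sy, each = n_sim)), n_sim, L)
  sy_m <- matrix(sy, n_sim, L, byrow = TRUE)

  num <- bx_star * by_star / sy_m^2
  den <- bx_star^2 / sy_m^2
  b_loo_star <- (rowSums(num) - num) / (rowSums(den) - den)
  res_star <- (by_star - b_loo_star * bx_star)^2 / sy_m^2
  rss_star <- rowSums(res_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + colSums(res_star >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * L)
  names(p_adj) <- pairs$snp_id
  list(global_rss_obs = rss_obs, global_p = global_p, outlier_p = p_adj,
       outlier_snps = pairs$snp_id[p_adj < outlier_alpha],
       n_sim = as.integer(n_sim), seed = as.integer(seed))
}

#' Statistical power of MR with a binary outcome
#'
#' Non-centrality-parameter power calculation for a two-sided Wald test of
#' the causal log-OR, given the variance in the exposure explained by the
#' instruments. The causal OR is first converted to an approximate
#' unit-change effect on disease liability via
#' b = K (OR/(1 + K(OR - 1)) - 1) with K the case fraction; with sampling
#' variance v = (K(1-K) - b^2)/N the non-centrality parameter is
#' b^2 r2 / v and power = P(chi^2_1(ncp) > chi^2 critical value).
#'
#' @param r2 Variance in the exposure explained by the instrument set.
#' @param or_alt Causal odds ratio under the alternative.
#' @param n Total outcome sample size.
#' @param case_fraction Proportion of cases K.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[alpha, 1]` (equals `alpha` at OR = 1).
#' @export
mr_power_binary <- function(r2, or_alt, n, case_fraction, alpha = 0.05) {
  stopifnot(r2 > 0, r2 < 1, or_alt > 0,
            case_fraction > 0, case_fraction < 1)
  K <- case_fraction
  b <- K * (or_alt / (1 + K * (or_alt - 1)) - 1)
  v <- (K * (1 - K) - b^2) / n
  ncp <- b^2 * r2 / v
  stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (p * m / rank with the
#' cumulative-minimum monotonicity correction, capped at 1).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Discovery-replication decision rule
#'
#' A protein is reported when its discovery FDR is below `fdr_threshold`,
#' its replication p-value is below `rep_alpha`, and the effect direction is
#' concordant across the two cohorts. Proteins absent from the replication
#' results are recorded as untestable, never passed.
#'
#' @param discovery,replication Data frames with columns `protein_id`,
#'   `beta_mr`, `pval` and (discovery only) `fdr`. Rows are matched by
#'   `protein_id` within one instrument group.
#' @param fdr_threshold Discovery FDR threshold (default 0.05).
#' @param rep_alpha Replication nominal alpha (default 0.05).
#' @return Character vector of passing protein ids, with attribute
#'   `untestable` listing discovery-significant proteins missing from the
#'   replication set.
#' @export
discover_replicate <- function(discovery, replication, fdr_threshold = 0.05,
                               rep_alpha = 0.05) {
  sig <- discovery[discovery$fdr < fdr_threshold, , drop = FALSE]
  idx <- match(sig$protein_id, replication$protein_id)
  untestable <- sig$protein_id[is.na(idx)]
  sig <- sig[!is.na(idx), , drop = FALSE]
  rep_ <- replication[idx[!is.na(idx)], , drop = FALSE]
  pass <- rep_$pval < rep_alpha &
    sign(sig$beta_mr) == sign(rep_$beta_mr) & sign(sig$beta_mr) != 0
  structure(sig$protein_id[pass], untestable = untestable)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
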