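# Single-causal-variant colocalization from summary statistics via
# Wakefield approximate Bayes factors. Five hypotheses for a region:
#   H0 no causal variant for either trait, H1/H2 a causal variant for one
#   trait only, H3 distinct causal variants, H4 a shared causal variant.
# A posterior PP.H4 > 0.8 is read as a shared variant; PP.H3 > 0.8 marks an
# MR signal confounded by LD between two distinct variants.

#' Default colocalization priors
#'
#' Per-SNP prior probabilities that a SNP is causal for trait 1 only (p1),
#' trait 2 only (p2), or both (p12).
#'
#' @return Named list `p1`, `p2`, `p12`.
#' @export
coloc_priors <- function() list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)

#' Wakefield approximate Bayes factor (log scale)
#'
#' With z = beta/se, V = se^2, W = prior_sd^2 and shrinkage r = W/(V + W),
#' the log Bayes factor in favour of association is
#' 0.5 * (log(1 - r) + r z^2). Vectorized over SNPs.
#'
#' @param beta,se Effect estimate and standard error (se > 0).
#' @param prior_sd Prior standard deviation of true effects (0.15 is
#'   standard for quantitative traits, 0.2 on the log-OR scale for
#'   case-control traits).
#' @return Log approximate Bayes factor(s).
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  stopifnot(all(se > 0), prior_sd >= 0)
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' @noRd
beta_se_from_p <- function(pval, maf, n, trait_type, case_fraction = NA) {
  z <- stats::qnorm(pval / 2, lower.tail = FALSE)
  v <- if (trait_type == "case_control") {
    1 / (2 * n * maf * (1 - maf) * case_fraction * (1 - case_fraction))
  } else {
    1 / (2 * n * maf * (1 - maf))
  }
  list(beta = z * sqrt(v), se = sqrt(v))
}

#' @noRd
trait_labf <- function(trait, trait_type, prior_sd, case_fraction = NA) {
  if (!is.null(trait$beta) && !is.null(trait$se)) {
    wakefield_abf(trait$beta, trait$se, prior_sd)
  } else {
    maf <- pmin(trait$eaf, 1 - trait$eaf)
    bs <- beta_se_from_p(trait$pval, maf, trait$n, trait_type, case_fraction)
    wakefield_abf(bs$beta, bs$se, prior_sd)
  }
}

#' Colocalization of two traits in one region
#'
#' Computes per-SNP log approximate Bayes factors for both traits,
#' accumulates the evidence for the five hypotheses by log-sum-exp, and
#' returns posterior probabilities (softmax against the priors). The SNP
#' lists of both traits must already be aligned one-to-one (see
#' [extract_region()]).
#'
#' @param trait1,trait2 Data frames over the same SNPs with `beta` and `se`
#'   columns (preferred) or `pval`, `eaf`, `n` (lower-fidelity route, noted
#'   in the result).
#' @param trait_types Character length-2: `"quantitative"` or
#'   `"case_control"` per trait.
#' @param case_fraction Numeric length-2; required where a trait is
#'   case-control and only p/MAF/n are supplied.
#' @param priors List as from [coloc_priors()].
#' @param prior_sd Length-2 effect-size prior sds; defaults to 0.15 for
#'   quantitative and 0.2 for case-control traits.
#' @param pp_threshold Decision threshold on the posteriors (default 0.8).
#' @return A `coloc_result` list: `pp` (named PP.H0..PP.H4), `n_snps`,
#'   `decision` (`"none"`, `"shared"`, `"distinct"`, `"trait1_only"`,
#'   `"trait2_only"` or `"underpowered"`), and `single_snp` flag (H3 is
#'   undefined with one SNP and gets posterior 0).
#' @export
coloc_region <- function(trait1, trait2,
                         trait_types = c("quantitative", "quantitative"),
                         case_fraction = c(NA, NA),
                         priors = coloc_priors(), prior_sd = NULL,
                         pp_threshold = 0.8) {
  n1 <- if (is.null(trait1$beta)) length(trait1$pval) else length(trait1$beta)
  n2 <- if (is.null(trait2$beta)) length(trait2$pval) else length(trait2$beta)
  if (n1 != n2) stop("traits must cover the identical SNP list")
  n_snps <- n1
  if (n_snps == 0L) {
    return(structure(list(pp = setNames(rep(NA_real_, 5),
                                        paste0("PP.H", 0:4)),
                          n_snps = 0L, decision = "underpowered",
                          single_snp = FALSE), class = "coloc_result"))
  }
  stopifnot(priors$p1 > 0, priors$p2 > 0, priors$p12 > 0,
            priors$p1 + priors$p2 + priors$p12 < 1)
  if (is.null(prior_sd))
    prior_sd <- ifelse(trait_types == "case_control", 0.2, 0.15)

  l1 <- trait_labf(trait1, trait_types[1], prior_sd[1], case_fraction[1])
  l2 <- trait_labf(trait2, trait_types[2], prior_sd[2], case_fraction[2])

  lse1 <- logsumexp(l1)
  lse2 <- logsumexp(l2)
  lse12 <- logsumexp(l1 + l2)

  lh0 <- 0
  lh1 <- log(priors$p1) + lse1
  lh2 <- log(priors$p2) + lse2
  lh4 <- log(priors$p12) + lse12
  single_snp <- n_snps == 1L
  if (single_snp) {
    lh3 <- -Inf
  } else {
    # sum_{i != j} exp(l1_i + l2_j), computed in shifted space with the
    # diagonal excluded term by term (the product-minus-diagonal shortcut
    # loses precision when a single SNP dominates both traits)
    e1 <- exp(l1 - max(l1))
    e2 <- exp(l2 - max(l2))
    cross <- sum(vapply(seq_along(e1),
                        function(i) e1[i] * sum(e2[-i]), numeric(1)))
    lh3 <- log(priors$p1) + log(priors$p2) +
      max(l1) + max(l2) + log(cross)
  }

  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.H", 0:4)

  decision <- if (pp["PP.H4"] > pp_threshold) "shared"
  else if (pp["PP.H3"] > pp_threshold) "distinct"
  else if (pp["PP.H1"] > pp_threshold) "trait1_only"
  else if (pp["PP.H2"] > pp_threshold) "trait2_only"
  else if (pp["PP.H0"] > pp_threshold) "none"
  else "underpowered"

  structure(list(pp = pp, n_snps = as.integer(n_snps), decision = decision,
                 single_snp = single_snp, labf1 = l1, labf2 = l2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_snps, "SNPs — decision:", x$decision, "\n")
  print(signif(x$pp, 3))
  invisible(x)
}

#' Extract and align a colocalization region around a sentinel SNP
#'
#' Slices both traits to SNPs within `half_width` base pairs of the sentinel
#' position on its chromosome, intersects the SNP lists and harmonizes the
#' second trait's effects to the first trait's effect alleles (palindromic
#' SNPs are kept: only aligned effect magnitudes enter the Bayes factors).
#'
#' @param trait1,trait2 Summary-statistic data frames (canonical columns).
#' @param sentinel snp_id of the sentinel (must be present in at least one
#'   trait).
#' @param half_width Region half-width in base pairs; the default 1e6 gives
#'   a 2 Mb window.
#' @return List with aligned `trait1`, `trait2` data frames (same SNP order)
#'   and `region` (chrom/start/end); 0-row traits when the intersection is
#'   empty.
#' @export
extract_region <- function(trait1, trait2, sentinel, half_width = 1e6) {
  src <- if (sentinel %in% trait1$snp_id) trait1 else trait2
  if (!sentinel %in% src$snp_id)
    stop("sentinel ", sentinel, " absent from both traits")
  at <- src[src$snp_id == sentinel, ][1, ]
  in_win <- function(tr) tr$chrom == at$chrom &
    abs(tr$pos - at$pos) <= half_width
  t1 <- trait1[in_win(trait1), , drop = FALSE]
  t2 <- trait2[in_win(trait2), , drop = FALSE]
  pairs <- if (nrow(t1) && nrow(t2))
    harmonize(t1, t2, drop_palindromic = FALSE)
  else NULL
  if (is.null(pairs) || nrow(pairs) == 0L) {
    empty <- t1[integer(0), , drop = FALSE]
    return(list(trait1 = empty, trait2 = empty,
                region = list(chrom = at$chrom,
                              start = max(1, at$pos - half_width),
                              end = at$pos + half_width)))
  }
  mk <- function(beta, se, pval, eaf, n) data.frame(
    snp_id = pairs$snp_id, chrom = pairs$chrom, pos = pairs$pos,
    beta = beta, se = se, pval = pval, eaf = eaf, n = n,
    stringsAsFactors = FALSE)
  list(trait1 = mk(pairs$beta_exp, pairs$se_exp, pairs$pval_exp,
                   pairs$eaf_exp, pairs$n_exp),
       trait2 = mk(pairs$beta_out, pairs$se_out, pairs$pval_out,
                   pairs$eaf_out, pairs$n_out),
       region = list(chrom = at$chrom,
                     start = max(1, at$pos - half_width),
                     end = at$pos + half_width))
}

#' Check the single-causal-variant assumption in a region
#'
#' Runs the stepwise conditional analysis within the region and reports
#' whether more than one conditionally independent signal reaches
#' `secondary_p_threshold`. Regions failing the check violate the
#' single-causal-variant assumption of the colocalization model and their
#' verdicts should be labelled accordingly.
#'
#' @param records Summary-statistic data frame for one trait in the region
#'   (needs beta, se, pval, n, snp_id).
#' @param ld Correlation matrix covering the records.
#' @param secondary_p_threshold Significance required of a secondary signal
#'   (default 5e-8).
#' @return List with `single_signal` (logical) and `n_signals`.
#' @export
single_signal_check <- function(records, ld, secondary_p_threshold = 5e-8) {
  sel <- conditional_select(records, ld, p_threshold = secondary_p_threshold)
  list(single_signal = nrow(sel) <= 1L, n_signals = nrow(sel))
}
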