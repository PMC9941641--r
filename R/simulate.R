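# Synthetic GWAS summary statistics with exported ground truth.
#
# The generator emulates the statistical structure of a proteome-wide MR
# study: regional LD (AR1 or block-exchangeable), strong cis-pQTLs with
# realistic variance explained, a large-case discovery cohort and a
# small-case replication cohort for the binary outcome, optional
# pleiotropic instruments, and shared vs distinct causal-variant
# architectures for colocalization. Marginal associations follow the
# standard summary-statistic model z ~ MVN(sqrt(n_eff) R b, R) on the
# genotype-standardized scale; case-control effects are emitted on the
# log-OR scale with se = 1/sqrt(2 maf (1-maf) n K (1-K)).
#
# Truth objects are emitted alongside every dataset and are never consumed
# by the analysis pipeline.

#' Simulation configuration
#'
#' Defaults mirror the study conditions this generator emulates: a pooled
#' protein GWAS of 51,799 individuals, a discovery outcome cohort of 8021
#' cases / 16,489 controls, a replication cohort of 346 cases / 207,748
#' controls, sentinel cis-pQTLs explaining 10-30% of protein variance, and
#' a protective causal effect of -0.3 log-OR per SD of protein.
#'
#' @param seed RNG seed.
#' @param n_snps_per_region SNPs per simulated region.
#' @param ld_model `"ar1"` (R_ij = rho^|i-j|) or `"block"` (constant r
#'   within blocks of `block_size`).
#' @param ld_rho AR1 decay / within-block correlation.
#' @param block_size Block size for the block model.
#' @param maf_range Minor-allele-frequency range.
#' @param exposure_n Protein GWAS sample size.
#' @param outcome_n,outcome_cases Length-2 vectors (discovery, replication).
#' @param true_theta Causal effect of exposure on outcome (log-OR per SD).
#' @param pleiotropy_frac Fraction of invalid instruments.
#' @param pleiotropy_shift Mean directional pleiotropic offset (log-OR).
#' @param n_instruments Number of independent instruments for
#'   [simulate_mr_instruments()].
#' @param instrument_r2_range Range of per-sentinel variance explained in
#'   the protein.
#' @param causal_z Length-2 target marginal z at the causal variant for
#'   trait 1 and trait 2 in [simulate_region()].
#' @param coloc_scenario `"shared"`, `"distinct"`, `"trait1_only"`, `"null"`.
#' @param distinct_r2 Target r^2 between the two causal variants under the
#'   distinct scenario.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 20230207L,
                       n_snps_per_region = 100L,
                       ld_model = c("ar1", "block"),
                       ld_rho = 0.9,
                       block_size = 10L,
                       maf_range = c(0.05, 0.5),
                       exposure_n = 51799L,
                       outcome_n = c(24510L, 208094L),
                       outcome_cases = c(8021L, 346L),
                       true_theta = -0.3,
                       pleiotropy_frac = 0,
                       pleiotropy_shift = 0,
                       n_instruments = 50L,
                       instrument_r2_range = c(0.1, 0.3),
                       causal_z = c(10, 8),
                       coloc_scenario = c("shared", "distinct",
                                          "trait1_only", "null"),
                       distinct_r2 = 0.3) {
  stopifnot(n_snps_per_region > 0, all(outcome_n > 0),
            all(outcome_cases >= 0), all(outcome_cases < outcome_n),
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, ld_rho >= 0, ld_rho < 1)
  structure(list(
    seed = as.integer(seed), n_snps_per_region = as.integer(n_snps_per_region),
    ld_model = match.arg(ld_model), ld_rho = ld_rho,
    block_size = as.integer(block_size), maf_range = maf_range,
    exposure_n = as.integer(exposure_n), outcome_n = as.integer(outcome_n),
    outcome_cases = as.integer(outcome_cases), true_theta = true_theta,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_shift = pleiotropy_shift,
    n_instruments = as.integer(n_instruments),
    instrument_r2_range = instrument_r2_range, causal_z = causal_z,
    coloc_scenario = match.arg(coloc_scenario), distinct_r2 = distinct_r2
  ), class = "sim_config")
}

#' Build a regional LD correlation matrix
#'
#' @param m Number of SNPs.
#' @param model `"ar1"` or `"block"`.
#' @param rho Decay / within-block correlation.
#' @param block_size Block size for the block model.
#' @param ids Optional dimnames.
#' @return m x m correlation matrix.
#' @export
make_ld <- function(m, model = "ar1", rho = 0.9, block_size = 10L,
                    ids = NULL) {
  if (model == "ar1") {
    R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  } else {
    blk <- (seq_len(m) - 1L) %/% block_size
    R <- (outer(blk, blk, "==")) * rho
    diag(R) <- 1
    if (rho >= 1 || rho <= -1 / (block_size - 1))
      stop("block correlation ", rho, " gives a non-positive-definite matrix")
  }
  if (!is.null(ids)) dimnames(R) <- list(ids, ids)
  R
}

#' @noRd
n_eff_cc <- function(n, n_cases) {
  K <- n_cases / n
  n * K * (1 - K)
}

# Draw one marginal z field: z ~ MVN(sqrt(n_eff) R b_std, R)
#' @noRd
draw_z <- function(chol_R, R, b_std, n_eff) {
  mu <- sqrt(n_eff) * drop(R %*% b_std)
  mu + drop(crossprod(chol_R, stats::rnorm(nrow(R))))
}

# Convert a z field to a canonical summary-statistic data frame
#' @noRd
z_to_sumstats <- function(z, maf, ids, chrom, pos, n, trait_type,
                          n_cases = NA, alleles = NULL) {
  se <- if (trait_type == "case_control") {
    K <- n_cases / n
    1 / sqrt(2 * maf * (1 - maf) * n * K * (1 - K))
  } else {
    1 / sqrt(2 * maf * (1 - maf) * n)
  }
  if (is.null(alleles))
    alleles <- data.frame(ea = rep("A", length(z)), oa = rep("G", length(z)))
  data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = alleles$ea, other_allele = alleles$oa,
    eaf = maf, beta = z * se, se = se, pval = z_to_p(z),
    n = n, n_cases = n_cases, stringsAsFactors = FALSE
  )
}

#' Simulate one region of summary statistics for two traits
#'
#' Trait 1 is a quantitative exposure (protein level); trait 2 a
#' case-control outcome at the discovery-cohort sample sizes. Under
#' `coloc_scenario = "shared"` both traits load on the same causal variant;
#' `"distinct"` places the second trait's causal variant at the LD offset
#' closest to `distinct_r2`; `"trait1_only"` and `"null"` zero the second
#' (or both) trait's effects. Causal-variant z targets come from
#' `config$causal_z`.
#'
#' @param config A [sim_config()].
#' @param chrom,start Region location (defaults chrom "1" at 10 Mb).
#' @param region_id Prefix for SNP identifiers.
#' @return List with `trait1`, `trait2` (canonical summary-statistic data
#'   frames), `ld` (correlation matrix) and `truth` (causal indices, true
#'   standardized effects, scenario).
#' @export
simulate_region <- function(config, chrom = "1", start = 10e6,
                            region_id = "r1") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  simulate_region_impl(config, chrom, start, region_id)
}

# Internal worker that uses the current RNG stream (callers manage seeding).
#' @noRd
simulate_region_impl <- function(config, chrom = "1", start = 10e6,
                                 region_id = "r1",
                                 scenario = config$coloc_scenario,
                                 causal_z = config$causal_z) {
  m <- config$n_snps_per_region
  ids <- sprintf("%s_snp%03d", region_id, seq_len(m))
  pos <- as.integer(round(seq(start, start + 2e6, length.out = m)))
  R <- make_ld(m, config$ld_model, config$ld_rho, config$block_size, ids)
  chol_R <- chol(R)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  c1 <- sample(seq(m %/% 4, 3 * m %/% 4), 1L)
  c2 <- c1
  if (scenario == "distinct") {
    # place the second causal variant at the offset whose LD best matches
    # the requested inter-causal r^2
    target_r <- sqrt(config$distinct_r2)
    off <- which.min(abs(R[c1, ] - target_r))
    c2 <- off
  }

  n1 <- config$exposure_n
  n2 <- config$outcome_n[1]
  k2 <- config$outcome_cases[1]
  ne1 <- n1
  ne2 <- n_eff_cc(n2, k2)

  b1 <- numeric(m); b2 <- numeric(m)
  if (scenario != "null") b1[c1] <- causal_z[1] / sqrt(ne1)
  if (scenario == "shared") b2[c1] <- causal_z[2] / sqrt(ne2)
  if (scenario == "distinct") b2[c2] <- causal_z[2] / sqrt(ne2)

  z1 <- draw_z(chol_R, R, b1, ne1)
  z2 <- draw_z(chol_R, R, b2, ne2)

  list(
    trait1 = z_to_sumstats(z1, maf, ids, chrom, pos, n1, "quantitative"),
    trait2 = z_to_sumstats(z2, maf, ids, chrom, pos, n2, "case_control", k2),
    ld = R,
    truth = list(causal_idx1 = if (scenario == "null") NA_integer_ else c1,
                 causal_idx2 = switch(scenario, shared = c1, distinct = c2,
                                      NA_integer_),
                 b_std1 = b1, b_std2 = b2, scenario = scenario,
                 mu_z1 = sqrt(ne1) * drop(R %*% b1),
                 mu_z2 = sqrt(ne2) * drop(R %*% b2))
  )
}

#' Simulate independent MR instruments with two outcome cohorts
#'
#' Draws `n_instruments` mutually independent instruments with
#' genotype-standardized exposure effects of the configured strength and
#' random sign. Outcome effects are `theta * beta_exp` plus a directional
#' pleiotropic offset for a `pleiotropy_frac` fraction of invalid
#' instruments; the discovery and replication cohorts share the true
#' effects but have independent sampling noise at their own sample sizes.
#'
#' @param config A [sim_config()].
#' @return List with `discovery` and `replication` harmonized-pair data
#'   frames and `truth` (true exposure effects, theta, invalid flags).
#' @export
simulate_mr_instruments <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  L <- config$n_instruments
  maf <- stats::runif(L, config$maf_range[1], config$maf_range[2])
  sc <- sqrt(2 * maf * (1 - maf))   # genotype sd scale

  # per-instrument variance explained, split evenly across instruments
  r2 <- stats::runif(L, config$instrument_r2_range[1],
                     config$instrument_r2_range[2]) / L
  b_std <- sqrt(r2) * sample(c(-1, 1), L, replace = TRUE)
  invalid <- stats::runif(L) < config$pleiotropy_frac
  theta <- config$true_theta
  b_out_std <- theta * b_std + ifelse(invalid, config$pleiotropy_shift, 0)

  se_x <- 1 / sqrt(config$exposure_n) / sc
  bx_hat <- b_std / sc + stats::rnorm(L, 0, se_x)

  cohort <- function(n, n_cases) {
    se_y <- 1 / sqrt(n_eff_cc(n, n_cases)) / sc
    by_hat <- b_out_std / sc + stats::rnorm(L, 0, se_y)
    data.frame(
      snp_id = sprintf("iv%03d", seq_len(L)), chrom = "1",
      pos = seq_len(L) * 5e6,
      effect_allele = "A", other_allele = "G",
      beta_exp = bx_hat, se_exp = se_x, pval_exp = z_to_p(bx_hat / se_x),
      eaf_exp = maf,
      beta_out = by_hat, se_out = se_y, pval_out = z_to_p(by_hat / se_y),
      eaf_out = maf,
      n_exp = config$exposure_n, n_out = n,
      palindromic = FALSE, action = "none", stringsAsFactors = FALSE
    )
  }
  list(
    discovery = cohort(config$outcome_n[1], config$outcome_cases[1]),
    replication = cohort(config$outcome_n[2], config$outcome_cases[2]),
    truth = list(b_std = b_std, theta = theta, invalid = invalid,
                 maf = maf)
  )
}

#' Simulate a full proteome-scale input bundle
#'
#' Emits everything the discovery-replication-colocalization pipeline
#' consumes: per-protein regional protein summary statistics (cis and,
#' for a subset, trans architectures), two outcome cohorts simulated over
#' the same regions, gene and consequence annotation tables, per-region LD
#' matrices, and a ground-truth table. `n_causal` proteins receive the
#' configured causal effect on the outcome (their outcome signal is
#' mediated by the protein's causal variants, i.e. shared); `n_confounded`
#' proteins are NOT causal but sit in a region where the outcome has its
#' own causal variant in LD (r^2 about `distinct_r2`) with the sentinel
#' pQTL — the architecture that produces LD-confounded MR hits that
#' colocalization must exclude. One protein's gene is placed inside the
#' MHC window and one trans hub region is shared by six proteins to
#' exercise the MHC and pleiotropy filters.
#'
#' @param config A [sim_config()].
#' @param n_proteins Number of proteins.
#' @param n_causal Number of truly causal proteins.
#' @param n_confounded Number of LD-confounded (non-causal) proteins.
#' @return List with `proteins`, `exposure` (named list of per-protein
#'   summary-statistic data frames), `outcome_discovery`,
#'   `outcome_replication` (data frames over all region SNPs), `ld` (named
#'   list per region), `consequences`, `config` and `truth`.
#' @export
simulate_proteome <- function(config, n_proteins = 100L, n_causal = 5L,
                              n_confounded = 1L) {
  stopifnot(n_causal + n_confounded <= n_proteins)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  m <- config$n_snps_per_region
  theta <- config$true_theta
  ne_out <- n_eff_cc(config$outcome_n, config$outcome_cases)
  ne_exp <- config$exposure_n

  status <- c(rep("causal", n_causal), rep("confounded", n_confounded),
              rep("null", n_proteins - n_causal - n_confounded))
  status <- sample(status)

  # architectures: mostly cis-only, some cis+trans; six proteins share a
  # pleiotropic trans hub; one null protein's gene sits in the MHC
  arch <- sample(c("cis", "cis_trans"), n_proteins, replace = TRUE,
                 prob = c(0.75, 0.25))
  hub_members <- sample(which(status == "null"), min(6L, sum(status == "null")))
  mhc_candidates <- setdiff(which(status == "null"), hub_members)
  mhc_protein <- if (length(mhc_candidates)) mhc_candidates[1] else NA

  hub_R <- NULL; hub_ids <- NULL
  ld <- list(); exposure <- list()
  out_disc <- list(); out_rep <- list()
  prot_rows <- list(); truth_rows <- list(); cons_rows <- list()

  for (i in seq_len(n_proteins)) {
    pid <- sprintf("prot%03d", i)
    gene_chrom <- as.character(sample(setdiff(1:22, 6), 1))
    gene_tss <- as.integer(sample(20:200, 1) * 1e6)
    if (identical(i, mhc_protein)) { gene_chrom <- "6"; gene_tss <- 30000000L }
    rid <- sprintf("%s_cis", pid)
    start <- gene_tss - 1e6

    ids <- sprintf("%s_%03d", rid, seq_len(m))
    R <- make_ld(m, config$ld_model, config$ld_rho, config$block_size, ids)
    chol_R <- chol(R)
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    pos <- as.integer(round(seq(start, start + 2e6, length.out = m)))

    # protein causal variant and strength (variance explained per sentinel)
    c1 <- sample(seq(m %/% 4, 3 * m %/% 4), 1L)
    r2_sent <- stats::runif(1, config$instrument_r2_range[1],
                            config$instrument_r2_range[2])
    b_prot <- numeric(m); b_prot[c1] <- sqrt(r2_sent)

    b_out <- numeric(m); c_out <- NA_integer_
    if (status[i] == "causal") {
      b_out <- theta * b_prot
      c_out <- c1
    } else if (status[i] == "confounded") {
      target_r <- sqrt(config$distinct_r2)
      c_out <- which.min(abs(R[c1, ] - target_r))
      b_out[c_out] <- config$causal_z[2] / sqrt(ne_out[1])
    }

    z_p <- draw_z(chol_R, R, b_prot, ne_exp)
    z_d <- draw_z(chol_R, R, b_out, ne_out[1])
    z_r <- draw_z(chol_R, R, sqrt(ne_out[1] / ne_out[1]) * b_out, ne_out[2])

    expo <- z_to_sumstats(z_p, maf, ids, gene_chrom, pos, ne_exp,
                          "quantitative")
    expo$region_id <- rid
    ld[[rid]] <- R
    out_disc[[rid]] <- z_to_sumstats(z_d, maf, ids, gene_chrom, pos,
                                     config$outcome_n[1], "case_control",
                                     config$outcome_cases[1])
    out_rep[[rid]] <- z_to_sumstats(z_r, maf, ids, gene_chrom, pos,
                                    config$outcome_n[2], "case_control",
                                    config$outcome_cases[2])

    # trans architecture: a weaker second region elsewhere, either private
    # or the shared pleiotropic hub
    use_hub <- i %in% hub_members
    if (arch[i] == "cis_trans" || use_hub) {
      if (use_hub) {
        t_chrom <- "12"; t_start <- 50e6; t_rid <- "hub_trans"
      } else {
        t_chrom <- as.character(sample(setdiff(1:22, c(6, as.integer(gene_chrom))), 1))
        t_start <- as.integer(sample(20:200, 1) * 1e6)
        t_rid <- sprintf("%s_trans", pid)
      }
      if (use_hub && !is.null(hub_R)) {
        t_ids <- hub_ids; R_t <- hub_R
      } else {
        t_ids <- sprintf("%s_%03d", t_rid, seq_len(m))
        R_t <- make_ld(m, config$ld_model, config$ld_rho,
                       config$block_size, t_ids)
        if (use_hub) { hub_R <- R_t; hub_ids <- t_ids }
      }
      if (is.null(ld[[t_rid]])) ld[[t_rid]] <- R_t
      chol_t <- chol(R_t)
      maf_t <- stats::runif(m, config$maf_range[1], config$maf_range[2])
      pos_t <- as.integer(round(seq(t_start, t_start + 2e6, length.out = m)))
      ct <- sample(seq(m %/% 4, 3 * m %/% 4), 1L)
      if (use_hub) ct <- m %/% 2   # shared hub causal variant
      r2_t <- stats::runif(1, 0.02, 0.08)
      b_pt <- numeric(m); b_pt[ct] <- sqrt(r2_t)
      b_ot <- if (status[i] == "causal") theta * b_pt else numeric(m)

      z_pt <- draw_z(chol_t, R_t, b_pt, ne_exp)
      expo_t <- z_to_sumstats(z_pt, maf_t, t_ids, t_chrom, pos_t, ne_exp,
                              "quantitative")
      expo_t$region_id <- t_rid
      expo <- rbind(expo, expo_t)
      if (is.null(out_disc[[t_rid]])) {
        z_dt <- draw_z(chol_t, R_t, b_ot, ne_out[1])
        z_rt <- draw_z(chol_t, R_t, b_ot, ne_out[2])
        out_disc[[t_rid]] <- z_to_sumstats(z_dt, maf_t, t_ids, t_chrom,
                                           pos_t, config$outcome_n[1],
                                           "case_control",
                                           config$outcome_cases[1])
        out_rep[[t_rid]] <- z_to_sumstats(z_rt, maf_t, t_ids, t_chrom,
                                          pos_t, config$outcome_n[2],
                                          "case_control",
                                          config$outcome_cases[2])
      }
    }

    exposure[[pid]] <- expo
    cons_rows[[pid]] <- data.frame(
      snp_id = expo$snp_id,
      consequence = sample(c("intron_variant", "intergenic_variant",
                             "missense_variant"),
                           nrow(expo), replace = TRUE,
                           prob = c(0.6, 0.38, 0.02)),
      stringsAsFactors = FALSE)
    prot_rows[[pid]] <- data.frame(
      protein_id = pid, uniprot_id = sprintf("U%05d", i),
      gene = sprintf("GENE%03d", i), gene_chrom = gene_chrom,
      gene_tss = gene_tss, stringsAsFactors = FALSE)
    truth_rows[[pid]] <- data.frame(
      protein_id = pid, status = status[i],
      causal = status[i] == "causal",
      theta = if (status[i] == "causal") theta else 0,
      architecture = if (i %in% hub_members) "hub" else arch[i],
      cis_causal_idx = c1, outcome_causal_idx = c_out,
      stringsAsFactors = FALSE)
  }

  cons <- do.call(rbind, cons_rows)
  cons <- cons[!duplicated(cons$snp_id), ]
  list(
    proteins = do.call(rbind, prot_rows),
    exposure = exposure,
    outcome_discovery = do.call(rbind, out_disc),
    outcome_replication = do.call(rbind, out_rep),
    ld = ld,
    consequences = cons,
    config = config,
    truth = do.call(rbind, truth_rows)
  )
}
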