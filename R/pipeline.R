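# End-to-end discovery -> replication -> colocalization workflow over a
# proteome bundle (as produced by simulate_proteome(), or assembled from
# read_sumstats() tables with the same shape).
#
# Order of operations: instrument filters -> group construction (A-D) ->
# per-group MR on the discovery cohort -> BH-FDR within group ->
# replication MR for FDR-passing proteins -> MR-PRESSO outlier removal
# where applicable -> colocalization against the discovery outcome for
# replicated proteins. A PP.H3 > threshold coloc verdict (distinct causal
# variants) excludes a replicated protein as LD-confounded; PP.H4 >
# threshold upgrades it to replicated_colocalized.

#' @noRd
method_label <- function(code) {
  switch(code,
         wald_ratio = "Wald ratio",
         ivw_fe = "Inverse variance weighted (fixed effects)",
         ivw_mre = "Inverse variance weighted (multiplicative random effects)",
         egger = "MR Egger", weighted_median = "Weighted median", code)
}

# Block-diagonal LD over possibly several regions (zero correlation across
# regions).
#' @noRd
assemble_ld <- function(snp_ids, region_ids, ld_list) {
  n <- length(snp_ids)
  R <- diag(1, n)
  dimnames(R) <- list(snp_ids, snp_ids)
  for (rid in unique(region_ids)) {
    idx <- which(region_ids == rid)
    sub <- ld_list[[rid]][snp_ids[idx], snp_ids[idx], drop = FALSE]
    R[idx, idx] <- sub
  }
  R
}

#' @noRd
group_mr <- function(inst, outcome, n_exp, presso_n_sim, seed) {
  expo_rec <- inst
  expo_rec$n <- n_exp
  out_rec <- outcome[match(inst$snp_id, outcome$snp_id), , drop = FALSE]
  out_rec <- out_rec[!is.na(out_rec$snp_id), , drop = FALSE]
  pairs <- harmonize(expo_rec, out_rec, drop_palindromic = TRUE)
  if (nrow(pairs) == 0L) return(NULL)
  presso <- NULL
  if (nrow(pairs) >= 4L) {
    presso <- suppressMessages(
      mr_presso(pairs, n_sim = presso_n_sim, seed = seed))
    if (!is.null(presso) && length(presso$outlier_snps) &&
        nrow(pairs) - length(presso$outlier_snps) >= 1L)
      pairs <- pairs[!pairs$snp_id %in% presso$outlier_snps, , drop = FALSE]
  }
  res <- if (nrow(pairs) == 1L) mr_wald_ratio(pairs) else mr_ivw(pairs, "auto")
  st <- mr_steiger(pairs)
  res$steiger_correct <- st$steiger_correct
  f <- f_statistic(pairs$beta_exp, pairs$se_exp)
  res$r2_total <- sum(snp_r2(f, pairs$n_exp))
  list(result = res, pairs = pairs, presso = presso)
}

#' Run the full proteome MR + colocalization pipeline
#'
#' @param bundle Input bundle: list with `proteins`, `exposure` (named list
#'   of per-protein summary statistics with a `region_id` column),
#'   `outcome_discovery`, `outcome_replication`, `ld` (named list per
#'   region), `consequences` (snp_id/consequence table) and `config` (for
#'   sample sizes). See [simulate_proteome()].
#' @param p_threshold Genome-wide significance threshold for instruments.
#' @param f_min Weak-instrument F cutoff.
#' @param clump_r2 LD-clumping threshold.
#' @param cis_window Cis window half-width (bp).
#' @param fdr_threshold Discovery BH-FDR threshold (per instrument group).
#' @param rep_alpha Replication nominal alpha.
#' @param pp_threshold Colocalization posterior threshold.
#' @param coloc_half_width Colocalization window half-width (bp).
#' @param presso_n_sim MR-PRESSO simulation replicates.
#' @param seed Seed for the stochastic sensitivity analyses.
#' @return List: `verdicts` (per protein: final_status, best group,
#'   coloc decision), `mr_discovery`, `mr_replication` (per protein x group
#'   results), `coloc` (per-protein coloc results), `table1`, `table2`
#'   (report data frames), `log` (per-filter counts).
#' @export
run_pipeline <- function(bundle,
                         p_threshold = 5e-8, f_min = 10, clump_r2 = 0.1,
                         cis_window = 1e6, fdr_threshold = 0.05,
                         rep_alpha = 0.05, pp_threshold = 0.8,
                         coloc_half_width = 1e6, presso_n_sim = 500L,
                         seed = 1L) {
  prot <- bundle$proteins
  n_exp <- bundle$config$exposure_n
  K_disc <- bundle$config$outcome_cases[1] / bundle$config$outcome_n[1]

  # --- significant pQTLs per protein + pleiotropy counts -----------------
  sig <- lapply(prot$protein_id, function(pid) {
    ex <- bundle$exposure[[pid]]
    s <- ex[ex$pval < p_threshold, , drop = FALSE]
    if (nrow(s)) s$protein_id <- pid
    s
  })
  names(sig) <- prot$protein_id
  all_sig <- do.call(rbind, sig[vapply(sig, nrow, 1L) > 0])
  pleio_counts <- if (!is.null(all_sig) && nrow(all_sig)) {
    tab <- tapply(all_sig$protein_id, all_sig$snp_id,
                  function(x) length(unique(x)))
    setNames(as.integer(tab), names(tab))
  } else integer(0)

  # --- filters + groups ---------------------------------------------------
  groups <- list(); filter_log <- list()
  for (i in seq_len(nrow(prot))) {
    pid <- prot$protein_id[i]
    s <- sig[[pid]]
    if (is.null(s) || nrow(s) == 0L) next
    s$consequence <- bundle$consequences$consequence[
      match(s$snp_id, bundle$consequences$snp_id)]
    s$f_stat <- f_statistic(s$beta, s$se)
    f <- filter_instruments(s, pleio_counts, p_threshold = p_threshold,
                            f_min = f_min, consequence_mode = "lenient")
    filter_log[[pid]] <- attr(f, "removed")
    if (nrow(f) == 0L) next
    f <- assign_cis_trans(f, prot$gene_chrom[i], prot$gene_tss[i],
                          window = cis_window)
    ldm <- assemble_ld(f$snp_id, f$region_id, bundle$ld)
    groups[[pid]] <- build_groups(f, ldm, clump_r2 = clump_r2,
                                  cond_p = p_threshold)
  }

  # --- discovery MR per group --------------------------------------------
  mr_rows <- function(outcome, which_prot = NULL) {
    rows <- list()
    for (pid in names(groups)) {
      if (!is.null(which_prot) && !pid %in% which_prot) next
      for (g in c("A", "B", "C", "D")) {
        inst <- groups[[pid]][[g]]
        if (is.null(inst) || nrow(inst) == 0L) next
        fit <- group_mr(inst, outcome, n_exp, presso_n_sim, seed)
        if (is.null(fit)) next
        r <- fit$result
        r$protein_id <- pid; r$group <- g
        rows[[paste(pid, g)]] <- r
      }
    }
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  }

  disc <- mr_rows(bundle$outcome_discovery)
  if (is.null(disc)) stop("no protein yielded any instruments")
  disc$fdr <- NA_real_
  for (g in unique(disc$group)) {
    idx <- disc$group == g
    disc$fdr[idx] <- bh_fdr(disc$pval[idx])
  }
  disc$power <- mapply(function(r2, or) {
    if (r2 <= 0 || r2 >= 1) return(NA_real_)
    mr_power_binary(r2, or, bundle$config$outcome_n[1], K_disc)
  }, disc$r2_total, disc$or_)

  fdr_pass <- unique(disc$protein_id[disc$fdr < fdr_threshold])
  repl <- if (length(fdr_pass))
    mr_rows(bundle$outcome_replication, which_prot = fdr_pass)
  else NULL

  # --- discovery -> replication rule per group ---------------------------
  replicated <- character(0)
  rep_by_group <- list()
  if (!is.null(repl)) {
    for (g in unique(disc$group)) {
      d <- disc[disc$group == g, , drop = FALSE]
      r <- repl[repl$group == g, , drop = FALSE]
      ok <- discover_replicate(d, r, fdr_threshold, rep_alpha)
      rep_by_group[[g]] <- ok
      replicated <- union(replicated, ok)
    }
  }

  # --- colocalization vs the discovery outcome ---------------------------
  coloc_res <- list()
  for (pid in replicated) {
    A <- groups[[pid]]$A
    sent <- if (!is.null(A) && nrow(A)) A$snp_id[1]
    else groups[[pid]]$D$snp_id[1]
    rid <- groups[[pid]]$D$region_id[match(sent, groups[[pid]]$D$snp_id)]
    if (is.na(rid)) rid <- groups[[pid]]$A$region_id[1]
    expo_reg <- bundle$exposure[[pid]]
    expo_reg <- expo_reg[expo_reg$region_id == rid, , drop = FALSE]
    sl <- extract_region(expo_reg, bundle$outcome_discovery, sent,
                         half_width = coloc_half_width)
    if (nrow(sl$trait1) == 0L) next
    ldm <- bundle$ld[[rid]]
    ssc1 <- single_signal_check(sl$trait1, ldm, p_threshold)
    ssc2 <- single_signal_check(sl$trait2, ldm, p_threshold)
    cr <- coloc_region(sl$trait1[, c("beta", "se")],
                       sl$trait2[, c("beta", "se")],
                       trait_types = c("quantitative", "case_control"),
                       pp_threshold = pp_threshold)
    cr$single_signal <- ssc1$single_signal && ssc2$single_signal
    cr$sentinel <- sent
    coloc_res[[pid]] <- cr
  }

  # --- verdicts -----------------------------------------------------------
  pref <- c(A = 1, B = 2, D = 3, C = 4)
  verdicts <- list()
  for (i in seq_len(nrow(prot))) {
    pid <- prot$protein_id[i]
    d <- disc[disc$protein_id == pid, , drop = FALSE]
    sig_groups <- d$group[d$fdr < fdr_threshold]
    status <- if (nrow(d) == 0L || !length(sig_groups)) "not_significant"
    else if (!pid %in% replicated) "discovery_only"
    else {
      cd <- coloc_res[[pid]]
      if (!is.null(cd) && cd$decision == "distinct") "excluded_LD_confounded"
      else if (!is.null(cd) && cd$decision == "shared") "replicated_colocalized"
      else "replicated"
    }
    rep_groups <- names(Filter(function(x) pid %in% x, rep_by_group))
    best_groups <- if (length(rep_groups)) rep_groups
    else if (length(sig_groups)) sig_groups
    else d$group
    best <- if (length(best_groups))
      best_groups[order(pref[best_groups])][1]
    else NA_character_
    verdicts[[pid]] <- data.frame(
      protein_id = pid, final_status = status, group = best,
      coloc_decision = if (!is.null(coloc_res[[pid]]))
        coloc_res[[pid]]$decision else NA_character_,
      stringsAsFactors = FALSE)
  }
  verdicts <- do.call(rbind, verdicts); rownames(verdicts) <- NULL

  out <- list(verdicts = verdicts, mr_discovery = disc,
              mr_replication = repl, coloc = coloc_res,
              groups = groups, log = filter_log,
              proteins = prot, pp_threshold = pp_threshold)
  rep_tables <- verdict_report(out)
  out$table1 <- rep_tables$table1
  out$table2 <- rep_tables$table2
  out$summary <- rep_tables$summary
  out
}

#' Report tables in the study layout
#'
#' Builds the MR results table (protein, UniProt ID, method, p, FDR, OR
#' with 95% CI, r2, power, group; one row per reported protein, the
#' preferred group A > B > D > C shown) and the colocalization table
#' (protein, SNP count, PP.H0..PP.H4, decision), plus a one-line status
#' summary.
#'
#' @param run A [run_pipeline()] result (or the partial list it builds).
#' @param dir Optional directory; when given, writes `table1.tsv`,
#'   `table2.tsv` and `summary.txt` there.
#' @return List with `table1`, `table2`, `summary`.
#' @export
verdict_report <- function(run, dir = NULL) {
  v <- run$verdicts
  reported <- v[v$final_status %in%
                  c("replicated", "replicated_colocalized"), , drop = FALSE]
  mk_row <- function(pid, grp) {
    d <- run$mr_discovery
    r <- d[d$protein_id == pid & d$group == grp, , drop = FALSE]
    u <- run$proteins$uniprot_id[match(pid, run$proteins$protein_id)]
    data.frame(protein = pid, UniprotID = u,
               method = method_label(r$method), pval = r$pval, FDR = r$fdr,
               OR = r$or_, lower = r$or_lci, upper = r$or_uci,
               r2 = r$r2_total, power = r$power, group = grp,
               stringsAsFactors = FALSE)
  }
  table1 <- if (nrow(reported)) {
    do.call(rbind, Map(mk_row, reported$protein_id, reported$group))
  } else {
    data.frame(protein = character(0), UniprotID = character(0),
               method = character(0), pval = numeric(0), FDR = numeric(0),
               OR = numeric(0), lower = numeric(0), upper = numeric(0),
               r2 = numeric(0), power = numeric(0), group = character(0),
               stringsAsFactors = FALSE)
  }

  coloc_ids <- names(run$coloc)
  table2 <- if (length(coloc_ids)) {
    do.call(rbind, lapply(coloc_ids, function(pid) {
      cr <- run$coloc[[pid]]
      u <- run$proteins$uniprot_id[match(pid, run$proteins$protein_id)]
      cbind(data.frame(protein = pid, UniprotID = u, N = cr$n_snps,
                       stringsAsFactors = FALSE),
            as.data.frame(t(signif(cr$pp, 3))),
            data.frame(decision = cr$decision,
                       single_signal = cr$single_signal))
    }))
  } else data.frame(protein = character(0))
  rownames(table1) <- rownames(table2) <- NULL

  counts <- table(factor(v$final_status,
                         levels = c("not_significant", "discovery_only",
                                    "replicated", "excluded_LD_confounded",
                                    "replicated_colocalized")))
  summary_txt <- paste0(
    sum(counts[c("replicated", "replicated_colocalized")]),
    " protein(s) reported (", counts[["replicated_colocalized"]],
    " colocalized); ", counts[["excluded_LD_confounded"]],
    " excluded as LD-confounded; ", counts[["discovery_only"]],
    " discovery-only; ", counts[["not_significant"]], " not significant.")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table1, file.path(dir, "table1.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(table2, file.path(dir, "table2.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(summary_txt, file.path(dir, "summary.txt"))
  }
  list(table1 = table1, table2 = table2, summary = summary_txt)
}

#' Score pipeline verdicts against simulation truth
#'
#' Compares the reported protein set (final status `replicated` or
#' `replicated_colocalized`) with the ground-truth causal flags of a
#' [simulate_proteome()] bundle.
#'
#' @param verdicts Verdict data frame from [run_pipeline()].
#' @param truth Truth data frame from the bundle.
#' @return List with counts `tp`, `fp`, `fn`, observed `fdr` and
#'   `sensitivity`, and the number of LD-confounded proteins correctly
#'   excluded.
#' @export
score_verdicts <- function(verdicts, truth) {
  rep_ids <- verdicts$protein_id[
    verdicts$final_status %in% c("replicated", "replicated_colocalized")]
  causal <- truth$protein_id[truth$causal]
  tp <- length(intersect(rep_ids, causal))
  fp <- length(setdiff(rep_ids, causal))
  fn <- length(setdiff(causal, rep_ids))
  excl <- verdicts$protein_id[verdicts$final_status == "excluded_LD_confounded"]
  conf <- truth$protein_id[truth$status == "confounded"]
  list(tp = tp, fp = fp, fn = fn,
       fdr = if (tp + fp) fp / (tp + fp) else 0,
       sensitivity = if (length(causal)) tp / length(causal) else NA_real_,
       confounded_excluded = length(intersect(excl, conf)))
}
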