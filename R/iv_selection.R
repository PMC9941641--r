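# Instrument selection for proteome-wide MR: significance / strength / MHC /
# pleiotropy / coding-variant filters, cis-trans assignment, sentinel
# selection, LD clumping, summary-statistic conditional analysis, and the
# four instrument groupings:
#   A  sentinel cis-pQTLs only (never clumped: the sentinel is the most
#      significant SNP of its region by construction)
#   B  sentinel plus conditionally independent cis-pQTLs, clumped r^2 < 0.1
#   C  trans-pQTLs only, clumped
#   D  all pQTLs, clumped

#' MHC exclusion window (GRCh37)
#'
#' The extended major histocompatibility complex region on chromosome 6,
#' excluded from instrument lists for its extreme LD and pleiotropy.
#'
#' @return List with `chrom`, `start`, `end` (1-based inclusive).
#' @export
mhc_region <- function() list(chrom = "6", start = 27477797, end = 34448354)

#' Protein-coding-altering consequence classes excluded from instruments
#'
#' Coding variants can alter the measured epitope rather than protein
#' abundance (binding artefacts), so pQTLs with these predicted consequences
#' are not used as instruments.
#'
#' @return Character vector of consequence terms.
#' @export
coding_consequences <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost",
    "frameshift_variant", "inframe_insertion", "inframe_deletion")
}

#' Instrument F statistic and per-SNP variance explained
#'
#' F is computed from the marginal association as (beta/se)^2; the variance
#' in the exposure explained by one SNP follows as r2 = F/(F + n - 2).
#'
#' @param beta,se Marginal effect and standard error.
#' @param n Sample size (for [snp_r2()]).
#' @return Numeric vector.
#' @export
f_statistic <- function(beta, se) (beta / se)^2

#' @rdname f_statistic
#' @param f F statistic.
#' @export
snp_r2 <- function(f, n) f / (f + n - 2)

#' Apply the pQTL instrument filters
#'
#' Retains records that are genome-wide significant (`pval < p_threshold`),
#' strong (`f_stat >= f_min`), outside the MHC window, associated with at
#' most `max_proteins` proteins, and not protein-coding-altering. Removal
#' counts per filter are recorded in the `removed` attribute.
#'
#' @param records pQTL data frame: canonical summary-statistic columns plus
#'   `protein_id` and `consequence`; `f_stat` is computed from beta/se when
#'   absent.
#' @param pleiotropy_counts Named integer vector, snp_id -> number of
#'   proteins the SNP is associated with (computed over the full
#'   genome-wide-significant pQTL table).
#' @param p_threshold Genome-wide significance threshold.
#' @param f_min Weak-instrument cutoff on F.
#' @param max_proteins Pleiotropy cutoff (SNPs associated with more than
#'   this many proteins are excluded everywhere).
#' @param mhc MHC window as from [mhc_region()].
#' @param consequence_mode `"strict"` errors on a missing consequence
#'   annotation, `"lenient"` keeps and flags the record.
#' @return Filtered pQTL data frame with attribute `removed`.
#' @export
filter_instruments <- function(records, pleiotropy_counts = NULL,
                               p_threshold = 5e-8, f_min = 10,
                               max_proteins = 5, mhc = mhc_region(),
                               consequence_mode = c("strict", "lenient")) {
  consequence_mode <- match.arg(consequence_mode)
  if (is.null(records$f_stat))
    records$f_stat <- f_statistic(records$beta, records$se)

  if (any(is.na(records$consequence))) {
    if (consequence_mode == "strict")
      stop("records lack consequence annotation; use consequence_mode='lenient' to keep them")
    records$consequence[is.na(records$consequence)] <- "unannotated"
  }

  removed <- c(not_significant = 0L, weak_instrument = 0L, mhc = 0L,
               pleiotropic = 0L, coding = 0L)
  keep <- records$pval < p_threshold
  removed["not_significant"] <- sum(!keep)

  ok_f <- records$f_stat >= f_min
  removed["weak_instrument"] <- sum(keep & !ok_f)
  keep <- keep & ok_f

  in_mhc <- records$chrom == mhc$chrom &
    records$pos >= mhc$start & records$pos <= mhc$end
  removed["mhc"] <- sum(keep & in_mhc)
  keep <- keep & !in_mhc

  if (!is.null(pleiotropy_counts)) {
    cnt <- pleiotropy_counts[records$snp_id]
    cnt[is.na(cnt)] <- 1L
    pleio <- cnt > max_proteins
    removed["pleiotropic"] <- sum(keep & pleio)
    keep <- keep & !pleio
  }

  coding <- records$consequence %in% coding_consequences()
  removed["coding"] <- sum(keep & coding)
  keep <- keep & !coding

  structure(records[keep, , drop = FALSE], removed = removed)
}

#' Assign cis/trans status relative to the encoded gene
#'
#' A pQTL is cis when it lies on the gene's chromosome within `window` base
#' pairs of the transcription start site (boundary inclusive), trans
#' otherwise. With unknown gene coordinates every record is trans-only and a
#' warning is raised (the protein is then absent from cis groups).
#'
#' @param records pQTL data frame.
#' @param gene_chrom,gene_tss Gene coordinates (GRCh37).
#' @param window Cis window half-width in base pairs (default 1 Mb).
#' @return `records` with logical column `is_cis`.
#' @export
assign_cis_trans <- function(records, gene_chrom, gene_tss, window = 1e6) {
  if (is.na(gene_chrom) || is.na(gene_tss)) {
    warning("gene coordinates missing: all records treated as trans")
    records$is_cis <- FALSE
    return(records)
  }
  records$is_cis <- records$chrom == as.character(gene_chrom) &
    abs(records$pos - gene_tss) <= window
  records
}

#' Select sentinel pQTLs
#'
#' Greedily picks the SNP with the lowest p-value, masks all SNPs within
#' `region_span` base pairs of it on the same chromosome, and repeats until
#' no SNPs remain. Ties are broken by larger F statistic, then snp_id.
#'
#' @param records pQTL data frame (one protein).
#' @param region_span Region half-width in base pairs (default 1 Mb).
#' @return The sentinel rows of `records`.
#' @export
select_sentinel <- function(records, region_span = 1e6) {
  if (nrow(records) == 0L) return(records)
  if (is.null(records$f_stat))
    records$f_stat <- f_statistic(records$beta, records$se)
  ord <- order(records$pval, -records$f_stat, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  picked <- integer(0)
  alive <- rep(TRUE, nrow(rec))
  while (any(alive)) {
    i <- which(alive)[1L]
    picked <- c(picked, i)
    alive <- alive & !(rec$chrom == rec$chrom[i] &
                         abs(rec$pos - rec$pos[i]) <= region_span)
  }
  rec[picked, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Orders SNPs by ascending p-value, retains the best remaining SNP and
#' discards every SNP with squared correlation `>= r2_threshold` against any
#' retained SNP. The output is therefore pairwise r^2 below the threshold.
#'
#' @param records pQTL data frame.
#' @param ld SNP x SNP correlation matrix (r, not r^2) with dimnames covering
#'   all `records$snp_id`.
#' @param r2_threshold Clumping threshold on r^2 (default 0.1).
#' @param priority Optional character vector of snp_ids ranked ahead of all
#'   other SNPs in the greedy order (used to keep group D consistent with
#'   the already-selected B and C sets); within and outside the priority set
#'   the order is by ascending p.
#' @return The retained rows of `records`.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.1, priority = NULL) {
  if (nrow(records) <= 1L) return(records)
  missing <- setdiff(records$snp_id, rownames(ld))
  if (length(missing))
    stop("SNPs missing from LD matrix: ", paste(missing, collapse = ", "))
  pri <- records$snp_id %in% priority
  ord <- order(!pri, records$pval, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  r2 <- ld[rec$snp_id, rec$snp_id, drop = FALSE]^2
  keep <- logical(nrow(rec))
  alive <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive <- alive & r2[i, ] < r2_threshold
    alive[i] <- FALSE
  }
  rec[keep, , drop = FALSE]
}

#' Stepwise conditional selection of independent signals
#'
#' Approximate conditional and joint analysis from summary statistics: on
#' the standardized scale (b = z/sqrt(n), se = 1/sqrt(n)) the joint effects
#' of a candidate set S are R_S^{-1} b_S with sampling covariance
#' R_S^{-1}/n. Starting from the sentinel (lowest marginal p), each step
#' evaluates every remaining SNP's effect conditional on the selected set
#' and adds the SNP with the smallest conditional p-value if it is below
#' `p_threshold`; candidates with r^2 > `collinear_r2` against the selected
#' set are skipped.
#'
#' @param records pQTL data frame with beta, se, pval, n.
#' @param ld Correlation matrix with dimnames covering `records$snp_id`.
#' @param p_threshold Conditional significance threshold (default 5e-8).
#' @param collinear_r2 Collinearity guard (default 0.9).
#' @return The selected rows of `records` with columns `beta_cond`,
#'   `se_cond`, `pval_cond` (standardized scale), in selection order.
#' @export
conditional_select <- function(records, ld, p_threshold = 5e-8,
                               collinear_r2 = 0.9) {
  if (nrow(records) == 0L) return(records)
  ids <- records$snp_id
  R <- ld[ids, ids, drop = FALSE]
  z <- records$beta / records$se
  b <- z / sqrt(records$n)

  sel <- order(records$pval, ids)[1L]
  if (records$pval[sel] >= p_threshold)
    return(records[integer(0), , drop = FALSE])

  cond_stats <- function(set) {
    Rs <- R[set, set, drop = FALSE]
    inv <- tryCatch(solve(Rs), error = function(e)
      stop("singular LD submatrix in conditional analysis: ",
           conditionMessage(e), call. = FALSE))
    bj <- drop(inv %*% b[set])
    sej <- sqrt(diag(inv) / records$n[set])
    list(beta = bj, se = sej, p = z_to_p(bj / sej))
  }

  repeat {
    remaining <- setdiff(seq_along(ids), sel)
    if (!length(remaining)) break
    max_r2 <- apply(R[remaining, sel, drop = FALSE]^2, 1, max)
    cand <- remaining[max_r2 <= collinear_r2]
    if (!length(cand)) break
    best_p <- Inf; best <- NA_integer_
    for (j in cand) {
      st <- cond_stats(c(sel, j))
      pj <- st$p[length(st$p)]
      if (pj < best_p) { best_p <- pj; best <- j }
    }
    if (best_p < p_threshold) sel <- c(sel, best) else break
  }

  st <- cond_stats(sel)
  out <- records[sel, , drop = FALSE]
  out$beta_cond <- st$beta
  out$se_cond <- st$se
  out$pval_cond <- st$p
  out
}

#' Build the four instrument groups for one protein
#'
#' @param records Filtered pQTL data frame for one protein with `is_cis`
#'   assigned.
#' @param ld Correlation matrix covering all records.
#' @param clump_r2 Clumping threshold (default 0.1).
#' @param cond_p Conditional-analysis significance threshold (default 5e-8).
#' @param region_span Sentinel region half-width (default 1 Mb).
#' @return Named list of data frames `A`, `B`, `C`, `D` (possibly 0-row).
#'   Group A is never clumped; B, C and D are clumped at `clump_r2`, with D
#'   clumped giving priority to the SNPs already selected into B and C so
#'   that the groups nest (A in B in D, C in D).
#' @export
build_groups <- function(records, ld, clump_r2 = 0.1, cond_p = 5e-8,
                         region_span = 1e6) {
  cis <- records[records$is_cis, , drop = FALSE]
  trans <- records[!records$is_cis, , drop = FALSE]

  A <- select_sentinel(cis, region_span = region_span)
  B <- if (nrow(cis)) {
    ind <- conditional_select(cis, ld, p_threshold = cond_p)
    pool <- rbind(A, cis[cis$snp_id %in%
                           setdiff(ind$snp_id, A$snp_id), , drop = FALSE])
    ld_clump(pool, ld, r2_threshold = clump_r2, priority = A$snp_id)
  } else cis
  C <- if (nrow(trans)) ld_clump(trans, ld, r2_threshold = clump_r2) else trans
  D <- if (nrow(records)) {
    ld_clump(records, ld, r2_threshold = clump_r2,
             priority = c(A$snp_id, B$snp_id, C$snp_id))
  } else records
  list(A = A, B = B, C = C, D = D)
}
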