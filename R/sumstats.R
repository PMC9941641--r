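# GWAS summary-statistic records: I/O, validation, allele harmonization and
# fixed-effect inverse-variance meta-analysis.
#
# A summary-statistic table is an ordinary data.frame with the canonical
# columns snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
# pval, n, n_cases (eaf and n_cases may be NA). Positions are GRCh37,
# 1-based. beta is the additive per-allele effect (log-OR for case-control
# traits), always reported for the effect allele.

CANONICAL_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n", "n_cases")

#' Default column mapping for summary-statistic tables
#'
#' Maps canonical field names to the column headers commonly used in GWAS
#' summary-statistic releases. Override entries to match a specific source.
#'
#' @return Named character vector: canonical field -> source column name.
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pval = "P", n = "N", n_cases = "N_CASES")
}

#' Trait metadata
#'
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param n Total sample size.
#' @param n_cases Number of cases (case-control traits only).
#' @param uniprot_id,gene,gene_chrom,gene_tss Optional protein/gene annotation
#'   used for cis/trans assignment (TSS in GRCh37 base pairs).
#' @return A `trait_meta` list.
#' @export
trait_meta <- function(trait_id, trait_type = c("quantitative", "case_control"),
                       n, n_cases = NA_integer_, uniprot_id = NA_character_,
                       gene = NA_character_, gene_chrom = NA_character_,
                       gene_tss = NA_integer_) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "case_control") {
    if (is.na(n_cases) || n_cases <= 0 || n_cases >= n)
      stop("case_control trait requires 0 < n_cases < n")
  }
  structure(list(trait_id = trait_id, trait_type = trait_type, n = n,
                 n_cases = n_cases, uniprot_id = uniprot_id, gene = gene,
                 gene_chrom = gene_chrom, gene_tss = gene_tss),
            class = "trait_meta")
}

#' Validate summary-statistic rows
#'
#' Applies the record invariants: valid distinct alleles, positive se,
#' p in (0, 1], eaf (when present) strictly inside (0, 1), positive n, and
#' consistency of the reported p-value with the two-sided normal p implied by
#' z = beta/se (relative tolerance `zp_tol`, guarding against column
#' mix-ups while tolerating rounded published p-values).
#'
#' @param df Data frame with the canonical columns.
#' @param zp_tol Relative tolerance for the z/p consistency check.
#' @return List with `records` (valid rows) and `drop_counts` (named counts
#'   per violated rule).
#' @export
validate_sumstats <- function(df, zp_tol = 0.1) {
  stopifnot(all(CANONICAL_COLS %in% names(df)))
  bases <- c("A", "C", "G", "T")
  drop <- c(bad_alleles = 0L, bad_se = 0L, bad_pval = 0L, bad_eaf = 0L,
            bad_n = 0L, zp_inconsistent = 0L)

  ok_alleles <- df$effect_allele %in% bases & df$other_allele %in% bases &
    df$effect_allele != df$other_allele
  ok_se <- is.finite(df$se) & df$se > 0
  ok_p <- is.finite(df$pval) & df$pval > 0 & df$pval <= 1
  ok_eaf <- is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)
  ok_n <- is.finite(df$n) & df$n > 0

  # z/p agreement on the p scale; only checkable where se and p are valid
  p_implied <- z_to_p(df$beta / df$se)
  ok_zp <- !ok_se | !ok_p |
    abs(p_implied - df$pval) <= zp_tol * pmax(p_implied, df$pval)

  drop["bad_alleles"] <- sum(!ok_alleles)
  drop["bad_se"] <- sum(ok_alleles & !ok_se)
  drop["bad_pval"] <- sum(ok_alleles & ok_se & !ok_p)
  drop["bad_eaf"] <- sum(ok_alleles & ok_se & ok_p & !ok_eaf)
  drop["bad_n"] <- sum(ok_alleles & ok_se & ok_p & ok_eaf & !ok_n)
  drop["zp_inconsistent"] <-
    sum(ok_alleles & ok_se & ok_p & ok_eaf & ok_n & !ok_zp)

  keep <- ok_alleles & ok_se & ok_p & ok_eaf & ok_n & ok_zp
  list(records = df[keep, , drop = FALSE], drop_counts = drop)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited table with a header, renames columns via
#' `column_map`, validates every row and drops (with counts) rows violating
#' the record invariants.
#'
#' @param path Path to the delimited file.
#' @param column_map Named vector as from [default_column_map()]. `eaf` and
#'   `n_cases` entries are optional; all other fields are mandatory.
#' @param meta Optional [trait_meta()]; when given, a missing `n` column is
#'   filled from it.
#' @param zp_tol Passed to [validate_sumstats()].
#' @return Data frame of validated records with the canonical columns;
#'   attribute `drop_counts` carries the per-filter removal counts.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          meta = NULL, zp_tol = 0.1) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)

  optional <- c("eaf", "n_cases")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in CANONICAL_COLS) {
    src <- column_map[[field]]
    if (!is.null(src) && src %in% names(raw)) {
      out[[field]] <- raw[[src]]
    } else if (field == "n" && !is.null(meta)) {
      out[[field]] <- meta$n
    } else if (field %in% optional) {
      out[[field]] <- NA_real_
    } else {
      stop("missing mandatory column '", field, "' (source '", src, "') in ",
           path, call. = FALSE)
    }
  }
  out$chrom <- as.character(out$chrom)
  v <- validate_sumstats(out, zp_tol = zp_tol)
  if (nrow(v$records) == 0L)
    stop("no valid summary-statistic rows in ", path, call. = FALSE)
  structure(v$records, drop_counts = v$drop_counts)
}

#' Write a normalized summary-statistics table
#'
#' Writes the canonical-column TSV plus an optional JSON sidecar with the
#' per-filter drop counts recorded by [read_sumstats()].
#'
#' @param records Summary-statistic data frame.
#' @param path Output TSV path.
#' @param sidecar Logical; write `<path>.json` with drop counts.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(records, path, sidecar = TRUE) {
  utils::write.table(records[, CANONICAL_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (sidecar) {
    dc <- attr(records, "drop_counts") %||% integer(0)
    jsonlite::write_json(as.list(dc), paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @noRd
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches records by `snp_id` and orients the outcome effect to the
#' exposure's effect allele: when the outcome's alleles are swapped relative
#' to the exposure, its beta is negated and eaf replaced by 1 - eaf
#' (`action` `"flipped"`); allele sets that cannot be reconciled are dropped;
#' palindromic SNPs (A/T or C/G) are dropped when `drop_palindromic` is TRUE,
#' since their strand cannot be resolved from alleles alone.
#'
#' @param exposure,outcome Summary-statistic data frames.
#' @param drop_palindromic Drop palindromic SNPs (default TRUE).
#' @return Data frame of harmonized pairs (one row per retained SNP) with
#'   columns snp_id, chrom, pos, effect_allele, other_allele, beta_exp,
#'   se_exp, pval_exp, eaf_exp, beta_out, se_out, pval_out, n_exp, n_out,
#'   palindromic, action. Attribute `dropped` reports counts by reason.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  if (anyDuplicated(exposure$snp_id))
    stop("duplicate snp_id in exposure", call. = FALSE)
  if (anyDuplicated(outcome$snp_id))
    stop("duplicate snp_id in outcome", call. = FALSE)

  idx <- match(exposure$snp_id, outcome$snp_id)
  keep <- !is.na(idx)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[idx[keep], , drop = FALSE]
  dropped <- c(unmatched = sum(!keep), palindromic = 0L, irreconcilable = 0L)

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  beta_out <- ifelse(swapped, -ou$beta, ou$beta)
  eaf_out <- ifelse(swapped, 1 - ou$eaf, ou$eaf)

  pairs <- data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval, eaf_exp = ex$eaf,
    beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
    eaf_out = eaf_out, n_exp = ex$n, n_out = ou$n,
    palindromic = pal,
    action = ifelse(same, "none", ifelse(swapped, "flipped", "dropped")),
    stringsAsFactors = FALSE
  )

  dropped["irreconcilable"] <- sum(pairs$action == "dropped")
  retain <- pairs$action != "dropped"
  if (drop_palindromic) {
    dropped["palindromic"] <- sum(retain & pairs$palindromic)
    retain <- retain & !pairs$palindromic
  }
  structure(pairs[retain, , drop = FALSE], dropped = dropped)
}

#' Fixed-effect inverse-variance meta-analysis across studies
#'
#' Pools per-SNP effects across >= 2 studies with inverse-variance weights:
#' beta* = sum(b_i/se_i^2) / sum(1/se_i^2), se* = sqrt(1/sum(1/se_i^2)),
#' n summed, p from z = beta*/se*. Alleles must already be oriented to the
#' first study. SNPs present in a single study pass through unchanged and
#' are flagged in the `single_study` column.
#'
#' @param studies List (length >= 2) of summary-statistic data frames.
#' @return Pooled summary-statistic data frame with extra columns
#'   `n_studies` and `single_study`.
#' @export
meta_analyze <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 2L)
  for (s in studies)
    if (anyDuplicated(s$snp_id)) stop("duplicate snp_id within a study")

  all_ids <- unique(unlist(lapply(studies, `[[`, "snp_id")))
  tmpl_src <- do.call(rbind, lapply(studies, function(s)
    s[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "eaf")]))
  tmpl <- tmpl_src[match(all_ids, tmpl_src$snp_id), , drop = FALSE]

  w_sum <- bw_sum <- n_sum <- k <- setNames(numeric(length(all_ids)), all_ids)
  for (s in studies) {
    i <- match(s$snp_id, all_ids)
    w <- 1 / s$se^2
    w_sum[i] <- w_sum[i] + w
    bw_sum[i] <- bw_sum[i] + s$beta * w
    n_sum[i] <- n_sum[i] + s$n
    k[i] <- k[i] + 1L
  }
  beta <- bw_sum / w_sum
  se <- sqrt(1 / w_sum)
  out <- data.frame(
    snp_id = all_ids, chrom = tmpl$chrom, pos = tmpl$pos,
    effect_allele = tmpl$effect_allele, other_allele = tmpl$other_allele,
    eaf = tmpl$eaf, beta = beta, se = se, pval = z_to_p(beta / se),
    n = n_sum, n_cases = NA_real_, n_studies = as.integer(k),
    single_study = k == 1L, stringsAsFactors = FALSE
  )
  # single-study SNPs pass through untouched
  single <- out$single_study
  if (any(single)) {
    for (s in studies) {
      i <- match(s$snp_id[s$snp_id %in% out$snp_id[single]], out$snp_id)
      j <- match(out$snp_id[i], s$snp_id)
      out$beta[i] <- s$beta[j]; out$se[i] <- s$se[j]; out$pval[i] <- s$pval[j]
    }
  }
  rownames(out) <- NULL
  out
}
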