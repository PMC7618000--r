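# Variant qualification: QC, rarity, consequence class, TTN exon restriction.

#' Filtering thresholds for variant qualification
#'
#' Defaults mirror the cohort pipeline: genotyping call rate >= 90%,
#' QualByDepth >= 6, exact Hardy-Weinberg p >= 1e-6, popmax minor allele
#' frequency < 0.01% (1e-4), and for \emph{TTN} an exon inclusion proportion
#' (PSI) >= 0.90 in cardiac tissue. Edge conventions: QC thresholds pass on
#' equality (a call rate of exactly 0.90 passes), rarity is strict (an
#' allele frequency of exactly 1e-4 fails).
#'
#' @param maf_threshold Popmax allele-frequency cut-off, strict \code{<}.
#' @param min_call_rate Minimum genotyping call rate, passes on equality.
#' @param min_qual_by_depth Minimum QualByDepth, passes on equality.
#' @param hwe_p_floor Variants with exact HWE p below this are excluded.
#' @param ttn_psi_threshold Minimum exon inclusion proportion for TTN.
#' @param strict If \code{TRUE} (default) missing QC fields are an error;
#'   otherwise such variants pass QC and are counted in the filter log.
#' @return A list of class \code{"filter_config"}.
#' @export
filter_config <- function(maf_threshold = 1e-4,
                          min_call_rate = 0.90,
                          min_qual_by_depth = 6,
                          hwe_p_floor = 1e-6,
                          ttn_psi_threshold = 0.90,
                          strict = TRUE) {
  stopifnot(maf_threshold > 0, maf_threshold < 1,
            min_call_rate >= 0, min_call_rate <= 1,
            min_qual_by_depth >= 0,
            hwe_p_floor >= 0, hwe_p_floor <= 1,
            ttn_psi_threshold >= 0, ttn_psi_threshold <= 1,
            is.logical(strict))
  structure(list(maf_threshold = maf_threshold,
                 min_call_rate = min_call_rate,
                 min_qual_by_depth = min_qual_by_depth,
                 hwe_p_floor = hwe_p_floor,
                 ttn_psi_threshold = ttn_psi_threshold,
                 strict = strict),
            class = "filter_config")
}

#' Variant-level quality control
#'
#' A variant passes QC iff its call rate and QualByDepth meet their minima
#' (on equality) and the exact Hardy-Weinberg p-value computed from its
#' genotype counts is at least the floor.
#'
#' @param variants Data frame with columns \code{call_rate},
#'   \code{qual_by_depth}, \code{n_homref}, \code{n_het}, \code{n_homalt}.
#' @param cfg A \code{\link{filter_config}}.
#' @return Logical vector, one element per variant.
#' @export
passes_variant_qc <- function(variants, cfg = filter_config()) {
  qc_verdict(variants, cfg)$pass
}

qc_verdict <- function(variants, cfg) {
  n <- nrow(variants)
  cr <- variants$call_rate %||% rep(NA_real_, n)
  qd <- variants$qual_by_depth %||% rep(NA_real_, n)
  have_counts <- all(c("n_homref", "n_het", "n_homalt") %in% names(variants))
  incomplete <- is.na(cr) | is.na(qd) | !have_counts
  if (any(incomplete)) {
    if (isTRUE(cfg$strict)) {
      stop("missing QC fields on ", sum(incomplete),
           " variant(s); supply call_rate, qual_by_depth and genotype ",
           "counts, or set strict = FALSE")
    }
  }
  hwe_p <- rep(1, n)
  if (have_counts) {
    tot <- variants$n_homref + variants$n_het + variants$n_homalt
    idx <- which(!is.na(tot) & tot > 0)
    if (length(idx)) {
      hwe_p[idx] <- hwe_exact_test(variants$n_homref[idx],
                                   variants$n_het[idx],
                                   variants$n_homalt[idx])
    }
  }
  reason <- rep(NA_character_, n)
  reason[!is.na(hwe_p) & hwe_p < cfg$hwe_p_floor] <- "hwe_violation"
  reason[!is.na(qd) & qd < cfg$min_qual_by_depth] <- "low_qual_by_depth"
  reason[!is.na(cr) & cr < cfg$min_call_rate] <- "low_call_rate"
  list(pass = is.na(reason), reason = reason,
       n_missing_qc = sum(incomplete), hwe_p = hwe_p)
}

#' Population-frequency rarity filter
#'
#' A variant is rare iff its allele frequency is strictly below the threshold
#' in every reference population supplied, i.e. the popmax frequency is
#' \code{< threshold}. Populations in which the variant is absent (\code{NA})
#' contribute frequency 0; a variant with no frequency columns at all is
#' unobserved in the reference and counts as rare.
#'
#' @param afs Data frame or matrix of per-population allele frequencies
#'   (columns \code{af_<pop>}), or a numeric vector for a single variant.
#' @param threshold Strict upper bound on the popmax frequency.
#' @return Logical vector, one element per variant.
#' @export
passes_rarity_filter <- function(afs, threshold = 1e-4) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(dim(afs))) {
    if (length(afs) == 0) return(TRUE)
    return(max(c(afs, 0), na.rm = TRUE) < threshold)
  }
  afs <- as.matrix(afs)
  if (ncol(afs) == 0L || nrow(afs) == 0L) return(rep(TRUE, nrow(afs)))
  popmax <- apply(afs, 1L, function(x) max(c(x, 0), na.rm = TRUE))
  popmax < threshold
}

#' Constitutive-exon restriction for TTN truncating variants
#'
#' \emph{TTN} truncating variants only cause disease when they hit exons
#' constitutively included in the cardiac transcript, so a TTN variant
#' qualifies only if its exon inclusion proportion (PSI) is known and at
#' least the threshold. A TTN variant with missing PSI is conservatively
#' excluded.
#'
#' @param ttn_psi Numeric vector of exon inclusion proportions (\code{NA}
#'   when unknown).
#' @param cfg A \code{\link{filter_config}}.
#' @return Logical vector.
#' @export
passes_ttn_exon_filter <- function(ttn_psi, cfg = filter_config()) {
  !is.na(ttn_psi) & ttn_psi >= cfg$ttn_psi_threshold
}

#' Qualifying variants per gene
#'
#' Applies the full qualification cascade to every variant in a cohort: QC
#' (call rate, QualByDepth, exact HWE), popmax rarity, consequence-class
#' match against the gene's mechanism rule, and the constitutive-exon
#' restriction for genes that require it (TTN). Returns the per-gene sets of
#' qualifying variant keys, with an entry (possibly empty) for every rule
#' gene. Variants annotated to genes without a rule are ignored and counted.
#'
#' @param cohort A \code{\link{dcm_cohort}} (genotype counts for the HWE test
#'   are taken from its genotype matrix when not already present as columns).
#' @param rules Gene rules, see \code{\link{dcm_gene_rules}}.
#' @param cfg A \code{\link{filter_config}}.
#' @return Named list mapping each rule gene to a character vector of
#'   qualifying variant keys. Attributes: \code{"detail"}, a data frame with
#'   one row per variant (key, gene, class, qualifies, reason);
#'   \code{"n_unassigned"}, the count of variants in non-rule genes.
#' @export
qualifying_variants <- function(cohort, rules = dcm_gene_rules(),
                                cfg = filter_config()) {
  stopifnot(inherits(cohort, "dcm_cohort"))
  rules <- validate_gene_rules(rules)
  variants <- cohort$variants
  if (nrow(variants) > 0L &&
      !all(c("n_homref", "n_het", "n_homalt") %in% names(variants))) {
    variants <- cbind(variants, genotype_counts(cohort$genotypes))
  }
  detail <- qualify_variant_table(variants, rules, cfg)
  out <- lapply(stats::setNames(rules$gene, rules$gene), function(g) {
    detail$key[detail$qualifies & detail$gene == g]
  })
  attr(out, "detail") <- detail
  attr(out, "n_unassigned") <- sum(detail$reason == "no_rule_gene")
  out
}

# Core cascade on an annotation table that already carries genotype counts.
# Exclusion reasons are assigned in a fixed order: rule coverage, call rate,
# QualByDepth, HWE, popmax frequency, consequence class, TTN exon.
qualify_variant_table <- function(variants, rules, cfg) {
  n <- nrow(variants)
  cls <- character(n)
  for (i in seq_len(n)) cls[i] <- classify_consequence(variants$consequence_terms[i])
  reason <- rep("pass", n)

  has_rule <- variants$gene %in% rules$gene
  reason[!has_rule] <- "no_rule_gene"

  qc <- qc_verdict(variants, cfg)
  idx <- has_rule & !qc$pass
  reason[idx] <- qc$reason[idx]

  rare <- passes_rarity_filter(variants[af_columns(variants)],
                               cfg$maf_threshold)
  reason[reason == "pass" & !rare] <- "common_af"

  rule_class <- rules$qualifying_class[match(variants$gene, rules$gene)]
  cls_ok <- !is.na(rule_class) & class_matches_rule(cls, rule_class)
  reason[reason == "pass" & !cls_ok] <- "class_mismatch"

  needs_exon <- rules$requires_constitutive_exon[match(variants$gene, rules$gene)]
  psi <- variants$ttn_psi %||% rep(NA_real_, n)
  exon_ok <- !isTRUE_v(needs_exon) | passes_ttn_exon_filter(psi, cfg)
  reason[reason == "pass" & !exon_ok] <- "ttn_non_constitutive"

  data.frame(key = variants$key, gene = variants$gene, class = cls,
             qualifies = reason == "pass", reason = reason,
             stringsAsFactors = FALSE)
}

isTRUE_v <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a
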