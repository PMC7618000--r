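# Sex-stratified gene-based burden analysis: collapse, test, adjust.

#' Collapse qualifying variants to per-sample carrier flags
#'
#' A sample is a carrier iff it carries at least one alternate allele at at
#' least one qualifying variant; several qualifying variants still count as
#' one carrier. Missing genotypes count as non-carrier (post-QC missingness
#' is below 10% by construction, and case denominators stay fixed).
#'
#' @param genotypes Allele-count matrix (variants x samples).
#' @param qualifying Character vector of qualifying variant keys (row names).
#' @param samples Optional sample sheet; if supplied, every sample in it must
#'   be present in the genotype matrix.
#' @return Named logical vector over the genotype matrix's samples.
#' @export
carrier_flags <- function(genotypes, qualifying, samples = NULL) {
  if (!is.null(samples)) {
    miss <- setdiff(samples$sample_id, colnames(genotypes))
    if (length(miss)) {
      stop("samples absent from genotype matrix: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  bad <- setdiff(qualifying, rownames(genotypes))
  if (length(bad)) {
    stop("qualifying keys absent from genotype matrix: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  g <- genotypes[qualifying, , drop = FALSE]
  if (length(qualifying) == 0L) {
    return(stats::setNames(rep(FALSE, ncol(genotypes)), colnames(genotypes)))
  }
  colSums(g > 0, na.rm = TRUE) > 0
}

#' Minimum-carrier exclusion rule
#'
#' Genes with fewer than \code{min_carriers} carriers in the combined male
#' and female data are excluded from testing (too few carriers for a
#' meaningful sex comparison); the boundary is strict, so exactly
#' \code{min_carriers} carriers is tested.
#'
#' @param tables Named list of 2x2 carrier tables (see
#'   \code{\link{build_table}}).
#' @param min_carriers Minimum combined carrier count, default 5.
#' @return List with \code{tested} (named list of tables) and
#'   \code{excluded} (data frame of gene and reason).
#' @export
exclude_low_count <- function(tables, min_carriers = 5L) {
  stopifnot(min_carriers >= 1L)
  carriers <- vapply(tables, function(t) sum(t[, 1L]), numeric(1))
  keep <- carriers >= min_carriers
  excluded <- data.frame(
    gene = names(tables)[!keep],
    reason = sprintf("fewer than %d carriers (%d)", min_carriers,
                     as.integer(carriers[!keep])),
    stringsAsFactors = FALSE
  )
  list(tested = tables[keep], excluded = excluded)
}

#' Benjamini-Hochberg adjustment over the tested genes
#'
#' Standard step-up false-discovery-rate adjustment, with the family size
#' equal to the number of p-values supplied (i.e. tested genes only —
#' excluded genes contribute no p-value).
#'
#' @param pvals Named numeric vector of raw p-values in (0, 1].
#' @return Named vector of adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Sex-stratified rare-variant burden fit
#'
#' The main fitting function. For each gene rule: qualify variants (QC,
#' rarity, consequence class, TTN exon), collapse to carriers, build the
#' female/male by carrier/non-carrier table, drop genes with fewer than
#' \code{min_carriers} combined carriers, test the remainder with the exact
#' conditional test (\code{\link{fisher_exact}}), and adjust the two-sided
#' p-values with Benjamini-Hochberg over the tested genes. Odds ratios above
#' 1 indicate carrier enrichment in females.
#'
#' @param cohort A \code{\link{dcm_cohort}} of cases.
#' @param rules Gene rules (\code{\link{dcm_gene_rules}}).
#' @param config A \code{\link{filter_config}}.
#' @param subset Optional cohort restriction for sensitivity analyses: a
#'   predicate function on the sample sheet returning a logical vector, or a
#'   named list matched against sample-sheet columns (e.g.
#'   \code{list(ancestry = "European")}).
#' @param min_carriers Minimum combined carrier count for testing.
#' @return An object of class \code{"dcm_burden"}: a list with
#'   \code{results} (one row per gene: counts, \code{or_cmle},
#'   \code{or_sample}, CI, \code{p}, \code{p_fdr}, \code{tested},
#'   \code{exclusion_reason}), the per-gene \code{tables}, the qualification
#'   \code{detail}, and the fit settings.
#' @examples
#' fit <- dcm_burden(table1_cohort())
#' fit
#' coef(fit)
#' @export
dcm_burden <- function(cohort, rules = dcm_gene_rules(),
                       config = filter_config(), subset = NULL,
                       min_carriers = 5L) {
  stopifnot(inherits(cohort, "dcm_cohort"))
  rules <- validate_gene_rules(rules)

  keep <- subset_index(cohort$samples, subset)
  samples <- cohort$samples[keep, , drop = FALSE]
  if (sum(samples$sex == "female") < 1L || sum(samples$sex == "male") < 1L) {
    stop("need at least one sample of each sex after subsetting")
  }
  sub <- cohort
  sub$samples <- samples
  if (nrow(sub$variants) > 0L) {
    sub$genotypes <- cohort$genotypes[, samples$sample_id, drop = FALSE]
    # HWE genotype counts are recomputed on the analysed samples
    drop_cols <- intersect(c("n_homref", "n_het", "n_homalt"),
                           names(sub$variants))
    sub$variants <- sub$variants[setdiff(names(sub$variants), drop_cols)]
  }

  qual <- qualifying_variants(sub, rules, config)
  tables <- lapply(qual, function(keys) {
    build_table(carrier_flags(sub$genotypes, keys, samples), samples)
  })
  split <- exclude_low_count(tables, min_carriers)

  genes <- rules$gene
  res <- data.frame(
    gene = genes,
    qualifying_class = rules$qualifying_class,
    n_female = vapply(tables, function(t) t["female", "carrier"], numeric(1))[genes],
    n_male = vapply(tables, function(t) t["male", "carrier"], numeric(1))[genes],
    stringsAsFactors = FALSE
  )
  res$pct_female <- 100 * res$n_female / sum(samples$sex == "female")
  res$pct_male <- 100 * res$n_male / sum(samples$sex == "male")
  res$or_cmle <- NA_real_; res$or_sample <- NA_real_
  res$ci_lower <- NA_real_; res$ci_upper <- NA_real_
  res$p <- NA_real_; res$p_fdr <- NA_real_
  res$tested <- res$gene %in% names(split$tested)
  res$exclusion_reason <- NA_character_
  res$exclusion_reason[match(split$excluded$gene, res$gene)] <- split$excluded$reason

  for (g in names(split$tested)) {
    ft <- fisher_exact(split$tested[[g]])
    i <- match(g, res$gene)
    res$or_cmle[i] <- ft$or_cmle
    res$or_sample[i] <- sample_or(split$tested[[g]])
    res$ci_lower[i] <- ft$ci95[1L]
    res$ci_upper[i] <- ft$ci95[2L]
    res$p[i] <- ft$p
  }
  if (any(res$tested)) {
    res$p_fdr[res$tested] <- bh_adjust(stats::setNames(res$p[res$tested],
                                                       res$gene[res$tested]))
  }
  rownames(res) <- NULL

  structure(list(results = res, tables = tables,
                 detail = attr(qual, "detail"),
                 n_unassigned = attr(qual, "n_unassigned"),
                 n_female = sum(samples$sex == "female"),
                 n_male = sum(samples$sex == "male"),
                 config = config, rules = rules,
                 min_carriers = min_carriers),
            class = "dcm_burden")
}

subset_index <- function(samples, subset) {
  if (is.null(subset)) return(rep(TRUE, nrow(samples)))
  if (is.function(subset)) {
    keep <- subset(samples)
    stopifnot(is.logical(keep), length(keep) == nrow(samples))
    return(!is.na(keep) & keep)
  }
  if (is.list(subset)) {
    keep <- rep(TRUE, nrow(samples))
    for (col in names(subset)) {
      if (!col %in% names(samples)) stop("unknown sample-sheet column: ", col)
      keep <- keep & samples[[col]] %in% subset[[col]]
    }
    return(keep)
  }
  stop("subset must be NULL, a predicate function, or a named list")
}

#' @export
print.dcm_burden <- function(x, ...) {
  cat(sprintf("Sex-stratified rare-variant burden (%d female, %d male)\n\n",
              x$n_female, x$n_male))
  cat(format_table1(x), sep = "\n")
  invisible(x)
}

#' @export
summary.dcm_burden <- function(object, ...) {
  structure(list(fit = object), class = "summary.dcm_burden")
}

#' @export
print.summary.dcm_burden <- function(x, ...) {
  fit <- x$fit
  print(fit)
  d <- fit$detail
  if (!is.null(d) && nrow(d)) {
    cat("\nVariant qualification log:\n")
    tab <- table(d$reason)
    for (r in names(sort(tab, decreasing = TRUE))) {
      cat(sprintf("  %-22s %d\n", r, tab[[r]]))
    }
  }
  if (!is.null(fit$n_unassigned) && fit$n_unassigned > 0) {
    cat(sprintf("  (%d variant(s) in genes without a rule)\n",
                fit$n_unassigned))
  }
  invisible(x)
}

#' @export
coef.dcm_burden <- function(object, ...) {
  r <- object$results[object$results$tested, ]
  stats::setNames(r$or_cmle, r$gene)
}

#' Forest plot of per-gene odds ratios
#'
#' @param x A \code{\link{dcm_burden}} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.dcm_burden <- function(x, ...) {
  r <- x$results[x$results$tested, ]
  if (nrow(r) == 0L) stop("no tested genes to plot")
  idx <- rev(seq_len(nrow(r)))
  finite_hi <- r$ci_upper[is.finite(r$ci_upper)]
  xlim <- range(c(r$ci_lower[r$ci_lower > 0], finite_hi, 1))
  graphics::plot(r$or_cmle, idx, log = "x", xlim = xlim, yaxt = "n",
                 xlab = "odds ratio (female vs male carriers)", ylab = "",
                 pch = 19, ...)
  graphics::axis(2, at = idx, labels = r$gene, las = 1)
  graphics::segments(pmax(r$ci_lower, xlim[1]), idx,
                     pmin(r$ci_upper, xlim[2]), idx)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}
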