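# The cohort container: sample sheet + genotype matrix + variant annotations.

#' Assemble a cohort object
#'
#' Bundles the three inputs of the analysis: a pre-cleaned sample sheet, a
#' per-sample allele-count matrix, and a per-variant annotation table. Sample
#' level quality control (heterozygosity, chromosomal sex checks, relatedness
#' pruning) is deliberately NOT performed here: the sample sheet is assumed to
#' describe unrelated, QC-passing individuals already.
#'
#' @param samples Data frame with columns \code{sample_id} (unique),
#'   \code{sex} (\code{"female"}/\code{"male"}), \code{ancestry} and
#'   \code{status} (\code{"case"}/\code{"population"}).
#' @param genotypes Numeric matrix of alternate-allele counts (0, 1, 2, or
#'   \code{NA} for a missing call), variants in rows (rownames are variant
#'   keys \code{chrom:pos:ref:alt}), samples in columns (colnames are sample
#'   ids). Multi-allelic sites must be split to biallelic records upstream.
#' @param variants Data frame with one row per biallelic variant: columns
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt}, \code{gene},
#'   \code{consequence_terms} (comma-joined), per-population frequency
#'   columns named \code{af_<pop>}, and optionally \code{ttn_psi},
#'   \code{call_rate}, \code{qual_by_depth}.
#' @return An object of class \code{"dcm_cohort"}.
#' @export
dcm_cohort <- function(samples, genotypes, variants) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "sex", "status") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (!all(samples$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (!all(samples$status %in% c("case", "population"))) {
    stop("status must be 'case' or 'population'")
  }
  if (is.null(samples$ancestry)) samples$ancestry <- NA_character_

  variants <- validate_variant_table(variants)

  stopifnot(is.matrix(genotypes))
  if (nrow(genotypes) != nrow(variants)) {
    stop("genotype matrix rows must match the variant table")
  }
  if (nrow(genotypes) > 0L) {
    if (is.null(rownames(genotypes))) rownames(genotypes) <- variants$key
    if (!identical(rownames(genotypes), variants$key)) {
      stop("genotype rownames must equal the variant keys, in order")
    }
  }
  if (is.null(colnames(genotypes))) {
    stop("genotype matrix must carry sample ids as colnames")
  }
  missing_gt <- setdiff(samples$sample_id, colnames(genotypes))
  if (nrow(variants) > 0L && length(missing_gt) > 0L) {
    stop("samples absent from genotype matrix: ",
         paste(utils::head(missing_gt, 5L), collapse = ", "))
  }
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("genotypes must be allele counts 0/1/2 or NA")

  structure(list(samples = samples, genotypes = genotypes,
                 variants = variants),
            class = "dcm_cohort")
}

validate_variant_table <- function(variants) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence_terms")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(variants) > 0L) {
    stopifnot(all(variants$pos >= 1))
    af <- af_columns(variants)
    if (length(af)) {
      vals <- unlist(variants[af], use.names = FALSE)
      vals <- vals[!is.na(vals)]
      if (length(vals) && (any(vals < 0) || any(vals > 1))) {
        stop("allele frequencies must lie in [0, 1]")
      }
    }
  }
  if (is.null(variants$key)) {
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  if (anyDuplicated(variants$key)) stop("duplicate variant keys")
  variants
}

#' @export
print.dcm_cohort <- function(x, ...) {
  s <- x$samples
  cat("DCM analysis cohort\n")
  cat(sprintf("  samples:  %d (%d female, %d male; %d case, %d population)\n",
              nrow(s), sum(s$sex == "female"), sum(s$sex == "male"),
              sum(s$status == "case"), sum(s$status == "population")))
  cat(sprintf("  variants: %d across %d annotated genes\n",
              nrow(x$variants), length(unique(x$variants$gene))))
  invisible(x)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

af_columns <- function(variants) {
  grep("^af_", names(variants), value = TRUE)
}

# Per-variant genotype counts (hom-ref, het, hom-alt) over non-missing calls,
# restricted to the given sample ids.
genotype_counts <- function(genotypes, sample_ids = colnames(genotypes)) {
  g <- genotypes[, sample_ids, drop = FALSE]
  cbind(n_homref = rowSums(g == 0, na.rm = TRUE),
        n_het = rowSums(g == 1, na.rm = TRUE),
        n_homalt = rowSums(g == 2, na.rm = TRUE))
}
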