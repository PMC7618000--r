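# Plain-text I/O: VCF (v4.2, GT-only) plus tab-separated side tables.

#' Write a cohort to disk
#'
#' Writes \code{<prefix>.vcf} (VCFv4.2, GT-only FORMAT),
#' \code{<prefix>_samples.tsv} and \code{<prefix>_annotations.tsv} into
#' \code{dir}. The annotation table carries the consequence terms,
#' per-population frequencies and QC metrics; the VCF carries genotypes
#' only, keeping the two concerns separate.
#'
#' @param cohort A \code{\link{dcm_cohort}}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "dcm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             samples = file.path(dir, paste0(prefix, "_samples.tsv")),
             annotations = file.path(dir, paste0(prefix, "_annotations.tsv")))

  v <- cohort$variants
  g <- cohort$genotypes[, cohort$samples$sample_id, drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(v$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$samples$sample_id),
                    collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$key, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths["vcf"])

  keep <- setdiff(names(cohort$samples), c("carrier_gene", "disease"))
  utils::write.table(cohort$samples[keep], paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(v, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from a VCF and side tables
#'
#' Genotypes are parsed from the VCF with \pkg{vcfR} and joined to the
#' annotation table by variant key (\code{chrom:pos:ref:alt}); every VCF
#' record must be biallelic (split multi-allelics upstream).
#'
#' @param vcf,annotations,samples File paths as written by
#'   \code{\link{write_cohort}}.
#' @return A \code{\link{dcm_cohort}}.
#' @export
read_cohort <- function(vcf, annotations, samples) {
  sam <- utils::read.delim(samples, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character"))
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)

  x <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(x)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multi-allelic VCF records found; split to biallelic first")
  }
  gt <- vcfR::extract.gt(x, element = "GT")
  alt_count <- function(s) {
    a <- strsplit(s, "[/|]")[[1L]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  g <- matrix(vapply(gt, alt_count, numeric(1)), nrow = nrow(gt),
              dimnames = dimnames(gt))
  keys <- variant_key(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"])
  rownames(g) <- keys

  ann <- validate_variant_table(ann)
  m <- match(keys, ann$key)
  if (anyNA(m)) {
    stop(sum(is.na(m)), " VCF record(s) missing from the annotation table")
  }
  dcm_cohort(sam, g, ann[m, , drop = FALSE])
}

#' Write the bundled fixtures to disk
#'
#' Materialises the cohort fixture (under \code{dir/table1/}) and the
#' population-validation fixture (under \code{dir/ukb/}) as VCF + TSV files,
#' together with the variant manifest, the expected carrier counts, and an
#' expected burden report computed from the manifest counts.
#'
#' @param dir Output directory.
#' @return Invisibly, a list of written paths by fixture.
#' @export
write_fixture_table1 <- function(dir) {
  t1 <- table1_cohort()
  man <- attr(t1, "manifest")
  p1 <- write_cohort(t1, file.path(dir, "table1"), "table1")
  utils::write.table(man$variants,
                     file.path(dir, "table1", "variant_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(man$counts,
                     file.path(dir, "table1", "expected_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- dcm_burden(t1)
  utils::write.table(burden_report(fit),
                     file.path(dir, "table1", "expected_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ukb <- ukb_cohort()
  p2 <- write_cohort(ukb, file.path(dir, "ukb"), "ukb")
  invisible(list(table1 = p1, ukb = p2))
}

#' Load a run configuration
#'
#' Plain-text (YAML) configuration covering input paths, filter thresholds,
#' gene rules and prevalence settings; see \code{\link{run_pipeline}}.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}
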