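# End-to-end orchestration and report formatting.

#' Half-up rounding
#'
#' Rounds halves away from zero at the given number of decimals (the
#' convention used for the printed odds ratios), unlike \code{round()}'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

fmt_or <- function(x) {
  ifelse(is.finite(x), sprintf("%.2f", round_half_up(x, 2)), "Inf")
}

#' Human-readable burden table
#'
#' Formats a \code{\link{dcm_burden}} fit the way the cohort table is
#' printed: per-gene carrier counts and percentages by sex, the conditional
#' MLE odds ratio with its exact 95% interval to two decimals (half-up), and
#' the FDR-adjusted p to two significant figures. An infinite upper bound
#' renders as an open interval. Excluded genes are listed beneath with their
#' reasons.
#'
#' @param fit A \code{\link{dcm_burden}} object.
#' @return Character vector of report lines.
#' @export
format_table1 <- function(fit) {
  stopifnot(inherits(fit, "dcm_burden"))
  r <- fit$results
  if (nrow(r) == 0L) stop("empty result set")
  tested <- r[r$tested, , drop = FALSE]
  lines <- sprintf("%-7s %-8s %4s %6s %4s %6s  %-22s %-10s %s",
                   "Gene", "class", "N_f", "%_f", "N_m", "%_m",
                   "OR [95% CI]", "p", "p_FDR")
  for (i in seq_len(nrow(tested))) {
    x <- tested[i, ]
    ci <- sprintf("%s [%s - %s%s", fmt_or(x$or_cmle), fmt_or(x$ci_lower),
                  fmt_or(x$ci_upper), ifelse(is.finite(x$ci_upper), "]", ")"))
    lines <- c(lines, sprintf("%-7s %-8s %4d %6.2f %4d %6.2f  %-22s %-10s %s",
                              x$gene, x$qualifying_class,
                              as.integer(x$n_female), x$pct_female,
                              as.integer(x$n_male), x$pct_male, ci,
                              format(signif(x$p, 2)),
                              format(signif(x$p_fdr, 2))))
  }
  excl <- r[!r$tested, , drop = FALSE]
  if (nrow(excl)) {
    lines <- c(lines, "", "Excluded genes:")
    lines <- c(lines, sprintf("  %-7s %s", excl$gene, excl$exclusion_reason))
  }
  lines
}

# Machine-readable burden report (both odds-ratio estimators).
burden_report <- function(fit) {
  r <- fit$results
  num <- vapply(r, is.numeric, logical(1))
  r[num] <- lapply(r[num], function(x) ifelse(is.na(x), NA, signif(x, 10)))
  r
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates filter, burden and (optionally) penetrance stages and writes
#' the reports: \code{qualifying_variants.tsv} (per-variant verdicts and
#' reasons), \code{burden_report.tsv} (machine-readable, both odds-ratio
#' estimators), \code{burden_table.txt} (the human-readable table),
#' \code{penetrance.tsv} when counts are configured, and
#' \code{run_manifest.json} recording thresholds, seed and input checksums
#' so a rerun with an unchanged manifest is byte-identical.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   entries: \code{inputs} (\code{vcf}/\code{annotations}/\code{samples}
#'   paths, or \code{fixture: table1} / \code{fixture: ukb}),
#'   optional \code{filter} (arguments of \code{\link{filter_config}}),
#'   optional \code{rules} (path to a TSV with gene/qualifying_class
#'   columns), optional \code{subset} (named list matched against the
#'   sample sheet), optional \code{min_carriers}, optional
#'   \code{penetrance} (\code{case_counts}/\code{pop_counts} TSV paths with
#'   columns gene, stratum, carriers, n; \code{prevalence} scalar or by
#'   stratum; \code{draws}), and \code{seed}.
#' @param out_dir Output directory (overrides \code{config$out_dir}).
#' @return Invisibly, a list with the fit, optional penetrance table and
#'   written paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- config$inputs %||% stop("config lacks 'inputs'")
  checksums <- NULL
  if (!is.null(inputs$fixture)) {
    cohort <- switch(inputs$fixture,
                     table1 = table1_cohort(),
                     ukb = ukb_cohort(),
                     stop("unknown fixture: ", inputs$fixture))
  } else {
    for (f in c("vcf", "annotations", "samples")) {
      if (is.null(inputs[[f]])) stop("inputs lacks '", f, "'")
      if (!file.exists(inputs[[f]])) stop("missing input file: ", inputs[[f]])
    }
    cohort <- read_cohort(inputs$vcf, inputs$annotations, inputs$samples)
    checksums <- as.list(tools::md5sum(unlist(inputs[c("vcf", "annotations",
                                                       "samples")])))
  }

  cfg <- do.call(filter_config, config$filter %||% list())
  rules <- if (is.null(config$rules)) {
    dcm_gene_rules()
  } else if (is.character(config$rules)) {
    validate_gene_rules(utils::read.delim(config$rules,
                                          stringsAsFactors = FALSE))
  } else {
    validate_gene_rules(as.data.frame(config$rules))
  }

  fit <- dcm_burden(cohort, rules = rules, config = cfg,
                    subset = config$subset,
                    min_carriers = config$min_carriers %||% 5L)

  paths <- c(qualifying = file.path(out_dir, "qualifying_variants.tsv"),
             report = file.path(out_dir, "burden_report.tsv"),
             table = file.path(out_dir, "burden_table.txt"),
             manifest = file.path(out_dir, "run_manifest.json"))
  utils::write.table(fit$detail, paths["qualifying"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(burden_report(fit), paths["report"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(format_table1(fit), paths["table"])

  pen <- NULL
  if (!is.null(config$penetrance)) {
    pc <- config$penetrance
    pen <- penetrance_from_counts(
      utils::read.delim(pc$case_counts, stringsAsFactors = FALSE),
      utils::read.delim(pc$pop_counts, stringsAsFactors = FALSE),
      prevalence = pc$prevalence,
      n_draws = pc$draws %||% 1e5,
      seed = config$seed %||% 20250423L)
    paths["penetrance"] <- file.path(out_dir, "penetrance.tsv")
    utils::write.table(as.data.frame(pen), paths["penetrance"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcmburden")),
    inputs = inputs, input_md5 = checksums,
    filter = unclass(cfg), rules = rules,
    subset = config$subset, min_carriers = config$min_carriers %||% 5L,
    seed = config$seed %||% NA)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(fit = fit, penetrance = pen, paths = paths))
}

#' Penetrance estimates from count tables
#'
#' Convenience wrapper running \code{\link{sex_stratified_penetrance}} for
#' every gene present in both count tables.
#'
#' @param case_counts,pop_counts Data frames with columns \code{gene},
#'   \code{stratum} (\code{all}/\code{female}/\code{male}),
#'   \code{carriers}, \code{n}.
#' @param prevalence Scalar, or named list/vector by stratum.
#' @inheritParams estimate_penetrance
#' @return A \code{"penetrance_estimate"} data frame.
#' @export
penetrance_from_counts <- function(case_counts, pop_counts, prevalence,
                                   n_draws = 1e5, seed = 20250423L) {
  split_counts <- function(df, g) {
    rows <- df[df$gene == g, ]
    stats::setNames(lapply(seq_len(nrow(rows)),
                           function(i) c(rows$carriers[i], rows$n[i])),
                    rows$stratum)
  }
  genes <- intersect(unique(case_counts$gene), unique(pop_counts$gene))
  if (length(genes) == 0L) stop("no gene present in both count tables")
  out <- do.call(rbind, lapply(seq_along(genes), function(i) {
    sex_stratified_penetrance(genes[i],
                              split_counts(case_counts, genes[i]),
                              split_counts(pop_counts, genes[i]),
                              prevalence = prevalence, n_draws = n_draws,
                              seed = as.integer(seed) + 7919L * (i - 1L))
  }))
  class(out) <- c("penetrance_estimate", "data.frame")
  out
}
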