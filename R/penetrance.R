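# Cross-sectional penetrance: prevalence * (case frequency / population
# frequency), with Monte-Carlo interval propagation.

#' Cross-sectional penetrance of qualifying variants
#'
#' Bayes' rule gives the probability of disease given a qualifying genotype
#' as
#' \deqn{P(D \mid G) = P(G \mid D)\, P(D) / P(G),}
#' estimated as \code{prevalence * f_case / f_pop} from the carrier
#' frequency among diagnosed cases (\code{f_case}) and in the reference
#' population (\code{f_pop}), clamped to [0, 1]. For variants this rare,
#' counting carriers or alleles is equivalent (the factor of two cancels in
#' the ratio); set \code{allele_counts = TRUE} if the supplied counts are
#' allele counts over \code{2n} chromosomes.
#'
#' The confidence interval propagates counting uncertainty by Monte Carlo:
#' both frequencies are drawn from Jeffreys Beta posteriors
#' (\code{carriers + 1/2}, \code{n - carriers + 1/2}), the clamped ratio is
#' formed per draw, and the 2.5/97.5 percentiles are reported. Prevalence is
#' treated as fixed unless \code{prevalence_ci} is supplied, in which case it
#' is drawn log-normally with that 95% range. Identical seeds give
#' bit-identical intervals.
#'
#' @param case_carriers,case_n Carrier count and sample size among cases.
#' @param pop_carriers,pop_n Carrier count and sample size in the population.
#' @param prevalence Disease prevalence in the corresponding stratum; there
#'   is no universal default on purpose — supply the value appropriate to
#'   your population.
#' @param prevalence_ci Optional length-2 vector, a 95% interval for the
#'   prevalence, propagated log-normally.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed for the draws.
#' @param allele_counts Counts are alleles over 2n chromosomes, not carriers.
#' @param gene,stratum Labels carried through to the result.
#' @return Object of class \code{"penetrance_estimate"}: a one-row data
#'   frame with \code{point}, \code{ci_lower}, \code{ci_upper},
#'   \code{prevalence_used}, \code{n_clamped} (draws clamped at 1),
#'   \code{n_draws} and \code{seed}.
#' @examples
#' estimate_penetrance(20, 1000, 5, 10000, prevalence = 0.001)
#' @export
estimate_penetrance <- function(case_carriers, case_n, pop_carriers, pop_n,
                                prevalence, prevalence_ci = NULL,
                                n_draws = 1e5, seed = 20250423,
                                allele_counts = FALSE,
                                gene = NA_character_, stratum = "all") {
  stopifnot(case_carriers >= 0, case_n > 0, case_carriers <= case_n,
            pop_carriers >= 0, pop_n > 0, pop_carriers <= pop_n,
            n_draws >= 100)
  if (pop_carriers == 0) {
    stop("no carriers in the population sample: penetrance ratio undefined")
  }
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must lie strictly between 0 and 1")
  }
  denom <- if (allele_counts) 2 else 1
  f_case <- case_carriers / (denom * case_n)
  f_pop <- pop_carriers / (denom * pop_n)
  point <- min(1, prevalence * f_case / f_pop)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fc <- stats::rbeta(n_draws, case_carriers + 0.5,
                     denom * case_n - case_carriers + 0.5)
  fp <- stats::rbeta(n_draws, pop_carriers + 0.5,
                     denom * pop_n - pop_carriers + 0.5)
  prev <- if (is.null(prevalence_ci)) {
    prevalence
  } else {
    stopifnot(length(prevalence_ci) == 2L, prevalence_ci[1] > 0,
              prevalence_ci[1] <= prevalence_ci[2])
    stats::rlnorm(n_draws, log(prevalence),
                  (log(prevalence_ci[2]) - log(prevalence_ci[1])) / (2 * 1.959964))
  }
  draws <- prev * fc / fp
  n_clamped <- sum(draws > 1)
  draws <- pmin(draws, 1)
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  # keep the interval bracketing the point estimate at the boundaries
  # (e.g. zero case carriers: point 0, upper bound from the posterior)
  ci <- c(min(ci[1], point), max(ci[2], point))

  out <- data.frame(gene = gene, stratum = stratum, point = point,
                    ci_lower = ci[1], ci_upper = ci[2],
                    prevalence_used = prevalence, n_clamped = n_clamped,
                    n_draws = n_draws, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("penetrance_estimate", "data.frame")
  out
}

#' Sex-stratified penetrance estimates for one gene
#'
#' Runs \code{\link{estimate_penetrance}} for the overall, female and male
#' strata, each with its own counts and prevalence. Per-stratum seeds are
#' derived deterministically from \code{seed} so the three intervals are
#' independent yet reproducible.
#'
#' @param gene Gene label.
#' @param case_counts,pop_counts Named lists with entries \code{all},
#'   \code{female}, \code{male}, each a vector \code{c(carriers, n)}.
#'   Strata absent from either list are skipped.
#' @param prevalence Single value or named vector/list by stratum.
#' @inheritParams estimate_penetrance
#' @return A data frame of class \code{"penetrance_estimate"} with one row
#'   per stratum.
#' @export
sex_stratified_penetrance <- function(gene, case_counts, pop_counts,
                                      prevalence, n_draws = 1e5,
                                      seed = 20250423,
                                      allele_counts = FALSE) {
  strata <- intersect(c("all", "female", "male"),
                      intersect(names(case_counts), names(pop_counts)))
  if (length(strata) == 0L) stop("no stratum present in both count lists")
  rows <- lapply(seq_along(strata), function(i) {
    s <- strata[i]
    prev <- if (!is.null(names(prevalence))) {
      if (!s %in% names(prevalence)) {
        stop("prevalence must name stratum '", s, "'")
      }
      prevalence[[s]]
    } else {
      if (length(prevalence) != 1L) stop("unnamed prevalence must be scalar")
      as.numeric(prevalence)
    }
    estimate_penetrance(case_counts[[s]][1], case_counts[[s]][2],
                        pop_counts[[s]][1], pop_counts[[s]][2],
                        prevalence = prev, n_draws = n_draws,
                        seed = as.integer(seed) + (i - 1L) * 1009L,
                        allele_counts = allele_counts,
                        gene = gene, stratum = s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("penetrance_estimate", "data.frame")
  out
}

#' @export
print.penetrance_estimate <- function(x, ...) {
  cat("Cross-sectional penetrance estimates\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s %-7s %s\n",
                ifelse(is.na(x$gene[i]), "", x$gene[i]), x$stratum[i],
                sprintf("%.2f [%.2f - %.2f]", x$point[i],
                        x$ci_lower[i], x$ci_upper[i])))
  }
  invisible(x)
}
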