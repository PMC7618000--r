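# Replicated simulation studies: null calibration of the burden test and
# parameter recovery of the penetrance estimator.

#' Null-model parameters calibrated to cohort-like carrier counts
#'
#' Builds equal-penetrance (no sex effect) simulation parameters whose
#' expected case-carrier fractions match the supplied per-gene fractions, by
#' inverting \eqn{f = qp / (qp + (1-q)b)} for the carrier frequency
#' \eqn{q}. Defaults reproduce the cohort's combined carrier counts at
#' 830 cases.
#'
#' @param case_fractions Named vector of per-gene carrier fractions among
#'   cases; defaults to the cohort counts over 830.
#' @param penetrance Common penetrance for both sexes.
#' @param background_risk Disease risk in non-carriers.
#' @param seed Seed stored with the parameters.
#' @return A \code{\link{simulation_params}} object.
#' @export
null_simulation_params <- function(case_fractions = NULL, penetrance = 0.10,
                                   background_risk = 0.0028,
                                   seed = 20250423L) {
  if (is.null(case_fractions)) {
    case_fractions <- stats::setNames(
      (.TABLE1_COUNTS$female + .TABLE1_COUNTS$male) / 830,
      .TABLE1_COUNTS$gene)
  }
  f <- case_fractions; p <- penetrance; b <- background_risk
  q <- f * b / (p * (1 - f) + f * b)
  rules <- dcm_gene_rules()
  genes <- data.frame(gene = names(f), carrier_freq = unname(q),
                      penetrance_female = p, penetrance_male = p,
                      qualifying_class = rules$qualifying_class[
                        match(names(f), rules$gene)],
                      decoy_fraction = 0, stringsAsFactors = FALSE)
  simulation_params(genes = genes, background_risk = b, seed = seed)
}

#' Type-I error of the burden test under the null
#'
#' Simulates case cohorts in which male and female penetrance are equal for
#' every gene, runs the full burden pipeline on each replicate, and reports
#' the fraction of tested gene-level p-values below \code{alpha}, together
#' with the two-sided 99% binomial band around \code{alpha} for that many
#' tests. The exact conditional test is discrete and therefore conservative,
#' so fractions at or below the nominal level are the expected behaviour.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_female,n_male Cases per sex in each replicate.
#' @param alpha Nominal level.
#' @param params Null-model parameters
#'   (\code{\link{null_simulation_params}}).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return List with \code{fraction}, \code{n_tests}, \code{bounds} (99%
#'   binomial band around alpha), \code{n_fdr_hits} (gene hits at
#'   FDR < 0.01 across replicates), and the per-replicate p-value matrix.
#' @export
null_calibration_study <- function(n_reps = 500L, n_female = 274L,
                                   n_male = 556L, alpha = 0.05,
                                   params = null_simulation_params(),
                                   seed = 1L) {
  seed <- as.integer(seed)
  pvals <- vector("list", n_reps)
  fdr_hits <- 0L
  for (r in seq_len(n_reps)) {
    cohort <- simulate_case_cohort(params, n_female, n_male,
                                   seed = (seed + 7919L * r) %% 2147483647L,
                                   decoys = FALSE)
    fit <- dcm_burden(cohort)
    res <- fit$results
    pvals[[r]] <- stats::setNames(res$p, res$gene)
    fdr_hits <- fdr_hits + sum(res$p_fdr < 0.01, na.rm = TRUE)
  }
  pmat <- do.call(rbind, pvals)
  obs <- pmat[!is.na(pmat)]
  n_tests <- length(obs)
  frac <- mean(obs < alpha)
  bounds <- stats::qbinom(c(0.005, 0.995), n_tests, alpha) / n_tests
  list(fraction = frac, n_tests = n_tests, bounds = bounds,
       n_fdr_hits = fdr_hits, pvals = pmat)
}

#' Parameter recovery of the penetrance estimator
#'
#' Simulates replicate frequency observations from the generative model —
#' case carriers binomial at the analytic case-carrier probability, and
#' population carriers binomial at the carrier frequency — at cohort-like
#' case sizes and population-biobank denominators, runs
#' \code{\link{estimate_penetrance}} on each with the model's true
#' sex-specific prevalence, and summarises coverage of the 95% interval and
#' the median relative bias of the point estimate against the true
#' penetrance.
#'
#' @param n_reps Number of replicates.
#' @param genes Genes (from \code{params}) to recover; defaults to the two
#'   with sex-asymmetric penetrance.
#' @param params Generative parameters (\code{\link{simulation_params}}).
#' @param n_case_female,n_case_male Case sample sizes.
#' @param n_pop_female,n_pop_male Population denominators (biobank scale).
#' @param n_draws Monte-Carlo draws per interval.
#' @param seed Integer seed.
#' @return List with \code{summary} (per gene x sex: truth, coverage,
#'   median point, median relative bias) and the replicate-level estimates.
#' @export
penetrance_recovery_study <- function(n_reps = 500L, genes = c("DSP", "TTN"),
                                      params = simulation_params(),
                                      n_case_female = 274L,
                                      n_case_male = 556L,
                                      n_pop_female = 91751L,
                                      n_pop_male = 75727L,
                                      n_draws = 4000L, seed = 1L) {
  seed <- as.integer(seed)
  probs <- case_carrier_probs(params)
  g <- params$genes
  cells <- expand.grid(gene = genes, sex = c("female", "male"),
                       stringsAsFactors = FALSE)
  set.seed(seed)
  est <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    gene <- cells$gene[i]; sex <- cells$sex[i]
    gi <- match(gene, g$gene)
    truth <- if (sex == "female") g$penetrance_female[gi] else g$penetrance_male[gi]
    n_case <- if (sex == "female") n_case_female else n_case_male
    n_pop <- if (sex == "female") n_pop_female else n_pop_male
    cc <- stats::rbinom(n_reps, n_case, probs$p_carrier[gene, sex])
    pc <- stats::rbinom(n_reps, n_pop, g$carrier_freq[gi])
    rows <- lapply(seq_len(n_reps), function(r) {
      if (pc[r] == 0) return(NULL)  # undefined ratio, dropped and counted
      e <- estimate_penetrance(cc[r], n_case, pc[r], n_pop,
                               prevalence = probs$prevalence[[sex]],
                               n_draws = n_draws,
                               seed = (seed + 7919L * r + 101L * i) %% 2147483647L,
                               gene = gene, stratum = sex)
      cbind(e, rep = r, truth = truth)
    })
    est[[i]] <- do.call(rbind, rows)
  }
  est <- do.call(rbind, est)
  agg <- do.call(rbind, lapply(split(est, list(est$gene, est$stratum), drop = TRUE),
    function(d) data.frame(
      gene = d$gene[1], sex = d$stratum[1], truth = d$truth[1],
      n_reps = nrow(d),
      coverage = mean(d$ci_lower <= d$truth & d$truth <= d$ci_upper),
      median_point = stats::median(d$point),
      median_rel_bias = (stats::median(d$point) - d$truth[1]) / d$truth[1],
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(summary = agg, estimates = est)
}
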