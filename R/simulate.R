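# Synthetic cohorts with known carrier frequencies and sex-specific
# penetrance, for validating the whole pipeline without patient data.

# Real chromosome assignments for the twelve genes (placeholder positions).
.GENE_LOCI <- data.frame(
  gene = c("TTN", "FLNC", "BAG3", "DES", "MYH7", "TNNC1", "TNNT2",
           "DSP", "LMNA", "RBM20", "SCN5A", "PLN", "MYBPC3"),
  chrom = c("2", "7", "10", "2", "14", "3", "1",
            "6", "1", "10", "3", "6", "11"),
  base = c(178500000, 128800000, 119600000, 219400000, 23400000, 52400000,
           201300000, 7540000, 156100000, 110500000, 38500000, 118548000,
           47330000),
  stringsAsFactors = FALSE
)

#' Parameters of the generative cohort model
#'
#' The generator assumes: each individual carries qualifying variants in at
#' most one gene (probability \code{carrier_freq} per gene, so per-gene
#' expectations stay analytic); disease arises with the sex-specific
#' penetrance of the carried gene, or with \code{background_risk} in
#' non-carriers. Defaults describe the study conditions: the background risk
#' is the population DCM prevalence of 0.28%, the per-gene carrier
#' frequencies are round values in the rare-variant regime that reproduce
#' cohort-like carrier counts at 274 female / 556 male cases, and the
#' penetrances of DSP (0.11 female / 0.02 male) and TTN (0.06 / 0.18) carry
#' the sex asymmetry under study while the remaining genes are sex-neutral.
#'
#' @param genes Data frame with columns \code{gene}, \code{carrier_freq},
#'   \code{penetrance_female}, \code{penetrance_male},
#'   \code{qualifying_class}, \code{decoy_fraction}; defaults to the twelve
#'   definitive DCM genes.
#' @param n_pop Population size for \code{\link{simulate_population}}.
#' @param sex_ratio_female Probability an individual is female.
#' @param background_risk Disease probability in non-carriers.
#' @param seed Integer seed recorded with the parameters.
#' @return List of class \code{"simulation_params"}.
#' @export
simulation_params <- function(genes = default_gene_params(),
                              n_pop = 20000L,
                              sex_ratio_female = 0.5,
                              background_risk = 0.0028,
                              seed = 20250423L) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "carrier_freq", "penetrance_female",
                  "penetrance_male", "qualifying_class") %in% names(genes)))
  if (is.null(genes$decoy_fraction)) genes$decoy_fraction <- 0.3
  p <- unlist(genes[c("carrier_freq", "penetrance_female",
                      "penetrance_male", "decoy_fraction")])
  stopifnot(all(p >= 0), all(p <= 1),
            sex_ratio_female >= 0, sex_ratio_female <= 1,
            background_risk >= 0, background_risk <= 1)
  if (any(genes$carrier_freq > 0.01)) {
    stop("carrier frequencies above 1% leave the rare-variant regime")
  }
  structure(list(genes = genes, n_pop = as.integer(n_pop),
                 sex_ratio_female = sex_ratio_female,
                 background_risk = background_risk,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' @rdname simulation_params
#' @export
default_gene_params <- function() {
  g <- data.frame(
    gene = c("TTN", "FLNC", "BAG3", "DES", "MYH7", "TNNC1", "TNNT2",
             "DSP", "LMNA", "RBM20", "SCN5A", "PLN"),
    carrier_freq = c(3e-3, 1e-4, 5e-5, 1.5e-4, 4e-4, 2e-5, 5e-5,
                     5e-4, 2.5e-4, 2e-4, 2.5e-4, 4e-5),
    penetrance_female = c(0.06, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                          0.11, 0.05, 0.05, 0.05, 0.05),
    penetrance_male = c(0.18, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                        0.02, 0.05, 0.05, 0.05, 0.05),
    stringsAsFactors = FALSE
  )
  g$qualifying_class <- dcm_gene_rules()$qualifying_class[
    match(g$gene, dcm_gene_rules()$gene)]
  g$decoy_fraction <- 0.3
  g
}

#' Analytic case-carrier probabilities implied by the model
#'
#' Under the generative model, the probability that a case of a given sex
#' carries a qualifying variant in gene \eqn{g} is
#' \deqn{P(G_g \mid D, s) = \frac{q_g\, \pi_{g,s}}{\sum_h q_h \pi_{h,s} + (1 - \sum_h q_h)\, b},}
#' where \eqn{q} are carrier frequencies, \eqn{\pi} sex-specific penetrances
#' and \eqn{b} the background risk. The denominator is the sex-specific
#' disease prevalence.
#'
#' @param params A \code{\link{simulation_params}}.
#' @return List with \code{prevalence} (named by sex) and \code{p_carrier}
#'   (gene x sex matrix of conditional carrier probabilities).
#' @export
case_carrier_probs <- function(params) {
  g <- params$genes
  qtot <- sum(g$carrier_freq)
  stopifnot(qtot <= 1)
  prev <- c(
    female = sum(g$carrier_freq * g$penetrance_female) +
      (1 - qtot) * params$background_risk,
    male = sum(g$carrier_freq * g$penetrance_male) +
      (1 - qtot) * params$background_risk
  )
  pc <- cbind(female = g$carrier_freq * g$penetrance_female / prev["female"],
              male = g$carrier_freq * g$penetrance_male / prev["male"])
  rownames(pc) <- g$gene
  list(prevalence = prev, p_carrier = pc)
}

#' Simulate a population
#'
#' Draws sex, per-gene carrier status (at most one gene per individual) and
#' disease status for \code{n_pop} individuals, then materialises concrete
#' variant records: every carrier receives a private heterozygous qualifying
#' variant, and decoy variants with failing annotations (common frequency,
#' synonymous consequence, low QualByDepth, low call rate, HWE-violating
#' genotypes, non-constitutive or unannotated TTN exons, wrong class,
#' unlisted gene) are interleaved. Reproducible given the seed.
#'
#' @param params A \code{\link{simulation_params}}.
#' @param genotypes \code{"dense"} to build the genotype matrix,
#'   \code{"none"} to skip it for large populations where only the sample
#'   sheet is needed.
#' @return A \code{\link{dcm_cohort}} whose sample sheet carries the truth
#'   columns \code{carrier_gene} and \code{disease} (status is
#'   \code{"case"} for diseased individuals, \code{"population"} otherwise),
#'   with attribute \code{"manifest"} describing every simulated variant.
#' @export
simulate_population <- function(params, genotypes = c("dense", "none")) {
  stopifnot(inherits(params, "simulation_params"))
  genotypes <- match.arg(genotypes)
  set.seed(params$seed)
  n <- params$n_pop
  g <- params$genes

  sex <- ifelse(stats::runif(n) < params$sex_ratio_female, "female", "male")
  assign <- sample(c(g$gene, "none"), n, replace = TRUE,
                   prob = c(g$carrier_freq, 1 - sum(g$carrier_freq)))
  pen <- ifelse(assign == "none", params$background_risk,
                ifelse(sex == "female",
                       g$penetrance_female[match(assign, g$gene)],
                       g$penetrance_male[match(assign, g$gene)]))
  disease <- stats::runif(n) < pen
  if (sum(g$carrier_freq) > 0) {
    expected_cases <- n * mean(c(case_carrier_probs(params)$prevalence))
    if (expected_cases < 10) {
      warning("parameters imply fewer than 10 expected cases")
    }
  }
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    sex = sex,
    ancestry = "European",
    status = ifelse(disease, "case", "population"),
    carrier_gene = assign,
    disease = disease,
    stringsAsFactors = FALSE
  )
  if (genotypes == "none") {
    out <- structure(list(samples = samples, genotypes = NULL,
                          variants = NULL),
                     class = "dcm_cohort")
    attr(out, "manifest") <- list(params = params)
    return(out)
  }
  materialise_cohort(samples, params)
}

#' Ascertain a case cohort from a simulated population
#'
#' Random sample, without replacement, of diseased individuals at the
#' requested sex split (mirroring clinical recruitment of diagnosed cases).
#'
#' @param population Result of \code{\link{simulate_population}}.
#' @param n_female,n_male Requested case counts per sex.
#' @param seed Integer seed.
#' @return A \code{\link{dcm_cohort}} of cases.
#' @export
ascertain_cases <- function(population, n_female, n_male, seed = 1L) {
  s <- population$samples
  set.seed(as.integer(seed))
  pick <- function(sx, k) {
    pool <- which(s$disease & s$sex == sx)
    if (length(pool) < k) {
      stop("insufficient simulated ", sx, " cases: have ", length(pool),
           ", need ", k)
    }
    sample(pool, k)
  }
  idx <- sort(c(pick("female", n_female), pick("male", n_male)))
  samples <- s[idx, , drop = FALSE]
  samples$status <- "case"
  rownames(samples) <- NULL
  if (is.null(population$genotypes)) {
    stop("population was simulated without genotypes")
  }
  out <- structure(list(
    samples = samples,
    genotypes = population$genotypes[, samples$sample_id, drop = FALSE],
    variants = population$variants), class = "dcm_cohort")
  attr(out, "manifest") <- attr(population, "manifest")
  out
}

#' Simulate a case cohort directly
#'
#' Draws a diagnosed cohort of the requested size by sampling each case's
#' carried gene from the analytic conditional distribution
#' \code{\link{case_carrier_probs}} — statistically identical to simulating
#' a large population and ascertaining cases, since individuals are
#' independent — then materialises variant records exactly as
#' \code{\link{simulate_population}} does. This is the scalable route used
#' by the replicated calibration and recovery studies.
#'
#' @inheritParams ascertain_cases
#' @param params A \code{\link{simulation_params}}.
#' @param decoys Materialise decoy variants as well.
#' @return A \code{\link{dcm_cohort}} of cases.
#' @export
simulate_case_cohort <- function(params, n_female = 274L, n_male = 556L,
                                 seed = 1L, decoys = TRUE) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(as.integer(seed))
  probs <- case_carrier_probs(params)
  g <- params$genes
  draw <- function(sx, k) {
    p <- probs$p_carrier[, sx]
    sample(c(g$gene, "none"), k, replace = TRUE, prob = c(p, 1 - sum(p)))
  }
  samples <- data.frame(
    sample_id = sprintf("C%05d", seq_len(n_female + n_male)),
    sex = c(rep("female", n_female), rep("male", n_male)),
    ancestry = "European",
    status = "case",
    carrier_gene = c(draw("female", n_female), draw("male", n_male)),
    disease = TRUE,
    stringsAsFactors = FALSE
  )
  p2 <- params
  if (!decoys) p2$genes$decoy_fraction <- 0
  materialise_cohort(samples, p2)
}

# Turn a truth-labelled sample sheet into a concrete cohort: private
# heterozygous qualifying variants for carriers, plus decoys. Assumes the
# RNG is already seeded by the caller.
materialise_cohort <- function(samples, params) {
  g <- params$genes
  n <- nrow(samples)
  rows <- list()
  geno <- list()  # per variant: named vector of sample index -> allele count

  add <- function(gene, terms, carriers_idx, af = 0, psi = NA_real_,
                  call_rate = 1, qd = NULL, counts = 1) {
    i <- length(rows) + 1L
    loc <- .GENE_LOCI[match(gene, .GENE_LOCI$gene), ]
    rows[[i]] <<- data.frame(
      chrom = loc$chrom, pos = loc$base + 100L * i, ref = "A", alt = "T",
      gene = gene, consequence_terms = terms,
      af_nfe = af, af_afr = 0,
      ttn_psi = psi, call_rate = call_rate,
      qual_by_depth = if (is.null(qd)) round(stats::runif(1, 8, 30), 1) else qd,
      stringsAsFactors = FALSE
    )
    geno[[i]] <<- stats::setNames(rep(counts, length(carriers_idx)),
                                  carriers_idx)
  }
  term_for <- function(class) {
    if (class == "pLoF") return(sample(.PLOF_TERMS, 1))
    if (class == "missense") return(sample(.MISSENSE_TERMS, 1))
    sample(c(.PLOF_TERMS, .MISSENSE_TERMS), 1)  # PAV
  }

  for (k in seq_len(nrow(g))) {
    gene <- g$gene[k]
    idx <- which(samples$carrier_gene == gene)
    for (i in idx) {
      psi <- if (gene == "TTN") round(stats::runif(1, 0.92, 1), 3) else NA_real_
      add(gene, term_for(g$qualifying_class[k]), i, psi = psi)
    }
    n_decoy <- round(g$decoy_fraction[k] * length(idx))
    if (n_decoy > 0) {
      types <- rep(c("common_af", "synonymous", "low_qd", "low_call_rate",
                     "hwe"), length.out = n_decoy)
      for (ty in types) {
        who <- sample(n, min(2L, n))
        switch(ty,
          common_af = add(gene, term_for(g$qualifying_class[k]), who,
                          af = 0.005),
          synonymous = add(gene, "synonymous_variant", who),
          low_qd = add(gene, term_for(g$qualifying_class[k]), who, qd = 3),
          low_call_rate = add(gene, term_for(g$qualifying_class[k]), who,
                              call_rate = 0.85),
          hwe = add(gene, term_for(g$qualifying_class[k]),
                    sample(n, min(max(4L, n %/% 500L), n)), counts = 2))
      }
    }
    if (gene == "TTN" && g$decoy_fraction[k] > 0 && length(idx) > 0) {
      add("TTN", "stop_gained", sample(n, 1), psi = 0.10)
      add("TTN", "stop_gained", sample(n, 1), psi = NA_real_)
      add("TTN", "missense_variant", sample(n, 1), psi = 0.99)
    }
  }
  if (sum(g$decoy_fraction) > 0 && length(rows) > 0) {
    add("MYBPC3", "missense_variant", sample(n, 1))
  }

  if (length(rows) == 0L) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gene = character(),
                           consequence_terms = character(),
                           af_nfe = numeric(), af_afr = numeric(),
                           ttn_psi = numeric(), call_rate = numeric(),
                           qual_by_depth = numeric(),
                           stringsAsFactors = FALSE)
    gmat <- matrix(numeric(0), nrow = 0, ncol = n,
                   dimnames = list(NULL, samples$sample_id))
  } else {
    variants <- do.call(rbind, rows)
    gmat <- matrix(0, nrow = nrow(variants), ncol = n,
                   dimnames = list(NULL, samples$sample_id))
    for (i in seq_along(geno)) {
      gmat[i, as.integer(names(geno[[i]]))] <- geno[[i]]
    }
    # low-call-rate variants get consistent missingness in the matrix
    low_cr <- which(variants$call_rate < 1)
    for (i in low_cr) {
      nmiss <- round((1 - variants$call_rate[i]) * n)
      gmat[i, sample(n, nmiss)] <- NA
    }
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
    rownames(gmat) <- variants$key
  }
  out <- dcm_cohort(samples, gmat, variants)
  attr(out, "manifest") <- list(params = params)
  out
}
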