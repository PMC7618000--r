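# Exact test of Hardy-Weinberg equilibrium on biallelic genotype counts.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact (Levene-Haldane) test conditional on the observed allele
#' counts. Given \code{n} genotyped diploids and \code{nA} copies of the minor
#' allele, the heterozygote count under equilibrium follows the conditional
#' distribution
#' \deqn{P(n_{AB} \mid n, n_A) \propto \frac{2^{n_{AB}}}{n_{AB}!\, n_{AA}!\, n_{BB}!}}
#' over heterozygote counts of the same parity as \code{nA}. The p-value sums
#' the probabilities of all outcomes no more probable than the observed one.
#' Monomorphic sites return 1.
#'
#' @param n_homref,n_het,n_homalt Non-negative genotype counts (vectorised).
#' @return Exact p-value(s) in (0, 1].
#' @examples
#' hwe_exact_test(500, 10, 20)   # heterozygote deficit
#' hwe_exact_test(830, 0, 0)     # monomorphic: p = 1
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  k <- max(length(n_homref), length(n_het), length(n_homalt))
  n_homref <- rep_len(as.numeric(n_homref), k)
  n_het <- rep_len(as.numeric(n_het), k)
  n_homalt <- rep_len(as.numeric(n_homalt), k)
  if (any(is.na(n_homref) | is.na(n_het) | is.na(n_homalt))) {
    stop("genotype counts must be non-missing")
  }
  if (any(n_homref < 0 | n_het < 0 | n_homalt < 0)) {
    stop("genotype counts must be non-negative")
  }
  if (any(n_homref + n_het + n_homalt <= 0)) {
    stop("total genotyped count must be positive")
  }
  vapply(seq_len(k), function(i) {
    hwe_exact_one(n_homref[i], n_het[i], n_homalt[i])
  }, numeric(1))
}

hwe_exact_one <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nA <- 2 * nbb + nab            # alt allele copies
  if (nA == 0 || nA == 2 * n) return(1)
  # orient to the minor allele; distribution is symmetric in allele labels
  nm <- min(nA, 2 * n - nA)
  # support: heterozygote counts with the parity of nm, 0/1 .. nm
  het <- seq.int(nm %% 2, min(nm, 2 * n - nm), by = 2)
  logp <- het * log(2) - lgamma(het + 1) -
    lgamma((nm - het) / 2 + 1) - lgamma((2 * n - nm - het) / 2 + 1)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  pobs <- p[match(nab, het)]
  if (is.na(pobs)) stop("inconsistent genotype counts")
  # sum of outcomes no more probable than observed (small relative slack
  # guards against ties lost to floating point)
  sum(p[p <= pobs * (1 + 1e-7)])
}
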