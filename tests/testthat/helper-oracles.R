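# Independent brute-force oracles. These deliberately take different
# computational routes from the package internals: multinomial coefficients
# instead of the parity-support formula for HWE, lchoose-based enumeration
# for the hypergeometric p, golden-section likelihood maximisation instead
# of mean-equation root finding for the conditional MLE, and inversion
# sampling instead of rbeta for the penetrance interval.

oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nA <- 2 * nbb + nab
  if (nA == 0 || nA == 2 * n) return(1)
  het <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  hom_alt <- (nA - het) / 2
  hom_ref <- n - het - hom_alt
  keep <- hom_ref >= 0 & hom_alt >= 0
  het <- het[keep]; hom_alt <- hom_alt[keep]; hom_ref <- hom_ref[keep]
  lp <- lgamma(n + 1) - lgamma(hom_ref + 1) - lgamma(het + 1) -
    lgamma(hom_alt + 1) + het * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pobs <- p[het == nab]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# p-values for every table sharing the margins (r1, r2, c1): returns a
# vector indexed along the support of the first cell.
oracle_fisher_p_margin <- function(r1, r2, c1) {
  supp <- max(0L, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(r1 + r2, c1)
  p <- exp(lp)
  vapply(p, function(pobs) min(1, sum(p[p <= pobs * (1 + 1e-7)])), numeric(1))
}

oracle_fisher_p <- function(a, b, c, d) {
  supp <- max(0L, (a + c) - (c + d)):min(a + b, a + c)
  oracle_fisher_p_margin(a + b, c + d, a + c)[supp == a]
}

oracle_cmle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0L, c1 - r2):min(r1, c1)
  if (a == supp[1L]) return(0)
  if (a == supp[length(supp)]) return(Inf)
  ldc <- lchoose(r1, supp) + lchoose(r2, c1 - supp)
  ll <- function(l) {
    w <- ldc + supp * l
    w0 <- max(w)
    a * l + ldc[supp == a] - (w0 + log(sum(exp(w - w0))))
  }
  gr <- (sqrt(5) - 1) / 2
  lo <- -40; hi <- 40
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- ll(x1); f2 <- ll(x2)
  while (hi - lo > 1e-11) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- ll(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- ll(x1)
    }
  }
  exp((lo + hi) / 2)
}

# random 2x2 tables with positive margins
random_tables <- function(n, max_total = 80, seed = 1) {
  set.seed(seed)
  t(replicate(n, {
    tot <- sample(4:max_total, 1)
    r1 <- sample(1:(tot - 1), 1)
    c1 <- sample(1:(tot - 1), 1)
    lo <- max(0, c1 - (tot - r1)); hi <- min(r1, c1)
    a <- sample(lo:hi, 1)
    c(a, r1 - a, c1 - a, tot - r1 - c1 + a)
  }))
}

# minimal cohort from a hand-written variant table; every listed carrier id
# is heterozygous for that variant
tiny_cohort <- function(variants, carriers, n_female = 4, n_male = 4) {
  samples <- data.frame(
    sample_id = c(sprintf("F%02d", seq_len(n_female)),
                  sprintf("M%02d", seq_len(n_male))),
    sex = c(rep("female", n_female), rep("male", n_male)),
    ancestry = "European", status = "case",
    stringsAsFactors = FALSE
  )
  variants$key <- paste(variants$chrom, variants$pos, variants$ref,
                        variants$alt, sep = ":")
  g <- matrix(0, nrow(variants), nrow(samples),
              dimnames = list(variants$key, samples$sample_id))
  for (i in seq_along(carriers)) g[i, carriers[[i]]] <- 1
  dcm_cohort(samples, g, variants)
}

base_variant <- function(gene = "DSP", terms = "missense_variant",
                         pos = 1000, af_nfe = 0, ttn_psi = NA_real_,
                         call_rate = 1, qual_by_depth = 20) {
  data.frame(chrom = "1", pos = pos, ref = "G", alt = "A", gene = gene,
             consequence_terms = terms, af_nfe = af_nfe, af_afr = 0,
             ttn_psi = ttn_psi, call_rate = call_rate,
             qual_by_depth = qual_by_depth, stringsAsFactors = FALSE)
}
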