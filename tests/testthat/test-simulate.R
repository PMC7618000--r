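test_that("simulation is deterministic given its seed", {
  p <- simulation_params(n_pop = 5000, seed = 11)
  a <- simulate_population(p)
  b <- simulate_population(p)
  expect_identical(a$samples, b$samples)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$variants, b$variants)
  c1 <- simulate_case_cohort(p, 50, 100, seed = 3)
  c2 <- simulate_case_cohort(p, 50, 100, seed = 3)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_false(identical(
    c1$genotypes, simulate_case_cohort(p, 50, 100, seed = 4)$genotypes))
})

test_that("zero carrier frequency yields no carriers and no tested gene", {
  g <- default_gene_params()
  g$carrier_freq <- 0
  p <- simulation_params(genes = g, n_pop = 2000, seed = 2)
  cohort <- simulate_case_cohort(p, 30, 60, seed = 5)
  expect_true(all(cohort$samples$carrier_gene == "none"))
  fit <- dcm_burden(cohort)
  expect_false(any(fit$results$tested))
})

test_that("population carrier frequency converges to its parameter", {
  p <- simulation_params(n_pop = 1e5, seed = 9)
  pop <- simulate_population(p, genotypes = "none")
  n <- nrow(pop$samples)
  for (gene in c("TTN", "DSP", "MYH7")) {
    q <- p$genes$carrier_freq[p$genes$gene == gene]
    obs <- sum(pop$samples$carrier_gene == gene)
    se <- sqrt(n * q * (1 - q))
    expect_lt(abs(obs - n * q), 3 * se + 1e-9)
  }
})

test_that("ascertainment returns the requested sex split deterministically", {
  p <- simulation_params(n_pop = 2e4, seed = 21)
  pop <- simulate_population(p)
  n_cases <- table(pop$samples$sex[pop$samples$disease])
  nf <- min(20L, n_cases[["female"]]); nm <- min(40L, n_cases[["male"]])
  cohort <- ascertain_cases(pop, nf, nm, seed = 8)
  expect_identical(sum(cohort$samples$sex == "female"), as.integer(nf))
  expect_identical(sum(cohort$samples$sex == "male"), as.integer(nm))
  expect_true(all(cohort$samples$status == "case"))
  again <- ascertain_cases(pop, nf, nm, seed = 8)
  expect_identical(cohort$samples, again$samples)
  expect_error(ascertain_cases(pop, 1e6, 1, seed = 1), "insufficient")
})

test_that("case cohorts match the analytic carrier expectation", {
  # cohort-like conditions: expected DSP case carriers ~6 female, ~2 male
  p <- simulation_params(seed = 1)
  probs <- case_carrier_probs(p)
  expect_equal(unname(probs$prevalence["female"]),
               sum(p$genes$carrier_freq * p$genes$penetrance_female) +
                 (1 - sum(p$genes$carrier_freq)) * p$background_risk)
  reps <- 200L
  tot <- c(female = 0L, male = 0L)
  for (r in seq_len(reps)) {
    cohort <- simulate_case_cohort(p, 274, 556, seed = 1000 + r,
                                   decoys = FALSE)
    s <- cohort$samples
    tot["female"] <- tot["female"] + sum(s$carrier_gene == "DSP" &
                                           s$sex == "female")
    tot["male"] <- tot["male"] + sum(s$carrier_gene == "DSP" &
                                       s$sex == "male")
  }
  for (sx in c("female", "male")) {
    n <- reps * if (sx == "female") 274 else 556
    pc <- probs$p_carrier["DSP", sx]
    expect_lt(abs(tot[[sx]] - n * pc), 3 * sqrt(n * pc * (1 - pc)))
  }
})

test_that("materialised cohorts carry qualifying variants and live decoys", {
  p <- simulation_params(n_pop = 20000, seed = 33)
  pop <- simulate_population(p)
  q <- qualifying_variants(pop)
  # every true carrier is recovered through the full filter chain
  for (gene in c("TTN", "DSP")) {
    flags <- carrier_flags(pop$genotypes, q[[gene]])
    truth <- pop$samples$carrier_gene == gene
    expect_identical(unname(flags[pop$samples$sample_id]), unname(truth))
  }
  # decoys never qualify
  d <- attr(q, "detail")
  expect_true(any(d$reason != "pass"))
  expect_true(all(d$reason[d$gene == "MYBPC3"] == "no_rule_gene"))
})

test_that("tiny populations warn about too few expected cases", {
  p <- simulation_params(n_pop = 200, seed = 3)
  expect_warning(simulate_population(p, genotypes = "none"), "expected cases")
})
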