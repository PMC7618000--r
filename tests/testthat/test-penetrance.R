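test_that("the Bayes identity holds in closed form", {
  # equal case and population frequency: point equals prevalence
  e <- estimate_penetrance(10, 1000, 10, 1000, prevalence = 0.003)
  expect_equal(e$point, 0.003)
  # direct formula evaluation
  e <- estimate_penetrance(20, 1000, 5, 10000, prevalence = 0.001)
  expect_equal(e$point, 0.001 * 0.02 / 5e-4)
  # zero case carriers: point 0 with a positive upper bound
  e <- estimate_penetrance(0, 274, 40, 100000, prevalence = 0.0028)
  expect_equal(e$point, 0)
  expect_equal(e$ci_lower, 0)
  expect_gt(e$ci_upper, 0)
  # clamping at 1, counted per draw
  e <- estimate_penetrance(200, 274, 2, 100000, prevalence = 0.01)
  expect_equal(e$point, 1)
  expect_gt(e$n_clamped, 0)
})

test_that("the point is linear in prevalence until clamped", {
  e1 <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002)
  e2 <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.004)
  expect_equal(e2$point, 2 * e1$point)
})

test_that("intervals are reproducible and respond to information", {
  a <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002, seed = 5)
  b <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002, seed = 5)
  expect_identical(a$ci_lower, b$ci_lower)
  expect_identical(a$ci_upper, b$ci_upper)
  c <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002, seed = 6)
  expect_false(identical(a$ci_lower, c$ci_lower))
  # scaling all counts tenfold keeps the point and narrows the interval
  big <- estimate_penetrance(200, 10000, 500, 1000000, prevalence = 0.002,
                             seed = 5)
  expect_equal(big$point, a$point)
  expect_lt(big$ci_upper - big$ci_lower, a$ci_upper - a$ci_lower)
})

test_that("the point estimate is monotone in its inputs", {
  base <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002)$point
  up_case <- estimate_penetrance(25, 1000, 50, 100000, prevalence = 0.002)$point
  up_pop <- estimate_penetrance(20, 1000, 80, 100000, prevalence = 0.002)$point
  expect_gte(up_case, base)
  expect_lte(up_pop, base)
})

test_that("the Monte-Carlo interval matches an independent oracle", {
  # oracle: inversion sampling (qbeta over runif), 1e6 draws, seed 99
  e <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002,
                           n_draws = 1e6)
  expect_equal(signif(e$ci_lower, 2), signif(0.04708, 2))
  expect_equal(signif(e$ci_upper, 2), signif(0.132, 2))
})

test_that("degenerate inputs are refused", {
  expect_error(estimate_penetrance(5, 100, 0, 1000, prevalence = 0.01),
               "undefined")
  expect_error(estimate_penetrance(5, 100, 5, 1000, prevalence = 0),
               "prevalence")
  expect_error(estimate_penetrance(5, 100, 5, 1000, prevalence = 1),
               "prevalence")
})

test_that("sex strata are estimated with their own inputs", {
  counts <- list(all = c(10, 1000), female = c(5, 500), male = c(5, 500))
  pop <- list(all = c(100, 100000), female = c(50, 50000),
              male = c(50, 50000))
  est <- sex_stratified_penetrance("DSP", counts, pop, prevalence = 0.003)
  expect_setequal(est$stratum, c("all", "female", "male"))
  # identical frequencies and prevalence by sex: identical points
  expect_equal(est$point[est$stratum == "female"],
               est$point[est$stratum == "male"])
  # doubling one stratum's prevalence doubles its point
  est2 <- sex_stratified_penetrance("DSP", counts, pop,
                                    prevalence = c(all = 0.003,
                                                   female = 0.006,
                                                   male = 0.003))
  expect_equal(est2$point[est2$stratum == "female"],
               2 * est$point[est$stratum == "female"])
  expect_error(sex_stratified_penetrance("DSP", counts, pop,
                                         prevalence = c(female = 1e-3)),
               "stratum")
})

test_that("allele-count mode matches carrier mode for rare variants", {
  carrier <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002)
  allele <- estimate_penetrance(20, 1000, 50, 100000, prevalence = 0.002,
                                allele_counts = TRUE)
  expect_equal(allele$point, carrier$point, tolerance = 1e-12)
})
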