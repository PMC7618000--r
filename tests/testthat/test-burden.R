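test_that("carrier collapsing counts each sample once", {
  v <- rbind(base_variant(pos = 100), base_variant(pos = 200),
             base_variant(pos = 300))
  cohort <- tiny_cohort(v, list(c("F01", "M01"), "F01", character(0)))
  g <- cohort$genotypes
  k <- cohort$variants$key
  flags <- carrier_flags(g, k[1:2])
  expect_true(flags[["F01"]])             # two qualifying variants, one carrier
  expect_true(flags[["M01"]])
  expect_identical(sum(flags), 2L)
  expect_false(carrier_flags(g, k[3])[["F01"]])
  # a missing genotype at the only qualifying variant is a non-carrier
  g["1:100:G:A", "M01"] <- NA
  expect_false(carrier_flags(g, k[1])[["M01"]])
  expect_error(
    carrier_flags(g[, 1:3], k[1], samples = cohort$samples), "absent")
  expect_error(carrier_flags(g, "nonexistent:key"), "absent")
})

test_that("the minimum-carrier rule is strict at five", {
  mk <- function(a, c) matrix(c(a, 10 - a, c, 20 - c), 2, byrow = TRUE,
                              dimnames = list(c("female", "male"),
                                              c("carrier", "noncarrier")))
  tables <- list(g4 = mk(2, 2), g5 = mk(2, 3), g0 = mk(0, 0))
  out <- exclude_low_count(tables, 5L)
  expect_named(out$tested, "g5")
  expect_setequal(out$excluded$gene, c("g4", "g0"))
  expect_match(out$excluded$reason[out$excluded$gene == "g4"], "fewer than 5")
})

test_that("BH adjustment follows the step-up rule over tested genes only", {
  expect_equal(bh_adjust(c(a = 0.03)), c(a = 0.03))
  expect_equal(unname(bh_adjust(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), ">")
})

test_that("the cohort fit reproduces the fixture's contingency tables", {
  fit <- dcm_burden(table1_cohort())
  expect_equal(unname(fit$tables$DSP),
               matrix(c(20, 254, 14, 542), 2, byrow = TRUE))
  expect_equal(unname(fit$tables$TTN),
               matrix(c(37, 237, 105, 451), 2, byrow = TRUE))
  r <- fit$results
  expect_identical(sum(r$tested), 8L)
  expect_setequal(r$gene[!r$tested], c("BAG3", "TNNC1", "TNNT2", "PLN"))
  expect_true(all(r$p_fdr[r$tested] >= r$p[r$tested]))
  # interval brackets the conditional MLE
  ok <- r$tested
  expect_true(all(r$ci_lower[ok] <= r$or_cmle[ok] &
                  r$or_cmle[ok] <= r$ci_upper[ok]))
})

test_that("subsetting is idempotent for the full cohort and errors when a sex empties", {
  cohort <- table1_cohort()
  full <- dcm_burden(cohort)
  same <- dcm_burden(cohort, subset = function(s) rep(TRUE, nrow(s)))
  expect_identical(full$results, same$results)
  eur <- dcm_burden(cohort, subset = list(ancestry = "European"))
  expect_identical(eur$n_female + eur$n_male, 756L)
  expect_error(dcm_burden(cohort, subset = function(s) s$sex == "male"),
               "each sex")
  expect_error(dcm_burden(cohort, subset = list(nonsense_column = "x")),
               "unknown")
})

test_that("fit accessors expose odds ratios and a forest plot", {
  fit <- dcm_burden(table1_cohort())
  co <- coef(fit)
  expect_named(co)
  expect_identical(length(co), 8L)
  expect_equal(round_half_up(co[["DSP"]], 2), 3.04)
  expect_output(print(summary(fit)), "qualification log")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
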