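test_that("symmetric tables give OR 1 and p 1", {
  for (k in c(1, 5, 12)) {
    ft <- fisher_exact(c(k, 30 - k, k, 30 - k))
    expect_equal(ft$p, 1)
    expect_equal(ft$or_cmle, 1, tolerance = 1e-8)
  }
})

test_that("published comparisons are reproduced from their counts", {
  # protein-altering DSP: 20/274 females vs 14/556 males
  dsp <- fisher_exact(c(20, 254, 14, 542))
  expect_equal(round_half_up(dsp$or_cmle, 2), 3.04)
  expect_equal(round_half_up(dsp$ci95[1], 2), 1.44)
  expect_equal(round_half_up(dsp$ci95[2], 2), 6.63)
  # truncating DSP: 6/274 vs 2/556 (frozen enumeration-oracle values)
  plof <- fisher_exact(c(6, 268, 2, 554))
  expect_equal(plof$p, 0.0182155558974, tolerance = 1e-9)
  expect_equal(plof$or_cmle, 6.187080497, tolerance = 1e-6)
  expect_equal(round_half_up(plof$or_cmle, 2), 6.19)
})

test_that("edge cells give one-sided intervals and sentinels", {
  lo <- fisher_exact(c(0, 10, 3, 7))
  expect_equal(lo$or_cmle, 0)
  expect_equal(lo$ci95[1], 0)
  hi <- fisher_exact(c(3, 7, 0, 10))
  expect_identical(hi$or_cmle, Inf)
  expect_identical(hi$ci95[2], Inf)
  expect_identical(sample_or(c(0, 10, 0, 10)), Inf)
  expect_equal(sample_or(c(2, 272, 4, 552)), 2 * 552 / (272 * 4))
  expect_error(fisher_exact(c(0, 0, 3, 7)), "margin")
})

test_that("swapping the sex rows inverts the odds ratio and keeps p", {
  tabs <- random_tables(60, max_total = 80, seed = 11)
  for (i in seq_len(nrow(tabs))) {
    x <- tabs[i, ]
    a <- fisher_exact(x)
    b <- fisher_exact(x[c(3, 4, 1, 2)])
    expect_equal(a$p, b$p, tolerance = 1e-10)
    if (is.finite(a$or_cmle) && a$or_cmle > 0) {
      expect_equal(a$or_cmle, 1 / b$or_cmle, tolerance = 1e-7)
    }
    so <- sample_or(x); sob <- sample_or(x[c(3, 4, 1, 2)])
    if (is.finite(so) && so > 0) expect_equal(so, 1 / sob, tolerance = 1e-12)
  }
})

test_that("results agree with the stats::fisher.test cross-check", {
  tabs <- rbind(random_tables(40, max_total = 200, seed = 3),
                c(20, 254, 14, 542), c(37, 237, 105, 451))
  for (i in seq_len(nrow(tabs))) {
    x <- tabs[i, ]
    mine <- fisher_exact(x)
    ref <- stats::fisher.test(matrix(x, 2, 2, byrow = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    if (is.finite(mine$or_cmle) && mine$or_cmle > 0) {
      # fisher.test solves its roots at ~1e-4 tolerance
      expect_equal(mine$or_cmle, unname(ref$estimate), tolerance = 1e-3)
      # fisher.test resolves extreme interval ends only coarsely
      expect_equal(mine$ci95[1], ref$conf.int[1], tolerance = 0.05)
      if (is.finite(mine$ci95[2])) {
        expect_equal(mine$ci95[2], ref$conf.int[2], tolerance = 0.05)
      }
    }
  }
})

test_that("conditional MLE approaches the sample OR on well-filled tables", {
  set.seed(5)
  tabs <- rbind(c(50, 60, 70, 80), c(100, 200, 150, 300),
                t(replicate(20, sample(50:400, 4))))
  for (i in seq_len(nrow(tabs))) {
    x <- tabs[i, ]
    rel <- abs(fisher_exact(x)$or_cmle - sample_or(x)) / sample_or(x)
    expect_lt(rel, 0.01)
  }
})

test_that("the sex-by-carrier table is assembled from flags and sheet", {
  samples <- data.frame(
    sample_id = c("F1", "F2", "F3", "M1", "M2"),
    sex = c("female", "female", "female", "male", "male"),
    stringsAsFactors = FALSE)
  flags <- c(F1 = TRUE, F2 = FALSE, F3 = TRUE, M1 = FALSE, M2 = TRUE)
  tab <- build_table(flags, samples)
  expect_identical(unname(tab), matrix(c(2L, 1L, 1L, 1L), 2, byrow = TRUE))
  expect_error(build_table(c(Z9 = TRUE), samples), "absent")
})
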