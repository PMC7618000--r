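test_that("QC thresholds pass on equality and fail below", {
  v <- rbind(
    base_variant(pos = 100), base_variant(pos = 200),
    base_variant(pos = 300), base_variant(pos = 400),
    base_variant(pos = 500))
  v$call_rate <- c(0.95, 0.85, 0.95, 0.90, 0.95)
  v$qual_by_depth <- c(10, 10, 5.9, 6, 10)
  v$n_homref <- c(800, 800, 800, 800, 810)
  v$n_het <- c(30, 30, 30, 30, 0)
  v$n_homalt <- c(0, 0, 0, 0, 20)  # last: gross heterozygote deficit
  got <- passes_variant_qc(v, filter_config())
  expect_identical(got, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("missing QC fields error under strict and pass otherwise", {
  v <- base_variant()
  v$call_rate <- NA_real_
  v$n_homref <- 8; v$n_het <- 0; v$n_homalt <- 0
  expect_error(passes_variant_qc(v, filter_config(strict = TRUE)), "missing QC")
  expect_true(passes_variant_qc(v, filter_config(strict = FALSE)))
})

test_that("rarity is a strict popmax bound with absent populations rare", {
  expect_true(passes_rarity_filter(c(nfe = 5e-5, afr = 0)))
  expect_false(passes_rarity_filter(c(nfe = 2e-4)))
  expect_true(passes_rarity_filter(numeric(0)))
  expect_false(passes_rarity_filter(c(nfe = 1e-4)))   # boundary fails
  expect_true(passes_rarity_filter(c(nfe = NA, afr = 5e-5)))
  df <- data.frame(af_nfe = c(0, 2e-4), af_afr = c(5e-5, 0))
  expect_identical(passes_rarity_filter(df), c(TRUE, FALSE))
})

test_that("TTN variants require a known constitutive exon", {
  cfg <- filter_config()
  expect_true(passes_ttn_exon_filter(0.99, cfg))
  expect_true(passes_ttn_exon_filter(0.90, cfg))    # boundary passes
  expect_false(passes_ttn_exon_filter(0.10, cfg))
  expect_false(passes_ttn_exon_filter(NA_real_, cfg))
})

test_that("qualification respects gene mechanism rules", {
  v <- rbind(
    base_variant(gene = "DSP", terms = "missense_variant", pos = 100),
    base_variant(gene = "TTN", terms = "missense_variant", pos = 200,
                 ttn_psi = 0.99),
    base_variant(gene = "TTN", terms = "stop_gained", pos = 300,
                 ttn_psi = 0.99),
    base_variant(gene = "MYH7", terms = "stop_gained", pos = 400),
    base_variant(gene = "NOTAGENE", terms = "stop_gained", pos = 500))
  cohort <- tiny_cohort(v, list("F01", "F02", "M01", "M02", "F03"))
  k <- cohort$variants$key
  q <- qualifying_variants(cohort)
  expect_length(q$DSP, 1L)                # PAV rule accepts missense
  expect_length(q$TTN, 1L)                # pLoF only: missense TTN rejected
  expect_identical(q$TTN, k[3])
  expect_length(q$MYH7, 0L)               # missense rule rejects pLoF
  expect_identical(attr(q, "n_unassigned"), 1L)
  d <- attr(q, "detail")
  expect_identical(d$reason[d$key == k[2]], "class_mismatch")
  # every rule gene has an entry
  expect_setequal(names(q), dcm_gene_rules()$gene)
})

test_that("an empty variant table yields empty sets for all rule genes", {
  v <- base_variant()[0, ]
  cohort <- tiny_cohort(v, list())
  q <- qualifying_variants(cohort)
  expect_length(q, 12L)
  expect_true(all(lengths(q) == 0L))
})

test_that("tightening thresholds never adds a qualifying variant", {
  cohort <- table1_cohort()
  base <- qualifying_variants(cohort, cfg = filter_config())
  tighter <- list(
    filter_config(maf_threshold = 1e-5),
    filter_config(ttn_psi_threshold = 0.999),
    filter_config(min_call_rate = 0.99, min_qual_by_depth = 10))
  for (cfg in tighter) {
    q <- qualifying_variants(cohort, cfg = cfg)
    for (g in names(base)) {
      expect_true(all(q[[g]] %in% base[[g]]))
    }
  }
})
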