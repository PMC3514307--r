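test_that("packaged fixtures hit the fixed crude odds ratios", {
  d1 <- make_fixture_dataset("SNP1")
  expect_equal(round(crude_or(d1, "SNP1", "Aa")$or, 2), 1.01)
  expect_equal(round(crude_or(d1, "SNP1", "aa")$or, 2), 2.04)
  expect_equal(sum(d1$status == "case"), 276)
  expect_equal(sum(d1$status == "control"), 420)
  d2 <- make_fixture_dataset("SNP2")
  expect_equal(round(crude_or(d2, "SNP2", "Aa")$or, 2), 1.30)
  expect_equal(round(crude_or(d2, "SNP2", "aa")$or, 2), 1.67)
})

test_that("fixture construction is deterministic", {
  expect_identical(make_fixture_dataset("SNP1"),
                   make_fixture_dataset("SNP1"))
  # equal-odds spec expands to proportional distributions
  d <- counts_dataset(c(30, 15, 15), c(60, 30, 30))
  expect_equal(crude_or(d, "L1", "Aa")$or, 1)
})

test_that("the bounded search reproduces the frozen fixture counts", {
  specs <- fixture_specs()
  for (nm in names(specs)) {
    found <- search_fixture_counts(specs[[nm]])
    frozen <- fixture_counts(nm)
    expect_equal(found$cases, unname(frozen$cases))
    expect_equal(found$controls, unname(frozen$controls))
  }
})

test_that("error introduction follows the column-conditional proportions", {
  # with exactly 116 true-Aa controls and the B-type table (gold-Aa
  # column 15/87/14), 15 become AA and 14 become aa
  d <- counts_dataset(c(50, 50, 20), c(98, 116, 33))
  out <- introduce_error(d, "L1", snp_discordance("B"))
  was_Aa <- d$L1 == "Aa" & d$status == "control"
  expect_equal(sum(out$L1[was_Aa] == "AA"), 15)
  expect_equal(sum(out$L1[was_Aa] == "aa"), 14)
  expect_equal(sum(out$L1[was_Aa] == "Aa"), 116 - 29)
  # cases and subject count are conserved
  expect_identical(out$L1[d$status == "case"], d$L1[d$status == "case"])
  expect_equal(nrow(out), nrow(d))
  # deterministic
  expect_identical(out, introduce_error(d, "L1", snp_discordance("B")))
})

test_that("a diagonal table introduces no error", {
  d <- make_fixture_dataset("SNP1")
  expect_identical(introduce_error(d, "SNP1", diagonal_table()), d)
})

test_that("introduced error round-trips through a rebuilt discordance table", {
  for (snp in c("A", "B")) {
    tab <- snp_discordance(snp)
    d <- make_fixture_dataset("SNP1")
    derr <- introduce_error(d, "SNP1", tab)
    ctrl <- d$status == "control"
    pairs <- data.frame(subject_id = d$subject_id[ctrl], locus_id = "L",
                        gold_call = d$SNP1[ctrl],
                        observed_call = derr$SNP1[ctrl])
    rebuilt <- build_discordance_table(pairs, "L")
    n_ctrl <- wgacorrect:::genotype_counts(d, "SNP1", "control")
    for (h in GT) {
      col_total <- sum(tab[, h])
      for (g in GT) {
        if (g == h) next
        expected <- wgacorrect:::round_half_up(
          n_ctrl[[h]] * tab[g, h] / col_total)
        expect_lte(abs(rebuilt[g, h] - expected), 1)
      }
    }
  }
})

test_that("efficacy study arms behave as designed", {
  res <- run_efficacy_study(m = 5, seed = 17, snps = "SNP1")
  expect_setequal(unique(res$error), c("none", "A", "B"))
  # no error: corrected and uncorrected identical
  none <- res[res$error == "none", ]
  unc <- none[none$analysis == "uncorrected", c("or", "ci_low", "ci_high")]
  cor <- none[none$analysis == "corrected", c("or", "ci_low", "ci_high")]
  expect_equal(unc, cor, tolerance = 1e-12, ignore_attr = TRUE)
  # with B-type error the corrected aa OR moves back toward the truth
  b <- res[res$error == "B" & res$term == "aa", ]
  truth <- crude_or(make_fixture_dataset("SNP1"), "SNP1", "aa")$or
  expect_lt(abs(b$or[b$analysis == "corrected"] - truth),
            abs(b$or[b$analysis == "uncorrected"] - truth))
})

test_that("validation-size study reports per-factor CI widths", {
  res <- run_validation_size_study(factors = c(0.5, 5), repeats = 2,
                                   m = 5, seed = 30)
  expect_equal(nrow(res), 2 * 2 * 2)  # repeats x factors x terms
  expect_true(all(res$ci_width > 0))
  expect_setequal(unique(res$factor), c(0.5, 5))
})

test_that("iteration study tracks the pooled-OR spread", {
  res <- run_iteration_study(ms = c(2, 8), repeats = 10, seed = 40)
  expect_equal(res$m, c(2, 8))
  expect_true(all(res$width > 0))
  ors <- attr(res, "ors")
  expect_equal(dim(ors), c(10, 2))
  expect_true(all(is.finite(ors)))
})

test_that("study runs are reproducible from their seed", {
  a <- run_efficacy_study(m = 3, seed = 55, snps = "SNP1", errors = "B")
  b <- run_efficacy_study(m = 3, seed = 55, snps = "SNP1", errors = "B")
  expect_identical(a, b)
})

test_that("the reconstructed multi-locus tables keep the observed margins", {
  tabs <- aus_all_tables()
  expect_length(tabs, 6)
  expect_equal(vapply(tabs, sum, 0),
               c(SNP_A = 213, SNP_B = 247, SNP_C = 246, SNP_D = 249,
                 SNP_E = 243, SNP_F = 248))
  disc <- vapply(tabs, function(t) sum(t) - sum(diag(t)), 0)
  expect_equal(unname(disc), c(5, 32, 12, 9, 18, 1))
})

test_that("demo counts expand into analysable datasets", {
  d <- demo_dataset("A")
  expect_equal(sum(d$status == "case"), 116 + 129 + 30)
  o <- crude_or(d, "A", "Aa")
  expect_equal(o$or, (129 * 186) / (184 * 116))
})
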