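test_that("covariate-free logistic ORs equal contingency-table crude ORs", {
  sets <- list(counts_dataset(c(30, 40, 20), c(50, 35, 25)),
               make_fixture_dataset("SNP1"),
               make_fixture_dataset("SNP2", locus = "L1"))
  loci <- c("L1", "SNP1", "L1")
  for (i in seq_along(sets)) {
    fit <- fit_logistic(sets[[i]], loci[i])
    for (lev in c("Aa", "aa")) {
      expect_equal(exp(fit$coef[[lev]]),
                   crude_or(sets[[i]], loci[i], lev)$or,
                   tolerance = 1e-7)
    }
  }
})

test_that("identical case and control genotype distributions give OR 1", {
  d <- counts_dataset(c(30, 20, 10), c(60, 40, 20))
  fit <- fit_logistic(d, "L1")
  expect_equal(exp(fit$coef[["Aa"]]), 1, tolerance = 1e-9)
  expect_equal(exp(fit$coef[["aa"]]), 1, tolerance = 1e-9)
})

test_that("the SNP1 fixture reproduces its fixed crude odds ratios", {
  d <- make_fixture_dataset("SNP1")
  fit <- fit_logistic(d, "SNP1")
  expect_equal(round(exp(fit$coef[["aa"]]), 2), 2.04)
  expect_equal(round(exp(fit$coef[["Aa"]]), 2), 1.01)
})

test_that("an empty genotype level is reported as undefined, not dropped", {
  d <- counts_dataset(c(30, 20, 0), c(50, 40, 0))
  d <- d[d$L1 != "aa", ]
  fit <- fit_logistic(d, "L1")
  expect_true("aa" %in% names(fit$coef))
  expect_true(is.na(fit$coef[["aa"]]))
  expect_equal(fit$undefined, "aa")
})

test_that("covariate fits agree with stats::glm", {
  set.seed(5)
  d <- make_fixture_dataset("SNP1")
  d$age <- round(rnorm(nrow(d), 6, 2), 1)
  d$sex <- sample(c("girl", "boy"), nrow(d), replace = TRUE)
  fit <- fit_logistic(d, "SNP1", covariates = c("age", "sex"))
  ref <- glm(I(status == "case") ~ factor(SNP1, c("AA", "Aa", "aa")) +
               age + sex, data = d, family = binomial())
  expect_equal(unname(fit$coef[c("Aa", "aa")]),
               unname(coef(ref)[2:3]), tolerance = 1e-6)
  expect_equal(unname(fit$se[["age"]]),
               unname(sqrt(diag(vcov(ref)))[4]), tolerance = 1e-6)
})

test_that("Rubin pooling reproduces the hand-computed example", {
  fake <- function(b, v) {
    structure(list(coef = c(x = b), se = c(x = sqrt(v))),
              class = "logit_fit")
  }
  pooled <- pool_rubin(list(fake(0.1, 0.04), fake(0.2, 0.04),
                            fake(0.3, 0.04)))
  expect_equal(pooled$estimate, 0.2)
  expect_equal(pooled$within_var, 0.04)
  expect_equal(pooled$between_var, 0.01)
  expect_equal(pooled$total_var, 0.04 + (4 / 3) * 0.01)
  # single draw: B defined as zero, total variance = within
  p1 <- pool_rubin(list(fake(0.5, 0.09)))
  expect_equal(p1$between_var, 0)
  expect_equal(p1$total_var, 0.09)
  expect_equal(p1$estimate, 0.5)
  # identical draws: between variance vanishes, CI equals single-fit CI
  p3 <- pool_rubin(list(fake(0.5, 0.09), fake(0.5, 0.09), fake(0.5, 0.09)))
  expect_equal(p3$total_var, 0.09)
  expect_equal(p3$ci_low, exp(0.5 - qnorm(0.975) * 0.3))
  # pooling is permutation-invariant
  fits <- list(fake(0.1, 0.04), fake(0.25, 0.02), fake(0.3, 0.05))
  expect_equal(as.data.frame(pool_rubin(fits)),
               as.data.frame(pool_rubin(rev(fits))))
  expect_error(pool_rubin(list(fake(0.1, 0.04),
                               structure(list(coef = c(y = 1),
                                              se = c(y = 1)),
                                         class = "logit_fit"))),
               "mixed term sets")
})

test_that("Rubin-df confidence intervals widen relative to normal ones", {
  fake <- function(b, v) {
    structure(list(coef = c(x = b), se = c(x = sqrt(v))),
              class = "logit_fit")
  }
  fits <- list(fake(0.1, 0.04), fake(0.3, 0.04), fake(0.5, 0.04))
  pn <- pool_rubin(fits, df_method = "normal")
  pr <- pool_rubin(fits, df_method = "rubin")
  expect_lt(pr$ci_low, pn$ci_low)
  expect_gt(pr$ci_high, pn$ci_high)
  expect_equal(pr$estimate, pn$estimate)
})

test_that("diagonal table makes the corrected analysis the naive fit", {
  d <- make_fixture_dataset("SNP1")
  naive <- pool_rubin(list(fit_logistic(d, "SNP1")))
  pooled <- corrected_association(d, "SNP1", diagonal_table(),
                                  m = 20, seed = 4)
  expect_equal(pooled$or, naive$or, tolerance = 1e-12)
  expect_equal(pooled$ci_low, naive$ci_low, tolerance = 1e-12)
  expect_equal(pooled$ci_high, naive$ci_high, tolerance = 1e-12)
  expect_equal(attr(pooled, "mean_control_counts"),
               c(AA = 156, Aa = 204, aa = 60))
})

test_that("corrected_association is deterministic given the seed", {
  d <- make_fixture_dataset("SNP1")
  tab <- snp_discordance("B")
  a <- corrected_association(d, "SNP1", tab, m = 10, seed = 123)
  b <- corrected_association(d, "SNP1", tab, m = 10, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- corrected_association(d, "SNP1", tab, m = 10, seed = 124)
  expect_false(identical(a$or, c_$or))
})

test_that("crude_or matches closed-form arithmetic and scale properties", {
  d <- counts_dataset(c(10, 10, 10), c(10, 10, 10))
  expect_equal(crude_or(d, "L1", "aa")$or, 1)
  d2 <- counts_dataset(c(120, 10, 54), c(186, 10, 41))
  expect_equal(crude_or(d2, "L1", "aa")$or, (54 * 186) / (41 * 120))
  dd <- counts_dataset(2 * c(120, 10, 54), 2 * c(186, 10, 41))
  o1 <- crude_or(d2, "L1", "aa"); o2 <- crude_or(dd, "L1", "aa")
  expect_equal(o2$or, o1$or)
  expect_lt(diff(o2$ci), diff(o1$ci))
  d0 <- counts_dataset(c(10, 5, 0), c(10, 5, 3))
  expect_error(crude_or(d0, "L1", "aa"), "zero cell")
})
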