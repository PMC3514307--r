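## Stage 3: per-draw logistic fits and Rubin's-rules pooling.
##
## Each corrected dataset is analysed with unconditional logistic
## regression (case/control outcome; genotype as two indicator terms with
## AA referent; optional covariates). Across the m imputation draws the
## coefficient mean is the pooled estimate and Rubin's total variance
## T = W + (1 + 1/m) B combines the mean within-draw variance W with the
## between-draw variance B of the coefficients.

## IRLS logistic fit on a prepared design matrix (hot path).
fit_core <- function(y, X) {
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  k <- ncol(X)
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  Rm <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  cov <- matrix(NA_real_, k, k)
  cov[piv, piv] <- chol2inv(Rm)
  se <- sqrt(diag(cov))
  names(se) <- colnames(X)
  list(coef = fit$coefficients, se = se,
       converged = fit$converged && p == k)
}

## Shared prep: outcome, genotype vector, covariate design, usable rows.
prepare_fit_frame <- function(dataset, locus, covariates = NULL) {
  check_genotype_dataset(dataset, locus)
  if (!all(c("case", "control") %in% dataset$status)) {
    stop("both cases and controls are required to fit the model",
         call. = FALSE)
  }
  cov_mm <- NULL
  keep <- !is.na(dataset[[locus]])
  if (length(covariates)) {
    miss <- setdiff(covariates, names(dataset))
    if (length(miss)) {
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    cov_df <- dataset[covariates]
    keep <- keep & stats::complete.cases(cov_df)
    cov_mm <- stats::model.matrix(~ ., data = cov_df[keep, , drop = FALSE])
    cov_mm <- cov_mm[, -1L, drop = FALSE]
  }
  list(y = as.integer(dataset$status[keep] == "case"),
       geno = dataset[[locus]][keep], cov_mm = cov_mm, keep = keep)
}

## Fit with genotype indicators (Aa, aa; referent AA) plus covariates.
## A genotype level absent from the data yields an NA coefficient recorded
## in `undefined`, never a silently dropped term.
fit_geno <- function(y, geno, cov_mm = NULL) {
  terms_geno <- c("Aa", "aa")
  present <- terms_geno[terms_geno %in% geno]
  X <- cbind(`(Intercept)` = 1,
             vapply(present, function(g) as.numeric(geno == g),
                    numeric(length(geno))))
  colnames(X) <- c("(Intercept)", present)
  if (!is.null(cov_mm)) X <- cbind(X, cov_mm)
  core <- fit_core(y, X)
  all_terms <- c("(Intercept)", terms_geno, colnames(cov_mm))
  coef <- stats::setNames(rep(NA_real_, length(all_terms)), all_terms)
  se <- coef
  coef[names(core$coef)] <- core$coef
  se[names(core$se)] <- core$se
  structure(list(coef = coef, se = se, n = length(y),
                 converged = core$converged,
                 undefined = setdiff(terms_geno, present)),
            class = "logit_fit")
}

#' Unconditional logistic regression for one locus
#'
#' Maximum-likelihood logistic fit of case/control status on genotype
#' (coded as `Aa` and `aa` indicators with `AA` referent) and optional
#' covariates. Rows with a missing genotype or covariate are excluded. A
#' genotype level absent from the data is reported as an undefined term
#' (`NA` coefficient), not silently dropped; non-convergence (including
#' separation) is flagged via `converged`.
#'
#' @inheritParams plan_reassignment
#' @param covariates character vector of covariate column names.
#' @return object of class `logit_fit`: list with named `coef` and `se`
#'   (log-odds scale), `n`, `converged`, and `undefined` (genotype terms
#'   with no data).
#' @export
#' @examples
#' d <- make_fixture_dataset("SNP1")
#' exp(fit_logistic(d, "SNP1")$coef["aa"])  # crude OR for aa vs AA
fit_logistic <- function(dataset, locus, covariates = NULL) {
  f <- prepare_fit_frame(dataset, locus, covariates)
  fit_geno(f$y, f$geno, f$cov_mm)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d%s)\n", x$n,
              if (x$converged) "" else "; NOT converged"))
  out <- data.frame(term = names(x$coef), coef = x$coef, se = x$se,
                    OR = exp(x$coef), row.names = NULL)
  print(out, digits = 4, row.names = FALSE)
  if (length(x$undefined)) {
    cat("Undefined terms (no subjects):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pool per-draw fits with Rubin's rules
#'
#' For each model term across `m` draws: pooled coefficient
#' `beta = mean(beta_i)`, within-imputation variance `W = mean(se_i^2)`,
#' between-imputation variance `B = var(beta_i)` (sample variance,
#' `m - 1` denominator; zero when `m = 1`), total variance
#' `T = W + (1 + 1/m) B`. Odds ratios are `exp(beta)` with
#' `exp(beta +/- q sqrt(T))` confidence limits and a Wald test of
#' `beta / sqrt(T)`. The reference quantile is standard normal by default;
#' `df_method = "rubin"` uses the t distribution with Rubin's
#' small-sample degrees of freedom `(m - 1)(1 + W / ((1 + 1/m) B))^2`.
#'
#' @param fits list of [fit_logistic()] results sharing the same terms.
#' @param conf_level confidence level for the interval.
#' @param df_method `"normal"` (default) or `"rubin"`.
#' @return object of class `pooled_result`: data frame with one row per
#'   term (`term`, `estimate`, `within_var`, `between_var`, `total_var`,
#'   `se`, `or`, `ci_low`, `ci_high`, `statistic`, `p`); attributes `m`,
#'   `conf_level`, `df_method`, `df`.
#' @export
pool_rubin <- function(fits, conf_level = 0.95,
                       df_method = c("normal", "rubin")) {
  df_method <- match.arg(df_method)
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (inherits(fits, "logit_fit")) fits <- list(fits)
  terms <- names(fits[[1L]]$coef)
  same <- vapply(fits, function(f) identical(names(f$coef), terms), TRUE)
  if (!all(same)) stop("fits have mixed term sets", call. = FALSE)
  m <- length(fits)
  coefs <- do.call(rbind, lapply(fits, `[[`, "coef"))
  ses <- do.call(rbind, lapply(fits, `[[`, "se"))
  est <- colMeans(coefs)
  W <- colMeans(ses^2)
  B <- if (m > 1L) apply(coefs, 2L, stats::var) else
    stats::setNames(rep(0, length(terms)), terms)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  alpha <- 1 - conf_level
  if (df_method == "rubin" && m > 1L) {
    df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
    q <- stats::qt(1 - alpha / 2, df)
    p <- 2 * stats::pt(-abs(est / se), df)
  } else {
    df <- rep(Inf, length(terms))
    q <- stats::qnorm(1 - alpha / 2)
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  out <- data.frame(term = terms, estimate = unname(est),
                    within_var = unname(W), between_var = unname(B),
                    total_var = unname(Tv), se = unname(se),
                    or = unname(exp(est)),
                    ci_low = unname(exp(est - q * se)),
                    ci_high = unname(exp(est + q * se)),
                    statistic = unname(est / se), p = unname(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, m = m, conf_level = conf_level, df_method = df_method,
            df = df, class = c("pooled_result", "data.frame"))
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled over %d draw(s) (%s quantiles, %.0f%% CI)\n",
              attr(x, "m"), attr(x, "df_method"),
              100 * attr(x, "conf_level")))
  show <- data.frame(term = x$term, OR = round(x$or, 2),
                     ci_low = round(x$ci_low, 2),
                     ci_high = round(x$ci_high, 2),
                     p = signif(x$p, 3))
  print(show, row.names = FALSE)
  mc <- attr(x, "mean_control_counts")
  if (!is.null(mc)) {
    cat("Mean corrected control counts:",
        paste(sprintf("%s %.1f", names(mc), mc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Misclassification-corrected association analysis
#'
#' The full correction pipeline for one locus: `m` stochastic correction
#' draws ([correct_once()] semantics), a logistic fit per draw, and
#' Rubin's-rules pooling ([pool_rubin()]). Deterministic given `seed`, `m`
#' and the inputs; all per-draw randomness is consumed sequentially from
#' one stream. Draws whose fit does not converge are dropped with a
#' warning (at most 10\% of `m`, else an error). With a purely diagonal
#' discordance table every draw is the observed data, so the result
#' equals the naive logistic fit.
#'
#' @inheritParams correct_once
#' @inheritParams pool_rubin
#' @param m number of imputation draws.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param covariates character vector of covariate column names.
#' @return a [pool_rubin()] result with extra attributes:
#'   `mean_control_counts` (mean corrected control count per genotype
#'   across draws), `m_requested`, `seed`, `locus`.
#' @export
#' @examples
#' d <- make_fixture_dataset("SNP1")
#' corrected_association(d, "SNP1", snp_discordance("A"), m = 10, seed = 1)
corrected_association <- function(dataset, locus, table, m = 50L,
                                  seed = NULL, covariates = NULL,
                                  stratum = c("control", "case", "both"),
                                  conf_level = 0.95,
                                  df_method = c("normal", "rubin")) {
  stratum <- match.arg(stratum)
  df_method <- match.arg(df_method)
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1L)
  m <- as.integer(m)
  check_genotype_dataset(dataset, locus)
  rates <- misclassification_rates(table)
  if (!is.null(seed)) set.seed(seed)
  f <- prepare_fit_frame(dataset, locus, covariates)
  geno0 <- dataset[[locus]]
  eligible <- !is.na(geno0) &
    (stratum == "both" | dataset$status == stratum)
  is_control <- dataset$status == "control" & !is.na(geno0)
  fits <- vector("list", m)
  ctrl_counts <- matrix(0, m, 3L, dimnames = list(NULL, GENOTYPES))
  for (i in seq_len(m)) {
    core <- draw_reassignments(geno0, eligible, rates)
    geno <- geno0
    if (nrow(core)) geno[core$index] <- core$to
    ctrl_counts[i, ] <- vapply(GENOTYPES, function(g)
      sum(geno[is_control] == g), numeric(1))
    fit <- tryCatch(fit_geno(f$y, geno[f$keep], f$cov_mm),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) fits[[i]] <- fit
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("no correction draw produced a converged fit",
                     call. = FALSE)
  if (sum(!ok) > 0L) {
    warning(sprintf("%d of %d draws failed to fit and were dropped",
                    sum(!ok), m), call. = FALSE)
    if (sum(!ok) > 0.1 * m) {
      stop("more than 10% of correction draws failed; inspect the data",
           call. = FALSE)
    }
  }
  pooled <- pool_rubin(fits[ok], conf_level = conf_level,
                       df_method = df_method)
  attr(pooled, "mean_control_counts") <-
    colMeans(ctrl_counts[ok, , drop = FALSE])
  attr(pooled, "m_requested") <- m
  attr(pooled, "seed") <- seed
  attr(pooled, "locus") <- locus
  pooled
}

#' Crude odds ratio from the 2x2 genotype margin
#'
#' Contingency-table odds ratio for one genotype level against the
#' referent, with a Woolf (log-OR normal-approximation) confidence
#' interval. Serves as a covariate-free closed-form cross-check of the
#' logistic fit and as the constraint used when constructing fixtures.
#'
#' @inheritParams plan_reassignment
#' @param level genotype level compared against `ref`.
#' @param ref referent genotype.
#' @param conf_level confidence level.
#' @return list with `or`, `ci` (length 2), `counts` (2x2 matrix),
#'   `level`, `ref`.
#' @export
#' @examples
#' crude_or(make_fixture_dataset("SNP1"), "SNP1", "aa")
crude_or <- function(dataset, locus, level, ref = "AA",
                     conf_level = 0.95) {
  check_genotype_dataset(dataset, locus)
  stopifnot(level %in% GENOTYPES, ref %in% GENOTYPES, level != ref)
  a <- genotype_counts(dataset, locus, "case")
  c_ <- genotype_counts(dataset, locus, "control")
  cells <- c(cases_level = a[[level]], cases_ref = a[[ref]],
             controls_level = c_[[level]], controls_ref = c_[[ref]])
  if (any(cells == 0L)) {
    stop("zero cell in the 2x2 margin (",
         paste(names(cells)[cells == 0L], collapse = ", "),
         "); crude OR undefined", call. = FALSE)
  }
  or <- (cells["cases_level"] * cells["controls_ref"]) /
    (cells["controls_level"] * cells["cases_ref"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(sum(1 / cells))
  list(or = unname(or), ci = unname(exp(log(or) + c(-half, half))),
       counts = matrix(cells, 2L, 2L,
                       dimnames = list(c(level, ref),
                                       c("cases", "controls"))),
       level = level, ref = ref)
}
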