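## Synthetic-data suite: reconstructed hypothetical case-control datasets,
## deterministic error introduction, and the three simulation studies
## (correction efficacy, validation-sample size, iteration count).

fixture_file <- function(...) {
  system.file("extdata", ..., package = "wgacorrect", mustWork = TRUE)
}

#' Packaged validation discordance tables
#'
#' The two bundled 3x3 gold-vs-observed discordance matrices from the
#' case validation sample: SNP A (213 pairs, 2.35\% discordant) and SNP B
#' (247 pairs, 12.96\% discordant — the worst locus observed).
#'
#' @param snp `"A"` or `"B"`.
#' @return a [discordance_table()].
#' @export
snp_discordance <- function(snp = c("A", "B")) {
  snp <- match.arg(snp)
  read_discordance_table(
    fixture_file(sprintf("snp%s_discordance.csv", snp)),
    locus_id = paste0("SNP_", snp))
}

#' A purely concordant (diagonal) discordance table
#'
#' Validation counts with zero off-diagonal cells: every misclassification
#' rate is zero, so correction leaves the data untouched. Used as the
#' no-error reference arm of the simulation studies.
#'
#' @param pairs_per_row validation pairs per observed-genotype row.
#' @param locus_id optional label.
#' @return a [discordance_table()].
#' @export
diagonal_table <- function(pairs_per_row = c(96, 91, 26),
                           locus_id = "no_error") {
  diagonal_counts <- diag(as.integer(pairs_per_row))
  discordance_table(diagonal_counts, locus_id = locus_id)
}

#' Specifications of the hypothetical datasets
#'
#' Target crude odds ratios (AA referent) and study scale for the two
#' artificial loci used to validate the correction: `SNP1` with an
#' approximate dominant risk model (OR Aa = 1.01, aa = 2.04) and `SNP2`
#' with an approximate log-additive model (OR Aa = 1.30, aa = 1.67 as
#' realized at study scale). The optional soft targets (`ci_Aa`, `ci_aa`,
#' `uncorrected_A`, `uncorrected_B`) pin down the genotype marginals,
#' which the odds ratios alone leave unidentified.
#'
#' @return named list of `fixture_spec` objects with fields `name`,
#'   `or_Aa`, `or_aa`, `n_cases`, `n_controls`, plus the soft targets.
#' @export
fixture_specs <- function() {
  spec <- function(name, or_Aa, or_aa, ci_Aa, ci_aa, unc_A, unc_B) {
    structure(list(name = name, or_Aa = or_Aa, or_aa = or_aa,
                   n_cases = 276L, n_controls = 420L,
                   ci_Aa = ci_Aa, ci_aa = ci_aa,
                   uncorrected_A = unc_A, uncorrected_B = unc_B),
              class = "fixture_spec")
  }
  list(
    SNP1 = spec("SNP1", 1.01, 2.04, c(0.73, 1.41), c(1.29, 3.21),
                c(1.07, 1.82), c(1.49, 1.66)),
    SNP2 = spec("SNP2", 1.30, 1.67, c(0.94, 1.80), c(1.03, 2.71),
                c(1.37, 1.50), c(1.92, 1.36))
  )
}

## Crude ORs (Aa, aa) vs AA from count vectors.
counts_or <- function(cases, controls) {
  c((cases[2L] * controls[1L]) / (controls[2L] * cases[1L]),
    (cases[3L] * controls[1L]) / (controls[3L] * cases[1L]))
}

#' Search for integer fixture counts matching a specification
#'
#' Bounded exhaustive search over control genotype marginals (cases are
#' then determined by the target odds ratios and the case total): keeps
#' candidates whose crude ORs round to the spec's targets at two decimals,
#' and among those minimizes the distance to the spec's soft targets —
#' the Woolf confidence limits and the crude ORs observed after
#' deterministic A-type/B-type error introduction ([introduce_error()]
#' with the packaged tables). The shipped fixtures were frozen from this
#' search; rerunning it reproduces them exactly.
#'
#' @param spec one element of [fixture_specs()].
#' @param control_range range searched for each control marginal count.
#' @param min_cell smallest admissible genotype count.
#' @return list with integer vectors `cases` and `controls` (AA, Aa, aa)
#'   and the achieved crude `or` pair.
#' @export
search_fixture_counts <- function(spec, control_range = c(80L, 300L),
                                  min_cell = 5L) {
  stopifnot(inherits(spec, "fixture_spec"))
  tab_A <- unclass(snp_discordance("A"))
  tab_B <- unclass(snp_discordance("B"))
  shift <- function(ctrl, M) {
    out <- as.numeric(ctrl)
    for (h in 1:3) {
      col_total <- sum(M[, h])
      for (g in 1:3) {
        if (g != h && M[g, h] > 0L) {
          k <- round_half_up(ctrl[h] * M[g, h] / col_total)
          out[h] <- out[h] - k
          out[g] <- out[g] + k
        }
      }
    }
    out
  }
  ci2 <- function(or, cells)
    exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * sqrt(sum(1 / cells)))
  best <- NULL
  best_score <- Inf
  for (c_AA in seq(control_range[1L], control_range[2L])) {
    for (c_Aa in seq(control_range[1L], control_range[2L])) {
      c_aa <- spec$n_controls - c_AA - c_Aa
      if (c_aa < 20L) next
      ctrl <- c(c_AA, c_Aa, c_aa)
      r1 <- spec$or_Aa * c_Aa / c_AA
      r2 <- spec$or_aa * c_aa / c_AA
      a_AA <- spec$n_cases / (1 + r1 + r2)
      cases <- c(round(a_AA), round(a_AA * r1), 0)
      cases[3L] <- spec$n_cases - cases[1L] - cases[2L]
      if (any(cases < min_cell)) next
      or <- counts_or(cases, ctrl)
      if (round(or[1L], 2) != spec$or_Aa ||
          round(or[2L], 2) != spec$or_aa) next
      score <- 0
      if (!is.null(spec$ci_Aa)) {
        ciA <- ci2(or[1L], c(cases[1:2], ctrl[1:2]))
        cia <- ci2(or[2L], c(cases[c(1, 3)], ctrl[c(1, 3)]))
        score <- score + sum((round(ciA, 2) - spec$ci_Aa)^2) +
          sum((round(cia, 2) - spec$ci_aa)^2)
      }
      if (!is.null(spec$uncorrected_A)) {
        score <- score +
          sum((counts_or(cases, shift(ctrl, tab_A)) -
                 spec$uncorrected_A)^2) +
          sum((counts_or(cases, shift(ctrl, tab_B)) -
                 spec$uncorrected_B)^2)
      }
      if (score < best_score) {
        best_score <- score
        best <- list(cases = as.integer(cases),
                     controls = as.integer(ctrl), or = or)
      }
    }
  }
  if (is.null(best)) stop("no integer counts satisfy the specification",
                          call. = FALSE)
  best
}

#' Frozen genotype counts of the packaged hypothetical datasets
#'
#' @param fixture `"SNP1"` or `"SNP2"`.
#' @return list with integer vectors `cases` and `controls` named
#'   (AA, Aa, aa).
#' @export
fixture_counts <- function(fixture = c("SNP1", "SNP2")) {
  fixture <- match.arg(fixture)
  tab <- utils::read.csv(fixture_file("fixture_counts.csv"),
                         stringsAsFactors = FALSE)
  tab <- tab[tab$fixture == fixture, ]
  pick <- function(st) {
    row <- tab[tab$status == st, c("AA", "Aa", "aa")]
    stats::setNames(as.integer(row), GENOTYPES)
  }
  list(cases = pick("case"), controls = pick("control"))
}

#' Construct a hypothetical case-control dataset
#'
#' Expands genotype counts into a subject-level dataset: cases then
#' controls, genotypes in (AA, Aa, aa) blocks, with deterministic subject
#' ids — the same counts always yield the identical dataset. By default
#' uses the frozen counts of the packaged fixtures, whose crude odds
#' ratios reproduce the fixed values of the hypothetical risk models.
#'
#' @param fixture `"SNP1"`, `"SNP2"`, or a list with `cases` and
#'   `controls` count vectors ordered (AA, Aa, aa).
#' @param locus name for the genotype column; defaults to the fixture
#'   name (or `"locus"` for ad-hoc counts).
#' @return a subject-level data frame (`subject_id`, `status`, genotype).
#' @export
#' @examples
#' d <- make_fixture_dataset("SNP1")
#' table(d$status, d$SNP1)
make_fixture_dataset <- function(fixture = "SNP1", locus = NULL) {
  if (is.character(fixture)) {
    if (is.null(locus)) locus <- fixture
    fixture <- fixture_counts(fixture)
  }
  if (is.null(locus)) locus <- "locus"
  stopifnot(is.list(fixture), all(c("cases", "controls") %in%
                                    names(fixture)))
  geno <- c(rep(GENOTYPES, fixture$cases), rep(GENOTYPES, fixture$controls))
  n_cases <- sum(fixture$cases)
  status <- rep(c("case", "control"), c(n_cases, sum(fixture$controls)))
  ids <- c(sprintf("case_%03d", seq_len(n_cases)),
           sprintf("ctrl_%03d", seq_len(sum(fixture$controls))))
  out <- data.frame(subject_id = ids, status = status,
                    stringsAsFactors = FALSE)
  out[[locus]] <- geno
  out
}

#' Introduce misclassification into a dataset
#'
#' Deterministically applies a discordance table's error pattern to a
#' stratum, emulating the physical error process gold -> observed: for
#' each TRUE genotype h, the column-conditional proportion
#' `count(g, h) / column_total(h)` of the stratum's h-subjects is switched
#' to observed genotype g (counts rounded half-up; subjects taken in
#' stable `subject_id` order). Note the asymmetry with the correction,
#' which is row-conditional (observed -> gold).
#'
#' @inheritParams correct_once
#' @return the dataset with error introduced.
#' @export
introduce_error <- function(dataset, locus, table,
                            stratum = c("control", "case", "both")) {
  stratum <- match.arg(stratum)
  check_genotype_dataset(dataset, locus)
  stopifnot(inherits(table, "discordance_table"))
  in_stratum <- (stratum == "both" | dataset$status == stratum) &
    !is.na(dataset[[locus]])
  if (!any(in_stratum)) stop("stratum is empty", call. = FALSE)
  geno <- dataset[[locus]]
  new_geno <- geno
  for (h in GENOTYPES) {
    col_total <- sum(table[, h])
    if (col_total == 0L) next
    pool <- which(in_stratum & geno == h)
    pool <- pool[order(dataset$subject_id[pool])]
    taken <- 0L
    for (g in GENOTYPES) {
      if (g == h || table[g, h] == 0L) next
      k <- round_half_up(length(pool) * table[g, h] / col_total)
      k <- min(k, length(pool) - taken)
      if (k > 0L) {
        new_geno[pool[taken + seq_len(k)]] <- g
        taken <- taken + k
      }
    }
  }
  dataset[[locus]] <- new_geno
  dataset
}

## Resolve an error arm to (dataset with error, correction table).
error_arm <- function(base, locus, error) {
  switch(error,
    none = list(data = base, table = diagonal_table()),
    A = list(data = introduce_error(base, locus, snp_discordance("A")),
             table = snp_discordance("A")),
    B = list(data = introduce_error(base, locus, snp_discordance("B")),
             table = snp_discordance("B")),
    stop("unknown error type ", sQuote(error), call. = FALSE))
}

pooled_rows <- function(pooled, keep = c("Aa", "aa")) {
  out <- as.data.frame(pooled)
  out[out$term %in% keep, c("term", "or", "ci_low", "ci_high", "p")]
}

#' Correction-efficacy study on the hypothetical datasets
#'
#' For each fixture and error pattern (none / A-type / B-type), fits the
#' uncorrected logistic model on the error-bearing data and runs the full
#' corrected analysis (`m` draws, Rubin pooling). With no error the
#' correction table is diagonal and the corrected results equal the
#' uncorrected ones; with error the corrected odds ratios should recover
#' the fixtures' true values.
#'
#' @param m imputation draws per corrected analysis.
#' @param seed study seed (one stream drives all arms).
#' @param snps fixtures to analyse.
#' @param errors error patterns to apply.
#' @return data frame with columns `snp`, `error`, `analysis`, `term`,
#'   `or`, `ci_low`, `ci_high`, `p`.
#' @export
run_efficacy_study <- function(m = 50L, seed = 101L,
                               snps = c("SNP1", "SNP2"),
                               errors = c("none", "A", "B")) {
  set.seed(seed)
  out <- list()
  for (snp in snps) {
    base <- make_fixture_dataset(snp)
    for (err in errors) {
      arm <- error_arm(base, snp, err)
      unc <- pooled_rows(pool_rubin(list(fit_logistic(arm$data, snp))))
      cor <- pooled_rows(corrected_association(arm$data, snp, arm$table,
                                               m = m))
      unc$analysis <- "uncorrected"
      cor$analysis <- "corrected"
      block <- rbind(unc, cor)
      block$snp <- snp
      block$error <- err
      out[[length(out) + 1L]] <- block
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("snp", "error", "analysis", "term", "or", "ci_low", "ci_high",
          "p")]
}

#' Validation-sample-size study
#'
#' Repeats the B-type correction experiment with the discordance table
#' scaled by each factor: the misclassification rates are unchanged, but
#' larger validation row totals tighten the binomially sampled correction
#' proportions, so pooled confidence intervals narrow as the validation
#' sample grows while the odds ratios stay put.
#'
#' @param factors scale factors applied to the discordance table.
#' @param repeats independent repetitions per factor.
#' @inheritParams run_efficacy_study
#' @param snp fixture to analyse.
#' @return data frame with columns `rep`, `factor`, `term`, `or`,
#'   `ci_low`, `ci_high`, `ci_width` (width on the odds-ratio scale).
#' @export
run_validation_size_study <- function(factors = c(0.5, 1, 5),
                                      repeats = 1L, m = 50L, seed = 202L,
                                      snp = "SNP1") {
  set.seed(seed)
  base <- make_fixture_dataset(snp)
  table_b <- snp_discordance("B")
  data_err <- introduce_error(base, snp, table_b)
  out <- list()
  for (r in seq_len(repeats)) {
    for (f in factors) {
      pooled <- corrected_association(data_err, snp, scale_table(table_b, f),
                                      m = m)
      rows <- pooled_rows(pooled)
      rows$rep <- r
      rows$factor <- f
      out[[length(out) + 1L]] <- rows
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$ci_width <- out$ci_high - out$ci_low
  out[, c("rep", "factor", "term", "or", "ci_low", "ci_high", "ci_width")]
}

#' Iteration-count study
#'
#' Distribution of the pooled odds ratio across independent repeats of the
#' whole corrected analysis, for several numbers of imputation draws `m`.
#' The 2.5th-97.5th percentile spread narrows as `m` grows, quantifying
#' how many draws the pooled estimate needs to stabilise. Uses the worst
#' observed misclassification (B-type) on the SNP1 fixture by default.
#'
#' @param ms numbers of imputation draws to compare.
#' @param repeats independent repetitions per `m`.
#' @inheritParams run_validation_size_study
#' @param term genotype term whose pooled OR is tracked.
#' @return data frame with columns `m`, `repeats`, `q2.5`, `q97.5`,
#'   `width`; attribute `ors` holds the repeats x length(ms) matrix of
#'   pooled odds ratios.
#' @export
run_iteration_study <- function(ms = c(25L, 50L, 100L), repeats = 200L,
                                seed = 303L, snp = "SNP1", term = "aa") {
  set.seed(seed)
  base <- make_fixture_dataset(snp)
  table_b <- snp_discordance("B")
  data_err <- introduce_error(base, snp, table_b)
  ors <- matrix(NA_real_, repeats, length(ms),
                dimnames = list(NULL, paste0("m", ms)))
  for (j in seq_along(ms)) {
    for (r in seq_len(repeats)) {
      pooled <- corrected_association(data_err, snp, table_b, m = ms[j])
      ors[r, j] <- pooled$or[pooled$term == term]
    }
  }
  qs <- apply(ors, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(m = as.integer(ms), repeats = as.integer(repeats),
                    q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                    width = qs[2L, ] - qs[1L, ], row.names = NULL)
  attr(out, "ors") <- ors
  out
}

#' Multi-locus validation tables from the case substudy
#'
#' The six per-locus discordance tables of the bundled validation sample.
#' SNP A and SNP B carry their full observed 3x3 matrices; for SNPs C-F
#' only the pair totals and the directional discordant counts were
#' recorded, so their concordant (diagonal) cells are a synthetic
#' reconstruction — split (0.45, 0.42, 0.13) across (AA, Aa, aa) with
#' largest-remainder rounding. Discordance summaries depend only on
#' totals and off-diagonal cells, which are observed.
#'
#' @return named list of six [discordance_table()] objects.
#' @export
aus_all_tables <- function() {
  tab <- utils::read.csv(fixture_file("validation_directional_counts.csv"),
                         stringsAsFactors = FALSE)
  split_diag <- function(concordant, props = c(0.45, 0.42, 0.13)) {
    base <- concordant * props
    out <- floor(base)
    left <- concordant - sum(out)
    if (left > 0) {
      bump <- order(base - out, decreasing = TRUE)[seq_len(left)]
      out[bump] <- out[bump] + 1
    }
    out
  }
  tables <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    id <- paste0("SNP_", row$locus)
    if (row$locus %in% c("A", "B")) return(snp_discordance(row$locus))
    m <- matrix(0L, 3L, 3L, dimnames = list(GENOTYPES, GENOTYPES))
    for (k in seq_len(nrow(DISCORDANCE_DIRECTIONS))) {
      d <- DISCORDANCE_DIRECTIONS[k, ]
      col <- sprintf("%s_to_%s", d$gold, d$observed)
      m[d$observed, d$gold] <- as.integer(row[[col]])
    }
    diag(m) <- split_diag(row$n_pairs - sum(m))
    discordance_table(m, locus_id = id)
  })
  stats::setNames(tables, paste0("SNP_", tab$locus))
}

#' Demo case-control genotype counts
#'
#' Per-locus genotype counts of the six-SNP demonstration analysis (the
#' real covariate-adjusted analysis is not reproducible from counts alone;
#' these serve as demo input for crude analyses).
#'
#' @return data frame with columns `locus`, `genotype`, `n_cases`,
#'   `n_controls`.
#' @export
demo_genotype_counts <- function() {
  utils::read.csv(fixture_file("demo_genotype_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' Expand demo counts for one locus into a subject-level dataset
#'
#' @param locus one of the loci in [demo_genotype_counts()].
#' @return a subject-level data frame.
#' @export
demo_dataset <- function(locus = "A") {
  tab <- demo_genotype_counts()
  tab <- tab[tab$locus == locus, ]
  if (nrow(tab) == 0L) stop("unknown demo locus ", sQuote(locus),
                            call. = FALSE)
  ord <- match(GENOTYPES, tab$genotype)
  make_fixture_dataset(list(cases = tab$n_cases[ord],
                            controls = tab$n_controls[ord]),
                       locus = locus)
}
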