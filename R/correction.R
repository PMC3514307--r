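## Stage 2: one stochastic correction draw.
##
## The discordance table is only an estimate, from one validation sample,
## of the true misclassification proportions. Each draw therefore samples
## the proportion to correct from the validation-sample binomial before
## reassigning that share of randomly chosen control records. Selection is
## always made against the ORIGINAL genotype variable (the paper's
## temporary-variable semantics), so a record reassigned out of one row can
## never be picked up again by another row in the same draw.

#' Sample a correction proportion from the validation binomial
#'
#' Draws `X ~ Binomial(n, p_total)` and returns `X / n`, where `n` is the
#' validation row total for the observed genotype and `p_total` its
#' combined misclassification rate. Larger validation samples give tighter
#' sampled proportions, which is how validation-sample size propagates into
#' the precision of the corrected estimates. Uses R's global RNG stream.
#'
#' @param row one row entry of [misclassification_rates()] (fields `n`,
#'   `p_total`).
#' @return a proportion in `[0, 1]`; `0` when the row total is zero.
#' @export
sample_proportion <- function(row) {
  stopifnot(is.list(row), !is.null(row$n), !is.null(row$p_total))
  if (row$n <= 0L || row$p_total <= 0) return(0)
  stats::rbinom(1L, row$n, row$p_total) / row$n
}

## Split c_T changes across 1 or 2 target genotypes: the first target gets
## round_half_up(split_1 * c_T), the second the remainder, so the parts
## always sum to c_T.
split_counts <- function(c_total, split) {
  if (length(split) <= 1L) return(c_total)
  c1 <- round_half_up(split[1L] * c_total)
  c(c1, c_total - c1)
}

## Core of a correction draw, on bare vectors (hot path).
## genotype: character vector; eligible: logical vector (stratum members
## with a non-missing call). Returns data.frame(index, from, to) plus a
## per-row info table as attribute "rows". Consumes the global RNG in a
## fixed row order (AA, Aa, aa) for reproducibility.
draw_reassignments <- function(genotype, eligible, rates) {
  stopifnot(inherits(rates, "misclass_rates"),
            length(genotype) == length(eligible))
  out_idx <- integer(0); out_from <- character(0); out_to <- character(0)
  info <- vector("list", 3L)
  for (g in GENOTYPES) {
    row <- rates$rows[[g]]
    if (row$p_total <= 0 || row$n <= 0L) next
    pool <- which(eligible & !is.na(genotype) & genotype == g)
    n_avail <- length(pool)
    p_hat <- sample_proportion(row)
    c_total <- round_half_up(p_hat * n_avail)
    if (c_total > n_avail) {
      warning(sprintf(
        "row %s: %d changes requested but only %d eligible; truncating",
        g, c_total, n_avail), call. = FALSE)
      c_total <- n_avail
    }
    info[[g]] <- data.frame(observed = g, n_eligible = n_avail,
                            p_hat = p_hat, c_total = c_total,
                            stringsAsFactors = FALSE)
    if (c_total == 0L) next
    drawn <- pool[sample.int(n_avail, c_total)]
    per_target <- split_counts(c_total, row$split)
    to <- rep(row$targets, per_target)
    out_idx <- c(out_idx, drawn)
    out_from <- c(out_from, rep(g, c_total))
    out_to <- c(out_to, to)
  }
  structure(
    data.frame(index = out_idx, from = out_from, to = out_to,
               stringsAsFactors = FALSE),
    rows = do.call(rbind, info[!vapply(info, is.null, TRUE)])
  )
}

#' Plan one correction draw
#'
#' For each observed-genotype row g with nonzero misclassification: sample
#' a proportion from the validation binomial, convert it to a number of
#' required changes `c_T = round(p_hat * N_g)` (`N_g` = eligible subjects
#' in the stratum with genotype g, rounding half-up), draw that many
#' subjects uniformly without replacement, and split them across the row's
#' target genotypes in draw order. The plan refers to the dataset's
#' current genotypes, so applying it changes each record at most once.
#'
#' @param dataset subject-level data frame with columns `subject_id`,
#'   `status` (`"case"`/`"control"`) and a genotype column per locus.
#' @param locus name of the genotype column to correct.
#' @param rates a [misclassification_rates()] object.
#' @param stratum which status stratum to correct; the misclassified
#'   source is typically the controls.
#' @return object of class `reassignment_plan`: data frame with columns
#'   `subject_id`, `from`, `to`; attributes `rows` (per-row sampled
#'   proportions and change counts) and `locus`.
#' @export
plan_reassignment <- function(dataset, locus, rates,
                              stratum = c("control", "case", "both")) {
  check_genotype_dataset(dataset, locus)
  stratum <- match.arg(stratum)
  if (!any(dataset$status == "control")) {
    stop("dataset has no control subjects", call. = FALSE)
  }
  eligible <- !is.na(dataset[[locus]]) &
    (stratum == "both" | dataset$status == stratum)
  core <- draw_reassignments(dataset[[locus]], eligible, rates)
  structure(
    data.frame(subject_id = dataset$subject_id[core$index],
               from = core$from, to = core$to, stringsAsFactors = FALSE),
    rows = attr(core, "rows"), locus = locus, stratum = stratum,
    class = c("reassignment_plan", "data.frame")
  )
}

#' Apply a reassignment plan
#'
#' Returns a new dataset in which exactly the planned subjects carry their
#' target genotypes; all other records (in particular every case record
#' when correcting controls) are untouched.
#'
#' @param dataset the dataset the plan was drawn from.
#' @param plan a [plan_reassignment()] result.
#' @param locus genotype column; defaults to the plan's locus.
#' @return the corrected dataset.
#' @export
apply_reassignment <- function(dataset, plan, locus = attr(plan, "locus")) {
  check_genotype_dataset(dataset, locus)
  if (nrow(plan) == 0L) return(dataset)
  idx <- match(plan$subject_id, dataset$subject_id)
  if (anyNA(idx)) {
    stop("plan references unknown subject(s): ",
         paste(utils::head(plan$subject_id[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  }
  cur <- dataset[[locus]][idx]
  if (any(is.na(cur) | cur != plan$from)) {
    stop("plan source genotypes do not match the dataset; was the plan ",
         "drawn from a different dataset?", call. = FALSE)
  }
  dataset[[locus]][idx] <- plan$to
  dataset
}

#' One stochastic correction draw
#'
#' Composes [misclassification_rates()], [plan_reassignment()] and
#' [apply_reassignment()]: every observed-genotype row with off-diagonal
#' discordance gets its sampled share of stratum records reassigned to the
#' row's gold-standard targets. With a purely diagonal table the result is
#' the input dataset, exactly.
#'
#' @inheritParams plan_reassignment
#' @param table a [discordance_table()] for the locus.
#' @return the corrected dataset.
#' @export
correct_once <- function(dataset, locus, table,
                         stratum = c("control", "case", "both")) {
  stratum <- match.arg(stratum)
  rates <- misclassification_rates(table)
  plan <- plan_reassignment(dataset, locus, rates, stratum = stratum)
  apply_reassignment(dataset, plan, locus)
}
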