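## Stage 1: validation-sample discordance tables.
##
## A discordance table cross-tabulates the error-prone (observed) genotype
## call against the gold-standard call for subjects genotyped from both DNA
## sources. Rows are indexed by the OBSERVED genotype, columns by the GOLD
## genotype, both in the fixed order (AA, Aa, aa). All correction
## probabilities are row-conditional: cell (g, h) / row total g is the
## probability that an observed g call should in truth have been h.

#' Construct a discordance table
#'
#' @param counts 3x3 matrix of non-negative counts; rows = observed
#'   (error-prone) genotype, columns = gold-standard genotype, both ordered
#'   (AA, Aa, aa). Dimnames, if present, are checked against that order.
#' @param locus_id optional locus identifier.
#' @return an object of class `discordance_table`: an integer matrix with
#'   `observed`/`gold` dimnames and a `locus_id` attribute.
#' @export
#' @examples
#' discordance_table(matrix(c(95, 1, 0, 1, 90, 3, 0, 0, 23), 3, 3), "SNP_A")
discordance_table <- function(counts, locus_id = NULL) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) {
    stop("discordance table must be 3x3 (AA, Aa, aa)", call. = FALSE)
  }
  if (!is.null(rownames(counts)) &&
      !identical(unname(rownames(counts)), GENOTYPES)) {
    stop("row order must be AA, Aa, aa", call. = FALSE)
  }
  if (!is.null(colnames(counts)) &&
      !identical(unname(colnames(counts)), GENOTYPES)) {
    stop("column order must be AA, Aa, aa", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (anyNA(counts) || any(counts < 0L)) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0L) {
    stop("discordance table is empty: no validation pairs", call. = FALSE)
  }
  dimnames(counts) <- list(observed = GENOTYPES, gold = GENOTYPES)
  structure(counts, locus_id = locus_id, class = "discordance_table")
}

#' @export
print.discordance_table <- function(x, ...) {
  id <- attr(x, "locus_id")
  cat("Discordance table", if (!is.null(id)) paste0("for ", id), "\n")
  cat(sprintf("%d validation pairs, %d discordant (%.2f%%)\n",
              sum(x), sum(x) - sum(diag(x)),
              100 * (sum(x) - sum(diag(x))) / sum(x)))
  print(unclass(x)[,], ...)
  invisible(x)
}

#' Build a discordance table from paired genotype calls
#'
#' Cross-tabulates gold-standard against error-prone calls for one locus of
#' a validation sample (subjects genotyped from both DNA sources, e.g.
#' blood-derived gDNA vs whole-genome-amplified buccal DNA). Pairs where
#' either call is missing are excluded before counting, so the table total
#' equals the number of complete pairs.
#'
#' @param pairs data frame with columns `gold_call` and `observed_call`
#'   (canonical genotypes or `NA`), and optionally `locus_id`.
#' @param locus_id if given and `pairs` has a `locus_id` column, restrict
#'   to that locus; otherwise used only to label the result.
#' @return a [discordance_table()].
#' @export
build_discordance_table <- function(pairs, locus_id = NULL) {
  stopifnot(is.data.frame(pairs))
  need <- c("gold_call", "observed_call")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns gold_call and observed_call",
         call. = FALSE)
  }
  if (!is.null(locus_id) && "locus_id" %in% names(pairs)) {
    pairs <- pairs[pairs$locus_id == locus_id, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    stop("no validation pairs", if (!is.null(locus_id))
      paste0(" for locus ", sQuote(locus_id)), call. = FALSE)
  }
  gold <- canonical_genotype(pairs$gold_call, what = "gold_call")
  obs <- canonical_genotype(pairs$observed_call, what = "observed_call")
  keep <- !is.na(gold) & !is.na(obs)
  if (!any(keep)) {
    stop("all validation pairs have a missing call; no usable data",
         call. = FALSE)
  }
  counts <- table(observed = factor(obs[keep], levels = GENOTYPES),
                  gold = factor(gold[keep], levels = GENOTYPES))
  discordance_table(unclass(counts), locus_id = locus_id)
}

#' Row-conditional misclassification rates
#'
#' For each observed genotype row g of a discordance table: the row total
#' `n` (the binomial trials parameter used when sampling a correction
#' proportion), the per-target rates `p_to[h] = count(g, h) / n` for each
#' gold genotype `h != g`, their sum `p_total` (combined probability that
#' an observed g call is wrong), and — where the row has misclassification
#' toward more than one target — conditional `split` weights
#' `p_to[targets] / p_total` summing to one. Rows with a zero total have
#' all rates defined as zero.
#'
#' @param table a [discordance_table()].
#' @return object of class `misclass_rates`: list with `locus_id` and
#'   `rows`, a named list (AA, Aa, aa) of per-row rate entries.
#' @export
#' @examples
#' snp_a <- snp_discordance("A")
#' misclassification_rates(snp_a)$rows$aa$p_total  # 3/26
misclassification_rates <- function(table) {
  stopifnot(inherits(table, "discordance_table"))
  rows <- lapply(GENOTYPES, function(g) {
    n <- sum(table[g, ])
    others <- setdiff(GENOTYPES, g)
    p_to <- if (n > 0L) table[g, others] / n else
      stats::setNames(c(0, 0), others)
    p_total <- sum(p_to)
    targets <- others[p_to > 0]
    split <- if (p_total > 0) p_to[targets] / p_total else numeric(0)
    list(observed = g, n = n, p_to = p_to, p_total = p_total,
         targets = targets, split = split)
  })
  structure(list(locus_id = attr(table, "locus_id"),
                 rows = stats::setNames(rows, GENOTYPES)),
            class = "misclass_rates")
}

#' @export
print.misclass_rates <- function(x, ...) {
  cat("Misclassification rates",
      if (!is.null(x$locus_id)) paste0("for ", x$locus_id), "\n")
  for (r in x$rows) {
    cat(sprintf("  %s (n = %d): p = %s%s\n", r$observed, r$n,
                format(r$p_total, digits = 4),
                if (length(r$targets))
                  paste0(" -> ", paste(sprintf("%s (%.3f)", r$targets,
                                               r$split), collapse = ", "))
                else ""))
  }
  invisible(x)
}

## Directions of discordance, gold -> observed, in reporting order.
## "Aa->AA" reads: gold-standard Aa called AA by the error-prone source
## (heterozygote loss / allelic drop-out toward the wild type).
DISCORDANCE_DIRECTIONS <- data.frame(
  direction = c("Aa->AA", "Aa->aa", "AA->Aa", "AA->aa", "aa->Aa", "aa->AA"),
  gold     = c("Aa", "Aa", "AA", "AA", "aa", "aa"),
  observed = c("AA", "aa", "Aa", "aa", "Aa", "AA"),
  stringsAsFactors = FALSE
)

#' Summarize discordance across loci
#'
#' Per-locus discordance percentages plus a pooled directional breakdown of
#' all discordant pairs, as in a multi-SNP validation report: counts and
#' percentages for the six gold-to-observed directions, the heterozygote
#' loss share (gold Aa called homozygous — the allelic drop-out signature)
#' and the homozygote-to-heterozygote share (gold AA or aa called Aa).
#' Percentages of direction counts use the discordant-pair denominator.
#'
#' @param tables a list of [discordance_table()] objects (or a single one).
#' @return object of class `discordance_summary`: list with `per_locus`
#'   data frame (`locus_id`, `n_pairs`, `n_discordant`, `pct_discordant`),
#'   `directions` data frame (`direction`, `count`, `pct_of_discordant`),
#'   and `pooled` list (`n_pairs`, `n_discordant`, `pct_discordant`,
#'   `het_loss_share`, `hom_to_het_share`, both shares in percent).
#' @export
summarize_discordance <- function(tables) {
  if (inherits(tables, "discordance_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "discordance_table")))
  per <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    id <- attr(tab, "locus_id")
    data.frame(locus_id = if (is.null(id)) paste0("locus", i) else id,
               n_pairs = sum(tab),
               n_discordant = sum(tab) - sum(diag(tab)),
               stringsAsFactors = FALSE)
  }))
  per$pct_discordant <- 100 * per$n_discordant / per$n_pairs
  dir_counts <- vapply(seq_len(nrow(DISCORDANCE_DIRECTIONS)), function(k) {
    sum(vapply(tables, function(tab)
      tab[DISCORDANCE_DIRECTIONS$observed[k],
          DISCORDANCE_DIRECTIONS$gold[k]], integer(1)))
  }, integer(1))
  n_disc <- sum(per$n_discordant)
  directions <- data.frame(
    direction = DISCORDANCE_DIRECTIONS$direction,
    count = dir_counts,
    pct_of_discordant = if (n_disc > 0) 100 * dir_counts / n_disc else
      rep(NA_real_, length(dir_counts)),
    stringsAsFactors = FALSE
  )
  from_het <- sum(dir_counts[DISCORDANCE_DIRECTIONS$gold == "Aa"])
  to_het <- sum(dir_counts[DISCORDANCE_DIRECTIONS$observed == "Aa"])
  pooled <- list(
    n_pairs = sum(per$n_pairs),
    n_discordant = n_disc,
    pct_discordant = 100 * n_disc / sum(per$n_pairs),
    het_loss_share = if (n_disc > 0) 100 * from_het / n_disc else NA_real_,
    hom_to_het_share = if (n_disc > 0) 100 * to_het / n_disc else NA_real_
  )
  structure(list(per_locus = per, directions = directions, pooled = pooled),
            class = "discordance_summary")
}

#' @export
print.discordance_summary <- function(x, ...) {
  cat("Per-locus discordance:\n")
  out <- x$per_locus
  out$pct_discordant <- sprintf("%.2f%%", out$pct_discordant)
  print(out, row.names = FALSE)
  cat(sprintf("\nPooled: %d/%d discordant (%.1f%%)\n",
              x$pooled$n_discordant, x$pooled$n_pairs,
              x$pooled$pct_discordant))
  if (x$pooled$n_discordant > 0) {
    d <- x$directions[x$directions$count > 0, ]
    cat(paste(sprintf("  %s: %d (%.1f%%)", d$direction, d$count,
                      d$pct_of_discordant), collapse = "\n"), "\n")
    cat(sprintf("Heterozygote loss: %.1f%%; homozygote -> Aa: %.1f%%\n",
                x$pooled$het_loss_share, x$pooled$hom_to_het_share))
  }
  invisible(x)
}

#' Scale a discordance table
#'
#' Multiplies every cell by `factor` and rounds half-up to an integer,
#' emulating a smaller (`factor < 1`) or larger (`factor > 1`) validation
#' sample with the same misclassification pattern. Point rates are
#' (near-)unchanged while the binomial sampling of correction proportions
#' tightens with the row totals, so corrected confidence intervals narrow
#' as the validation sample grows.
#'
#' @param table a [discordance_table()].
#' @param factor positive scaling factor.
#' @return a [discordance_table()] with scaled counts.
#' @export
#' @examples
#' scale_table(snp_discordance("B"), 5)
scale_table <- function(table, factor) {
  stopifnot(inherits(table, "discordance_table"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  discordance_table(round_half_up(unclass(table) * factor),
                    locus_id = attr(table, "locus_id"))
}
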