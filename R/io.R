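## Delimited-text readers and writers. Comma or tab is autodetected from
## the header line; missing values may be empty or NA.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    check.names = FALSE)
}

#' Read paired validation genotype calls
#'
#' Reads a delimited file of validation-sample pairs with columns
#' `subject_id`, `locus_id`, `gold_call`, `observed_call` (gold = the
#' trusted DNA source, observed = the error-prone one). Calls are
#' canonicalised; empty/`NA` entries stay missing and are later excluded
#' by [build_discordance_table()].
#'
#' @param path file path (comma- or tab-delimited, autodetected).
#' @param genotype_map optional named map of raw tokens to `AA`/`Aa`/`aa`.
#' @return data frame of paired calls.
#' @export
read_paired_calls <- function(path, genotype_map = NULL) {
  tab <- read_delim_file(path)
  need <- c("subject_id", "locus_id", "gold_call", "observed_call")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("pairs file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab[c("subject_id", "locus_id")])) {
    stop("duplicate (subject_id, locus_id) records in pairs file",
         call. = FALSE)
  }
  tab$gold_call <- canonical_genotype(tab$gold_call, genotype_map,
                                      what = "gold_call")
  tab$observed_call <- canonical_genotype(tab$observed_call, genotype_map,
                                          what = "observed_call")
  tab
}

#' Read a subject-level case-control genotype table
#'
#' Reads a delimited file with header `subject_id`, `status`, one column
#' per locus, and any covariate columns. Genotypes are canonicalised to
#' `AA`/`Aa`/`aa` (a `genotype_map` such as
#' `c("0" = "AA", "1" = "Aa", "2" = "aa")` recodes dosage data first);
#' unknown tokens raise an error naming the offending column and rows.
#'
#' @param path file path.
#' @param loci locus column names; default: every column that is not
#'   `subject_id`, `status` or a declared covariate.
#' @param covariates covariate column names (left untouched).
#' @param genotype_map optional named recode map applied to locus columns.
#' @return validated subject-level data frame.
#' @export
read_genotype_table <- function(path, loci = NULL, covariates = NULL,
                                genotype_map = NULL) {
  tab <- read_delim_file(path)
  if (!"subject_id" %in% names(tab)) {
    stop("genotype table lacks a subject_id column", call. = FALSE)
  }
  if (!"status" %in% names(tab)) {
    stop("genotype table lacks a status column", call. = FALSE)
  }
  if (is.null(loci)) {
    loci <- setdiff(names(tab), c("subject_id", "status", covariates))
  }
  miss <- setdiff(c(loci, covariates), names(tab))
  if (length(miss)) {
    stop("column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tab$status))) {
    stop("missing status for subject(s): ",
         paste(utils::head(tab$subject_id[is.na(tab$status)], 5L),
               collapse = ", "), call. = FALSE)
  }
  for (locus in loci) {
    tab[[locus]] <- canonical_genotype(tab[[locus]], genotype_map,
                                       what = paste0("genotype in column ",
                                                     sQuote(locus)))
  }
  check_genotype_dataset(tab)
  tab
}

#' Read a discordance table file
#'
#' Expects a 3x3 delimited matrix: a label column of observed genotypes
#' (rows) and header columns `AA`, `Aa`, `aa` for the gold genotypes, both
#' in that order.
#'
#' @param path file path.
#' @param locus_id optional locus label for the result.
#' @return a [discordance_table()].
#' @export
read_discordance_table <- function(path, locus_id = NULL) {
  tab <- read_delim_file(path)
  if (ncol(tab) != 4L || !identical(names(tab)[-1L], GENOTYPES)) {
    stop("discordance file must have an observed-genotype label column ",
         "followed by gold columns AA, Aa, aa", call. = FALSE)
  }
  if (!identical(tab[[1L]], GENOTYPES)) {
    stop("discordance file rows must be labelled AA, Aa, aa (observed)",
         call. = FALSE)
  }
  discordance_table(as.matrix(tab[, -1L]), locus_id = locus_id)
}

#' Write a discordance table file
#'
#' @param table a [discordance_table()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_discordance_table <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "discordance_table"))
  out <- data.frame(observed = GENOTYPES, unclass(table)[,],
                    check.names = FALSE)
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write pooled association results
#'
#' Machine-readable full-precision results table with one row per
#' genotype term: `locus`, `level`, `n_cases`,
#' `mean_n_controls_corrected`, `OR`, `CI_low`, `CI_high`, `p`, `m`,
#' `seed`.
#'
#' @param pooled a [corrected_association()] (or [pool_rubin()]) result.
#' @param path output path.
#' @param dataset optional source dataset, used to report per-genotype
#'   case counts.
#' @param locus locus label; defaults to the result's locus attribute.
#' @param delim field delimiter.
#' @return the written data frame, invisibly.
#' @export
write_association_results <- function(pooled, path, dataset = NULL,
                                      locus = attr(pooled, "locus"),
                                      delim = ",") {
  rows <- pooled[pooled$term %in% c("Aa", "aa"), ]
  mc <- attr(pooled, "mean_control_counts")
  n_cases <- if (!is.null(dataset) && !is.null(locus)) {
    genotype_counts(dataset, locus, "case")[rows$term]
  } else rep(NA_integer_, nrow(rows))
  seed <- attr(pooled, "seed")
  out <- data.frame(
    locus = if (is.null(locus)) NA_character_ else locus,
    level = rows$term,
    n_cases = as.integer(n_cases),
    mean_n_controls_corrected =
      if (is.null(mc)) NA_real_ else unname(mc[rows$term]),
    OR = rows$or, CI_low = rows$ci_low, CI_high = rows$ci_high,
    p = rows$p, m = attr(pooled, "m"),
    seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(out)
}
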