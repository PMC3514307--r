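#' @keywords internal
"_PACKAGE"

## Canonical genotype coding used throughout: diallelic SNP calls
## AA (homozygous wild type), Aa (heterozygous), aa (homozygous mutant).

GENOTYPES <- c("AA", "Aa", "aa")

#' Round half away from zero to the nearest integer
#'
#' Fractional counts produced by proportional scaling or by multiplying a
#' sampled proportion by a stratum size are rounded half-up (0.5 -> 1),
#' unlike [round()]'s round-half-even. Only used on non-negative quantities.
#'
#' @param x numeric vector, non-negative.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Canonicalise genotype calls
#'
#' Maps raw genotype tokens to the canonical three-level coding
#' `c("AA", "Aa", "aa")`. Empty strings, `NA` and `"NA"` become missing.
#' An optional named map recodes other schemes (e.g. dosage
#' `c("0" = "AA", "1" = "Aa", "2" = "aa")`) before validation.
#'
#' @param x character (or coercible) vector of genotype tokens.
#' @param map optional named character vector mapping raw tokens to
#'   canonical genotypes.
#' @param what label used in error messages (e.g. a column name).
#' @return character vector with values in `AA`, `Aa`, `aa` or `NA`.
#' @export
#' @examples
#' canonical_genotype(c("AA", "aa", NA, ""))
#' canonical_genotype(c("0", "2"), map = c("0" = "AA", "1" = "Aa", "2" = "aa"))
canonical_genotype <- function(x, map = NULL, what = "genotype") {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
  if (!is.null(map)) {
    hit <- !is.na(x) & x %in% names(map)
    x[hit] <- unname(map[x[hit]])
  }
  bad <- !is.na(x) & !(x %in% GENOTYPES)
  if (any(bad)) {
    stop(sprintf(
      "unknown %s token(s) %s at position(s) %s; expected AA/Aa/aa or NA",
      what,
      paste(sQuote(unique(x[bad])), collapse = ", "),
      paste(utils::head(which(bad), 5L), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

## Validate a subject-level case-control dataset; returns it invisibly.
check_genotype_dataset <- function(dataset, locus = NULL) {
  stopifnot(is.data.frame(dataset))
  need <- c("subject_id", "status")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) {
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(dataset$subject_id)) {
    stop("duplicate subject_id values in dataset", call. = FALSE)
  }
  if (any(is.na(dataset$status)) ||
      !all(dataset$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control' with no missing values",
         call. = FALSE)
  }
  if (!is.null(locus)) {
    if (!locus %in% names(dataset)) {
      stop("locus column ", sQuote(locus), " not found in dataset",
           call. = FALSE)
    }
    g <- dataset[[locus]]
    bad <- !is.na(g) & !(g %in% GENOTYPES)
    if (any(bad)) {
      stop("locus ", sQuote(locus), " holds non-canonical genotypes; ",
           "run canonical_genotype() first", call. = FALSE)
    }
  }
  invisible(dataset)
}

## Genotype counts (AA, Aa, aa) within one status stratum.
genotype_counts <- function(dataset, locus, status = c("case", "control")) {
  status <- match.arg(status)
  g <- dataset[[locus]][dataset$status == status]
  tab <- table(factor(g, levels = GENOTYPES))
  stats::setNames(as.integer(tab), GENOTYPES)
}
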