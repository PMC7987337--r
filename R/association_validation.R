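#' Cross-tabulate carrier status by study arm
#'
#' Builds the 2x2 table with arms in rows (severe first) and carrier status
#' in columns (non-carrier first), the layout used for the exact test.
#'
#' @param carrier logical (or 0/1) vector of carrier flags.
#' @param arm vector with values \code{"severe"} / \code{"asymptomatic"},
#'   aligned with \code{carrier}.
#' @return 2x2 integer matrix with dimnames.
#' @export
carrier_table <- function(carrier, arm) {
  if (length(carrier) == 0L) stop("empty input", call. = FALSE)
  if (length(carrier) != length(arm))
    stop("'carrier' and 'arm' must align", call. = FALSE)
  bad <- setdiff(unique(as.character(arm)), c("severe", "asymptomatic"))
  if (length(bad))
    stop("arm labels must be severe/asymptomatic; excluded subjects must be ",
         "filtered upstream (found: ", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  carrier <- as.logical(carrier)
  arm <- factor(arm, levels = c("severe", "asymptomatic"))
  tab <- table(arm, factor(carrier, levels = c(FALSE, TRUE)))
  out <- matrix(as.integer(tab), 2, 2,
                dimnames = list(arm = c("severe", "asymptomatic"),
                                carrier = c("non_carrier", "carrier")))
  out
}

check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0) stop("zero grand total", call. = FALSE)
  tab
}

#' Two-sided Fisher exact test by point-probability enumeration
#'
#' Conditional on the observed margins, the first cell of the table follows a
#' hypergeometric distribution; the two-sided p-value sums the point
#' probabilities of every table (over the full support) whose probability
#' does not exceed the observed table's, within a relative slack of 1e-7.
#' Evaluation is exact (log-space hypergeometric mass), with no normal
#' approximation.
#'
#' @param tab 2x2 non-negative integer matrix, e.g. from [carrier_table()].
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- check_table(tab)
  m <- sum(tab[, 2])            # carriers
  nn <- sum(tab[, 1])           # non-carriers
  k <- sum(tab[1, ])            # severe arm size
  x <- tab[1, 2]                # severe carriers
  support <- max(0, k - nn):min(k, m)
  pp <- dhyper(support, m, nn, k)
  p_obs <- dhyper(x, m, nn, k)
  min(1, sum(pp[pp <= p_obs * (1 + 1e-7)]))
}

#' Carrier odds ratio with optional continuity correction
#'
#' Odds of carrying a qualifying variant in the severe arm relative to the
#' asymptomatic arm. When any cell is zero and \code{correction} is on, 0.5
#' is added to every cell (Haldane-Anscombe). A table whose carrier (or
#' non-carrier) column is entirely zero has no defined odds ratio and is
#' returned as \code{NA} with \code{undefined = TRUE}; with the correction
#' off, a single zero cell yields an infinite estimate, flagged the same way.
#'
#' @param tab 2x2 matrix as from [carrier_table()].
#' @param correction apply the Haldane-Anscombe correction (default TRUE).
#' @return list with \code{or}, \code{corrected}, \code{undefined}.
#' @export
odds_ratio <- function(tab, correction = TRUE) {
  tab <- check_table(tab)
  if (any(rowSums(tab) == 0))
    stop("an arm has no subjects", call. = FALSE)
  if (any(colSums(tab) == 0))
    return(list(or = NA_real_, corrected = FALSE, undefined = TRUE))
  corrected <- FALSE
  if (any(tab == 0)) {
    if (correction) {
      tab <- tab + 0.5
      corrected <- TRUE
    } else {
      a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
      or <- (b / a) / (d / c)
      return(list(or = or, corrected = FALSE, undefined = !is.finite(or)))
    }
  }
  or <- (tab[1, 2] / tab[1, 1]) / (tab[2, 2] / tab[2, 1])
  list(or = or, corrected = corrected, undefined = FALSE)
}

#' Published roster of candidate-gene variants
#'
#' Packaged fixture with one row per patient-variant pair for the validated
#' X-linked candidate gene: eight severely affected male cases (two pairs of
#' patients share a variant) and one asymptomatic carrier control. Columns:
#' patient_id, gene, nucleotide_change, protein_change, dbsnp, consequence,
#' cadd, nfe_af (NA when not reported), functional_class (LOF / HYPO /
#' Neutral, experimentally determined and consumed as annotation, never
#' computed), clinical_category, age, cohort, arm. The control's exact age is
#' not published beyond being 60 or above and is recorded as 61.
#'
#' @return data frame with 9 rows.
#' @export
tlr7_roster <- function() {
  path <- system.file("extdata", "tlr7_case_variants.tsv",
                      package = "xburden", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Stratified carrier counts and fractions
#'
#' For each stratum (subjects younger than the age cutoff versus all ages)
#' and each qualification rule (the candidate rule - rare or missing
#' population frequency, qualifying consequence, CADD at or above threshold -
#' versus restriction to experimentally determined functional classes),
#' counts distinct carrier patients in the case arm and reports the fraction
#' of the corresponding cohort denominator as a percentage rounded to one
#' decimal (round-half-even).
#'
#' @param roster patient-variant table as from [tlr7_roster()]: requires
#'   columns patient_id, age, arm, consequence, nfe_af, cadd,
#'   functional_class.
#' @param denominators named vector \code{c(young = ..., all = ...)}: cohort
#'   sizes the carrier counts are referred to.
#' @param cfg an [filter_config()].
#' @param functional_classes classes counted as functionally deleterious
#'   (default LOF and HYPO).
#' @return data frame with columns stratum, rule, carriers, denominator,
#'   percent.
#' @export
summarize_carriers <- function(roster, denominators = c(young = 135,
                                                        all = 261),
                               cfg = filter_config(),
                               functional_classes = c("LOF", "HYPO")) {
  known <- c("LOF", "HYPO", "Neutral")
  bad <- setdiff(unique(roster$functional_class), known)
  if (length(bad))
    stop("unknown functional class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(c("young", "all") %in% names(denominators)))
    stop("'denominators' needs elements 'young' and 'all'", call. = FALSE)
  cases <- roster[roster$arm == "case", , drop = FALSE]
  candidate <- qualifies_as_candidate(cases, cfg)
  functional <- candidate & cases$functional_class %in% functional_classes
  young <- cases$age < cfg$age_cutoff
  count <- function(sel) length(unique(cases$patient_id[sel]))
  strata <- expand.grid(stratum = c("young", "all"),
                        rule = c("candidate", "functional"),
                        stringsAsFactors = FALSE)
  strata$carriers <- mapply(function(st, rl) {
    sel <- if (rl == "candidate") candidate else functional
    if (st == "young") sel <- sel & young
    count(sel)
  }, strata$stratum, strata$rule)
  strata$denominator <- unname(denominators[strata$stratum])
  strata$percent <- round(100 * strata$carriers / strata$denominator, 1)
  strata
}
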