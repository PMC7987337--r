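#' Variant-qualification and subject-inclusion settings
#'
#' Thresholds of the burden analysis: variants count toward a gene's burden
#' when their consequence class is in \code{qualifying_consequences} and
#' their population allele frequency is at most \code{maf_threshold} (a
#' missing frequency counts as rare when \code{missing_maf_is_rare}).
#' Candidate (deleterious) variants additionally require a CADD score of at
#' least \code{cadd_threshold}. The CADD rule is inclusive: a variant scored
#' exactly at the threshold is counted. Subjects enter the young-male
#' analysis only below \code{age_cutoff} years.
#'
#' @param maf_threshold maximum population allele frequency (default 0.01).
#' @param qualifying_consequences consequence classes that contribute burden.
#' @param cadd_threshold minimum CADD phred score for candidate variants.
#' @param missing_maf_is_rare whether a missing frequency counts as rare.
#' @param age_cutoff age (years) below which subjects are analysed.
#' @return list of class \code{xburden_filter}.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          qualifying_consequences = c("missense", "splicing",
                                                      "LOF"),
                          cadd_threshold = 12.28,
                          missing_maf_is_rare = TRUE,
                          age_cutoff = 60) {
  stopifnot(maf_threshold >= 0, cadd_threshold >= 0, age_cutoff >= 0)
  structure(list(maf_threshold = maf_threshold,
                 qualifying_consequences = qualifying_consequences,
                 cadd_threshold = cadd_threshold,
                 missing_maf_is_rare = isTRUE(missing_maf_is_rare),
                 age_cutoff = age_cutoff),
            class = "xburden_filter")
}

# map annotation dialects onto the consequence classes used by the filters;
# splice-donor/acceptor/region all count as "splicing"
normalize_consequence <- function(x) {
  x <- tolower(x)
  x[x %in% c("splice_donor", "splice_acceptor", "splice_region",
             "splice_donor_variant", "splice_acceptor_variant",
             "splice_region_variant", "splicing")] <- "splicing"
  x[x %in% c("stop_gained", "frameshift", "frameshift_variant",
             "start_lost", "stop_lost", "lof", "loss_of_function")] <- "LOF"
  x[x %in% c("missense_variant", "missense")] <- "missense"
  x[x %in% c("synonymous_variant", "synonymous")] <- "synonymous"
  x
}

#' Classify subjects into study arms
#'
#' A subject is a \code{case} if male, younger than the age cutoff,
#' PCR-confirmed and in clinical category 3 or 4 (hospitalised with
#' CPAP/BiPAP or intubation); a \code{control} if male, younger than the
#' cutoff, PCR-confirmed and category 0 (oligo-asymptomatic, not
#' hospitalised); anything else (categories 1--2, unconfirmed infection, age
#' at or above the cutoff, non-male) is \code{excluded}.
#'
#' @param subjects subject data frame (see [read_subjects()]).
#' @param cfg an [filter_config()].
#' @return factor with levels case, control, excluded.
#' @export
classify_subjects <- function(subjects, cfg = filter_config()) {
  cat_ <- subjects$clinical_category
  if (any(!cat_ %in% 0:4))
    stop("clinical_category outside 0..4", call. = FALSE)
  eligible <- subjects$sex == "M" & subjects$age < cfg$age_cutoff &
    as.logical(subjects$pcr_confirmed)
  out <- rep("excluded", nrow(subjects))
  out[eligible & cat_ %in% c(3L, 4L)] <- "case"
  out[eligible & cat_ == 0L] <- "control"
  factor(out, levels = c("case", "control", "excluded"))
}

#' Variant qualification rules
#'
#' `qualifies_for_burden()` applies the boolean-representation rule: the
#' consequence must be missense, splicing or loss-of-function (configurable)
#' and the population allele frequency at most the rarity threshold, with a
#' missing frequency counting as rare by default. `qualifies_as_candidate()`
#' additionally requires a CADD score at or above the deleteriousness
#' threshold; a missing CADD never qualifies and raises a warning.
#'
#' @param variants variant data frame with columns consequence, nfe_af, cadd.
#' @param cfg an [filter_config()].
#' @return logical vector, one element per variant row.
#' @export
qualifies_for_burden <- function(variants, cfg = filter_config()) {
  csq_ok <- normalize_consequence(variants$consequence) %in%
    normalize_consequence(cfg$qualifying_consequences)
  af <- variants$nfe_af
  rare <- ifelse(is.na(af), cfg$missing_maf_is_rare, af <= cfg$maf_threshold)
  csq_ok & rare
}

#' @rdname qualifies_for_burden
#' @export
qualifies_as_candidate <- function(variants, cfg = filter_config()) {
  burden <- qualifies_for_burden(variants, cfg)
  missing_cadd <- is.na(variants$cadd)
  if (any(missing_cadd & burden))
    warning("variant(s) with missing CADD score treated as non-candidate",
            call. = FALSE)
  burden & !missing_cadd & variants$cadd >= cfg$cadd_threshold
}

#' Collapse qualifying variants into a boolean gene matrix
#'
#' Entry (subject, gene) is 1 when the subject carries at least one variant
#' in that gene passing [qualifies_for_burden()], 0 otherwise; the collapse
#' is idempotent in the number of qualifying variants. Columns are the genes
#' observed in the input (or a supplied gene universe) in lexicographic
#' order; rows follow the subject table.
#'
#' @param variants variant data frame with a \code{carriers} list-column.
#' @param subjects subject data frame; every carrier ID must resolve here.
#' @param cfg an [filter_config()].
#' @param genes optional explicit gene universe fixing the column space.
#' @return integer matrix (subjects x genes) of 0/1 indicators.
#' @export
build_boolean_matrix <- function(variants, subjects, cfg = filter_config(),
                                 genes = NULL) {
  ids <- subjects$subject_id
  if (anyDuplicated(ids)) stop("duplicate subject IDs", call. = FALSE)
  if (is.null(genes)) genes <- unique(variants$gene)
  genes <- sort(unique(as.character(genes)))
  mat <- matrix(0L, nrow = length(ids), ncol = length(genes),
                dimnames = list(ids, genes))
  if (nrow(variants) == 0L) return(mat)
  unknown <- setdiff(unlist(variants$carriers), ids)
  if (length(unknown))
    stop("carrier ID(s) not in subject table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keep <- which(qualifies_for_burden(variants, cfg))
  for (i in keep) {
    carr <- variants$carriers[[i]]
    g <- variants$gene[i]
    if (!g %in% genes) next  # outside the supplied universe
    mat[carr, g] <- 1L
  }
  mat
}
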