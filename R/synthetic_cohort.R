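#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the simulated study: a male-only cohort of
#' severe (clinical category 3--4) and oligo-asymptomatic (category 0)
#' SARS-CoV-2-positive subjects, sparse rare-variant burden across a panel of
#' X-chromosome genes, one planted susceptibility gene with excess carriers
#' among cases, variant annotations (population frequency, CADD,
#' consequence), and qPCR Ct plates in which functional-variant carriers show
#' blunted agonist-induced expression.
#'
#' @param n_cases,n_controls arm sizes (defaults 79 and 77, the first-wave
#'   young-male design).
#' @param n_genes number of genes in the boolean representation.
#' @param planted_gene_index column index of the planted susceptibility gene.
#' @param carrier_freq_cases,carrier_freq_controls probability that a case
#'   (control) carries a qualifying variant in the planted gene.
#' @param background_burden_rate per-subject, per-gene probability of a
#'   qualifying background variant in every non-planted gene.
#' @param maf_range range of the log-uniform rare allele-frequency sampler.
#' @param missing_maf_rate fraction of qualifying variants whose population
#'   frequency is emitted as missing (exercises the missing-AF rule).
#' @param cadd_deleterious,cadd_benign uniform ranges for CADD scores of
#'   qualifying records and distractors; the defaults straddle the 12.28
#'   deleteriousness threshold.
#' @param consequence_mix named proportions over consequence classes used for
#'   qualifying records; only the mass on \code{missense}, \code{splicing}
#'   and \code{LOF} is used (renormalised).
#' @param distractor_rate per-subject, per-gene probability of an additional
#'   non-qualifying record (synonymous rare or common missense).
#' @param second_variant_rate probability that a burdened subject-gene pair
#'   receives a second qualifying variant (tests the "at least one" collapse).
#' @param n_older number of extra subjects aged 60 or above (alternating
#'   arms), exercising the age filter; default 0.
#' @param qpcr_baseline_log2 expected agonist-induced expression gain of
#'   target genes in non-carriers, in log2 units (Ct drop on stimulation).
#' @param qpcr_effect_log2 expected reduction of that induction in
#'   functional-variant carriers, in log2 units.
#' @param ct_noise_sd Gaussian noise SD per Ct replicate, in cycles.
#' @param replicates technical replicates per well.
#' @param target_genes,housekeeping qPCR panel and housekeeping gene.
#' @param seed integer seed; identical seeds reproduce outputs byte-for-byte.
#' @return an object of class \code{xburden_config} (a validated list).
#' @export
synth_config <- function(n_cases = 79L, n_controls = 77L, n_genes = 300L,
                         planted_gene_index = 1L,
                         carrier_freq_cases = 0.06,
                         carrier_freq_controls = 0,
                         background_burden_rate = 0.02,
                         maf_range = c(1e-6, 0.01),
                         missing_maf_rate = 0.1,
                         cadd_deleterious = c(12.28, 30),
                         cadd_benign = c(0, 12.27),
                         consequence_mix = c(missense = 0.7, splicing = 0.15,
                                             LOF = 0.15),
                         distractor_rate = 0.02,
                         second_variant_rate = 0,
                         n_older = 0L,
                         qpcr_baseline_log2 = 3,
                         qpcr_effect_log2 = 2,
                         ct_noise_sd = 0.2,
                         replicates = 3L,
                         target_genes = c("TLR7", "IRF7", "ISG15", "IFNA1",
                                          "IFNG"),
                         housekeeping = "HPRT1",
                         seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes),
              planted_gene_index = as.integer(planted_gene_index),
              carrier_freq_cases = carrier_freq_cases,
              carrier_freq_controls = carrier_freq_controls,
              background_burden_rate = background_burden_rate,
              maf_range = maf_range,
              missing_maf_rate = missing_maf_rate,
              cadd_deleterious = cadd_deleterious,
              cadd_benign = cadd_benign,
              consequence_mix = consequence_mix,
              distractor_rate = distractor_rate,
              second_variant_rate = second_variant_rate,
              n_older = as.integer(n_older),
              qpcr_baseline_log2 = qpcr_baseline_log2,
              qpcr_effect_log2 = qpcr_effect_log2,
              ct_noise_sd = ct_noise_sd,
              replicates = as.integer(replicates),
              target_genes = target_genes,
              housekeeping = housekeeping,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "xburden_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  counts <- c("n_cases", "n_controls", "n_genes", "replicates")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1)
      stop(sprintf("'%s' must be a positive count", f), call. = FALSE)
  }
  probs <- c("carrier_freq_cases", "carrier_freq_controls",
             "background_burden_rate", "missing_maf_rate", "distractor_rate",
             "second_variant_rate")
  for (f in probs) {
    p <- cfg[[f]]
    if (!is.numeric(p) || !is.finite(p) || p < 0 || p > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", f), call. = FALSE)
  }
  if (cfg$planted_gene_index < 1L || cfg$planted_gene_index > cfg$n_genes)
    stop("'planted_gene_index' must lie in 1..n_genes", call. = FALSE)
  if (cfg$ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0", call. = FALSE)
  if (cfg$n_older < 0L) stop("'n_older' must be >= 0", call. = FALSE)
  qual <- intersect(names(cfg$consequence_mix),
                    c("missense", "splicing", "LOF"))
  if (length(qual) == 0L || sum(cfg$consequence_mix[qual]) <= 0)
    stop("'consequence_mix' must put positive mass on missense/splicing/LOF",
         call. = FALSE)
  invisible(cfg)
}

gene_symbols <- function(n) sprintf("XG%04d", seq_len(n))

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Generate a synthetic extreme-phenotype cohort
#'
#' Draws a male-only case-control cohort with independent per-gene boolean
#' burden at \code{background_burden_rate}, except the planted gene which
#' uses the arm-specific carrier frequencies. Every burdened subject-gene
#' pair is materialised as at least one variant record whose annotations pass
#' the qualification filters (rare or missing population frequency,
#' missense/splicing/LOF consequence, CADD at or above 12.28); additional
#' non-qualifying distractor records (rare synonymous, common missense with
#' benign CADD) are emitted alongside.
#'
#' @param config an [synth_config()] object.
#' @return a list of class \code{xburden_cohort} with elements
#'   \code{variants} (data frame, one row per alternate allele, with a
#'   \code{carriers} list-column of subject IDs), \code{subjects} (phenotype
#'   data frame), \code{config}, and attribute \code{burden}: the true
#'   subjects x genes 0/1 matrix used to materialise the records.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  with_seed(config$seed, {
    subjects <- draw_subjects(config)
    n <- nrow(subjects)
    genes <- gene_symbols(config$n_genes)
    is_case_arm <- subjects$clinical_category >= 3L

    burden <- matrix(runif(n * config$n_genes) <
                       config$background_burden_rate,
                     nrow = n, ncol = config$n_genes,
                     dimnames = list(subjects$subject_id, genes))
    planted <- config$planted_gene_index
    freq <- ifelse(is_case_arm, config$carrier_freq_cases,
                   config$carrier_freq_controls)
    burden[, planted] <- runif(n) < freq

    variants <- materialise_variants(burden, subjects, config, genes)
    out <- list(variants = variants, subjects = subjects, config = config)
    attr(out, "burden") <- burden + 0L
    attr(out, "planted_gene") <- genes[planted]
    class(out) <- "xburden_cohort"
    out
  })
}

draw_subjects <- function(config) {
  n_young <- config$n_cases + config$n_controls
  arm <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  age <- sample(20:59, n_young, replace = TRUE)
  if (config$n_older > 0L) {
    arm <- c(arm, rep(c("case", "control"), length.out = config$n_older))
    age <- c(age, sample(60:85, config$n_older, replace = TRUE))
  }
  n <- length(arm)
  category <- ifelse(arm == "case", sample(3:4, n, replace = TRUE), 0L)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             sex = "M",
             age = as.integer(age),
             clinical_category = as.integer(category),
             cohort = "wave1",
             pcr_confirmed = TRUE,
             stringsAsFactors = FALSE)
}

materialise_variants <- function(burden, subjects, config, genes) {
  qual_classes <- intersect(names(config$consequence_mix),
                            c("missense", "splicing", "LOF"))
  qual_w <- config$consequence_mix[qual_classes]
  qual_w <- qual_w / sum(qual_w)
  n <- nrow(burden)

  rows <- list()
  # gene windows keep positions unique and sorted per gene
  win <- 100000L
  rare_af <- function(k)
    exp(runif(k, log(config$maf_range[1]), log(config$maf_range[2])))
  for (g in seq_along(genes)) {
    carriers <- rownames(burden)[burden[, g] > 0]
    extra <- rownames(burden)[runif(n) < config$distractor_rate]
    second <- if (length(carriers))
      runif(length(carriers)) < config$second_variant_rate
    else logical(0)
    qual_subj <- c(carriers, carriers[second])
    nq <- length(qual_subj)
    nd <- length(extra)
    total <- nq + nd
    if (total == 0L) next
    pos <- sort(sample.int(win - 1L, total)) + (g - 1L) * win + 1000000L
    al <- random_alleles(total)

    # qualifying records: rare (or missing) AF, damaging consequence and CADD
    af_q <- rare_af(nq)
    af_q[runif(nq) < config$missing_maf_rate] <- NA_real_
    csq_q <- if (nq) sample(qual_classes, nq, replace = TRUE, prob = qual_w)
             else character(0)
    cadd_q <- runif(nq, config$cadd_deleterious[1], config$cadd_deleterious[2])

    # distractors: rare synonymous or common missense, benign CADD
    syn <- runif(nd) < 0.5
    af_d <- ifelse(syn, rare_af(nd), runif(nd, 0.011, 0.2))
    csq_d <- ifelse(syn, "synonymous", "missense")
    cadd_d <- runif(nd, config$cadd_benign[1], config$cadd_benign[2])

    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "X", pos = pos, ref = al$ref, alt = al$alt, gene = genes[g],
      consequence = c(csq_q, csq_d), nfe_af = c(af_q, af_d),
      cadd = c(cadd_q, cadd_d),
      carriers = I(as.list(c(qual_subj, extra))),
      stringsAsFactors = FALSE)
  }

  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), consequence = character(),
                      nfe_af = numeric(), cadd = numeric(),
                      carriers = I(list()), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Ct plate for genotyped subjects
#'
#' Emits replicate Ct values per subject x gene x condition for a target
#' panel plus a housekeeping gene, under the Livak model: target Ct drops by
#' \code{qpcr_baseline_log2} cycles on stimulation in non-carriers (and
#' neutral-variant carriers), and by \code{qpcr_baseline_log2 -
#' qpcr_effect_log2} in functional-variant carriers; the housekeeping gene is
#' condition-independent in expectation. Gaussian noise with SD
#' \code{ct_noise_sd} is added per replicate.
#'
#' @param config an [synth_config()] object.
#' @param genotype named character vector mapping subject IDs to
#'   \code{"functional"}, \code{"neutral"} or \code{"non_carrier"}.
#' @param seed seed for the plate; defaults to \code{config$seed}.
#' @return data frame with columns subject_id, gene, condition
#'   (\code{stimulated}/\code{medium}), replicate, ct.
#' @export
generate_qpcr_plate <- function(config, genotype, seed = config$seed) {
  validate_config(config)
  if (length(genotype) == 0L || is.null(names(genotype)))
    stop("'genotype' must be a non-empty named vector", call. = FALSE)
  bad <- setdiff(unique(genotype),
                 c("functional", "neutral", "non_carrier"))
  if (length(bad))
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (config$ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0")

  hk_ct <- 24; target_medium_ct <- 28
  genes <- c(config$target_genes, config$housekeeping)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      condition = c("stimulated", "medium"),
                      gene = genes,
                      subject_id = names(genotype),
                      stringsAsFactors = FALSE)
  induction <- ifelse(genotype[grid$subject_id] == "functional",
                      config$qpcr_baseline_log2 - config$qpcr_effect_log2,
                      config$qpcr_baseline_log2)
  mu <- ifelse(grid$gene == config$housekeeping, hk_ct,
               ifelse(grid$condition == "stimulated",
                      target_medium_ct - induction, target_medium_ct))
  with_seed(seed, {
    ct <- mu + rnorm(nrow(grid), sd = config$ct_noise_sd)
    data.frame(subject_id = grid$subject_id, gene = grid$gene,
               condition = grid$condition, replicate = grid$replicate,
               ct = ct, stringsAsFactors = FALSE)
  })
}
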