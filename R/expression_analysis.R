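#' Relative quantification by the 2^-ddCt method
#'
#' For each subject and target gene, technical replicate Ct values are
#' averaged per gene and condition; the target is normalized to the
#' housekeeping gene within each condition (dCt = Ct_target - Ct_housekeeping),
#' the stimulated condition is referred to the medium condition
#' (ddCt = dCt_stimulated - dCt_medium), and the fold change is 2^-ddCt, so
#' log2(fold change) = -ddCt exactly.
#'
#' @param ct long-format Ct table with columns subject_id, gene, condition,
#'   replicate, ct (see [generate_qpcr_plate()]).
#' @param targets target gene symbols; default: every gene in the table
#'   except the housekeeping gene.
#' @param housekeeping housekeeping gene symbol (default \code{"HPRT1"}).
#' @param stimulated,medium condition labels.
#' @return data frame with one row per subject x target: dct_stimulated,
#'   dct_medium, ddct, fold_change.
#' @export
fold_change_ddct <- function(ct, targets = NULL, housekeeping = "HPRT1",
                             stimulated = "stimulated", medium = "medium") {
  needed <- c("subject_id", "gene", "condition", "ct")
  if (!all(needed %in% names(ct)))
    stop("Ct table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  if (is.null(targets)) targets <- setdiff(unique(ct$gene), housekeeping)

  # replicate average per subject x gene x condition
  means <- stats::aggregate(ct ~ subject_id + gene + condition, data = ct,
                            FUN = mean)
  lookup <- function(subject, gene, condition) {
    v <- means$ct[means$subject_id == subject & means$gene == gene &
                    means$condition == condition]
    if (length(v) != 1L)
      stop(sprintf("missing Ct for subject %s, gene %s, condition %s",
                   subject, gene, condition), call. = FALSE)
    v
  }
  rows <- expand.grid(subject_id = unique(ct$subject_id), gene = targets,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    s <- rows$subject_id[i]; g <- rows$gene[i]
    dct_s <- lookup(s, g, stimulated) - lookup(s, housekeeping, stimulated)
    dct_m <- lookup(s, g, medium) - lookup(s, housekeeping, medium)
    ddct <- dct_s - dct_m
    data.frame(subject_id = s, gene = g, dct_stimulated = dct_s,
               dct_medium = dct_m, ddct = ddct, fold_change = 2^(-ddct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Unpaired t-test on log-transformed fold changes
#'
#' Two-sample comparison of fold changes on the log2 scale (the t statistic
#' and p-value are invariant to the log base): pooled-variance Student t by
#' default, Welch available via \code{welch = TRUE}; two-sided p-value from
#' the t distribution; significance stars at the 0.05 / 0.01 / 0.001 / 0.0001
#' levels.
#'
#' @param group_a,group_b fold changes (positive), at least two per group.
#' @param welch use the Welch unequal-variance test instead of pooled.
#' @return list with \code{t}, \code{df}, \code{p}, \code{stars}.
#' @export
compare_groups_log_t <- function(group_a, group_b, welch = FALSE) {
  for (g in list(group_a, group_b)) {
    if (length(g) < 2L) stop("each group needs at least 2 values",
                             call. = FALSE)
    if (any(!is.finite(g)) || any(g <= 0))
      stop("fold changes must be positive and finite", call. = FALSE)
  }
  la <- log2(group_a); lb <- log2(group_b)
  if (stats::var(la) + stats::var(lb) == 0)
    stop("zero pooled variance", call. = FALSE)
  tt <- t.test(la, lb, var.equal = !welch)
  p <- tt$p.value
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = significance_stars(p))
}

#' @rdname compare_groups_log_t
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  cut_points <- c(1e-4, 1e-3, 1e-2, 5e-2)
  labels <- c("****", "***", "**", "*")
  vapply(p, function(pi) {
    hit <- which(pi < cut_points)
    if (length(hit)) labels[hit[1]] else "ns"
  }, character(1))
}
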