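#' Principal-component scores of the boolean gene matrix
#'
#' Projects subjects onto the top-k right singular directions of the
#' column-centered (unscaled) matrix, ordered by decreasing explained
#' variance. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param mat numeric matrix, subjects in rows (a boolean gene matrix).
#' @param k number of components (default 3).
#' @return list of class \code{xburden_pca} with \code{scores} (subjects x k),
#'   \code{sdev} (component SDs) and \code{center}.
#' @export
pca_scores <- function(mat, k = 3L) {
  mat <- as.matrix(mat) * 1.0
  if (nrow(mat) < k + 1L)
    stop("need at least k + 1 subjects for k components", call. = FALSE)
  vars <- apply(mat, 2, stats::var)
  if (all(vars == 0))
    stop("no variance: all columns are constant", call. = FALSE)
  pc <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = k)
  kk <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(kk), drop = FALSE]
  flip <- vapply(seq_len(kk), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(kk), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- rownames(mat)
  structure(list(scores = scores, sdev = pc$sdev[seq_len(kk)],
                 center = pc$center),
            class = "xburden_pca")
}

#' Flag PCA outliers
#'
#' A subject is flagged when, on any retained component, its score deviates
#' from the component mean by strictly more than \code{k_sd} standard
#' deviations. Mean and SD are computed over all subjects per component
#' (population SD; the scores are centered, so the rule reduces to
#' \code{|score| > k_sd * SD}). Flagging is a single pass: statistics are not
#' recomputed after removal. A component with zero SD flags nobody.
#'
#' @param pca an [pca_scores()] result.
#' @param k_sd deviation multiplier (default 5).
#' @return named logical vector, TRUE for flagged subjects.
#' @export
flag_outliers <- function(pca, k_sd = 5) {
  stopifnot(inherits(pca, "xburden_pca"), k_sd > 0)
  s <- pca$scores
  if (nrow(s) < 3L) stop("need at least 3 subjects", call. = FALSE)
  n <- nrow(s)
  mu <- colMeans(s)
  sd_pop <- sqrt(colMeans(sweep(s, 2, mu)^2))
  dev <- abs(sweep(s, 2, mu))
  flags <- rowSums(dev > matrix(k_sd * sd_pop, n, ncol(s),
                                byrow = TRUE)) > 0
  names(flags) <- rownames(s)
  flags
}

#' One-step cohort QC: PCA outlier removal
#'
#' Convenience wrapper running [pca_scores()] and [flag_outliers()] and
#' returning the subjects to keep. A matrix with no varying column carries no
#' information to deviate from, so no subject is flagged in that degenerate
#' case.
#'
#' @param mat boolean gene matrix (subjects x genes).
#' @param k number of components (default 3).
#' @param k_sd deviation multiplier (default 5).
#' @return list with \code{keep} (subject IDs retained), \code{flagged}
#'   (logical vector) and \code{pca} (NULL for the degenerate case).
#' @export
qc_cohort <- function(mat, k = 3L, k_sd = 5) {
  vars <- apply(as.matrix(mat) * 1.0, 2, stats::var)
  if (all(vars == 0)) {
    flags <- rep(FALSE, nrow(mat))
    names(flags) <- rownames(mat)
    return(list(keep = rownames(mat), flagged = flags, pca = NULL))
  }
  pca <- pca_scores(mat, k = k)
  flags <- flag_outliers(pca, k_sd = k_sd)
  list(keep = rownames(mat)[!flags], flagged = flags, pca = pca)
}
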