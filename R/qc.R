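#' Principal components for a two-group contrast
#'
#' PCA over the samples of one two-group comparison, used to judge replicate
#' coherence before differential testing. Probes are centered across the
#' subset (no unit-variance scaling) and the decomposition is taken on the
#' sample dimension. A deterministic sign convention is applied: the loading
#' of largest magnitude on each component is made positive.
#'
#' @param x `rppa_expression` object or log2 matrix.
#' @param samples Sample table restricted (or restrictable) to the contrast.
#' @param groups Character vector of the two group labels to compare.
#' @return List with `scores` (samples x components), `fractions`
#'   (explained-variance fractions, summing to 1), `labels` (group per sample).
#' @export
group_pca <- function(x, samples, groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sub <- samples[samples$group %in% groups, , drop = FALSE]
  tab <- table(factor(sub$group, levels = groups))
  if (any(tab < 2)) stop("each group needs >= 2 samples for PCA QC")
  v <- expr_values(x)[, sub$sample_id, drop = FALSE]
  v <- v[stats::complete.cases(v), , drop = FALSE]
  y <- t(v)                                   # samples x probes
  y <- sweep(y, 2L, colMeans(y), "-")         # probe-wise centering
  sv <- svd(y)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  vload <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (k in seq_along(d)) {
    i <- which.max(abs(vload[, k]))
    if (vload[i, k] < 0) {
      vload[, k] <- -vload[, k]
      u[, k] <- -u[, k]
    }
  }
  scores <- u %*% diag(d, nrow = length(d))
  rownames(scores) <- sub$sample_id
  fractions <- d^2 / sum(d^2)
  list(scores = scores, fractions = fractions,
       labels = stats::setNames(sub$group, sub$sample_id))
}

#' Number of components reaching a cumulative variance threshold
#'
#' @param fractions Nonnegative explained-variance fractions summing to 1.
#' @param threshold Cumulative fraction to reach (inclusive); default 0.95.
#' @return Smallest k with `cumsum(fractions)[k] >= threshold`.
#' @export
components_for_threshold <- function(fractions, threshold = 0.95) {
  if (length(fractions) == 0) stop("empty fraction vector")
  if (any(fractions < -1e-12)) stop("fractions must be nonnegative")
  cs <- cumsum(fractions)
  k <- which(cs >= threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(fractions)
  as.integer(k)
}

#' Silhouette widths in component space
#'
#' Classic silhouette s(i) = (b - a) / max(a, b) with Euclidean distance,
#' where a is the mean distance of sample i to its own group and b the mean
#' distance to the other group. Degenerate 0/0 (all points coincident) is
#' defined as 0, and singleton groups get width 0 by convention.
#'
#' @param scores Samples x k numeric score matrix.
#' @param labels Group label per sample (2 groups).
#' @return Numeric vector of per-sample widths in \[-1, 1\].
#' @export
silhouette_widths <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("silhouette needs two groups")
  n <- nrow(scores)
  dmat <- as.matrix(stats::dist(scores))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    oth <- which(labels != labels[i])
    if (length(own) == 0) { s[i] <- 0; next }   # singleton convention
    a <- mean(dmat[i, own])
    b <- mean(dmat[i, oth])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  stats::setNames(s, rownames(scores))
}

#' Mahalanobis separation of two groups in two dimensions
#'
#' Distance between the two group centroids under the pooled within-class
#' covariance, computed on the first two components. A singular pooled
#' covariance is ridge-regularised by eps * trace/2 on the diagonal.
#'
#' @param scores2d Samples x 2 score matrix.
#' @param labels Group label per sample (2 groups, each >= 2 samples).
#' @param eps Relative ridge used only when the pooled covariance is singular.
#' @return List with `distance` (centroid separation, one number) and
#'   `per_sample` (each sample's Mahalanobis distance to its own centroid).
#' @export
mahalanobis_separation <- function(scores2d, labels, eps = 1e-8) {
  scores2d <- as.matrix(scores2d)
  if (ncol(scores2d) != 2) stop("scores2d must have exactly 2 columns")
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("need exactly 2 groups")
  if (any(table(labels) < 2)) stop("each group needs >= 2 samples")
  sp <- split(seq_along(labels), labels)
  cent <- lapply(sp, function(i) colMeans(scores2d[i, , drop = FALSE]))
  # pooled within-class covariance
  ss <- Reduce(`+`, lapply(sp, function(i) {
    d <- sweep(scores2d[i, , drop = FALSE], 2L, colMeans(scores2d[i, , drop = FALSE]), "-")
    crossprod(d)
  }))
  S <- ss / (length(labels) - 2L)
  if (abs(det(S)) < 1e-300 || rcond(S) < 1e-12)
    S <- S + diag(eps * sum(diag(S)) / 2, 2)
  Sinv <- solve(S)
  dm <- cent[[1L]] - cent[[2L]]
  dist <- sqrt(drop(t(dm) %*% Sinv %*% dm))
  per_sample <- vapply(seq_along(labels), function(i) {
    d <- scores2d[i, ] - cent[[labels[i]]]
    sqrt(drop(t(d) %*% Sinv %*% d))
  }, numeric(1))
  list(distance = dist, per_sample = stats::setNames(per_sample, rownames(scores2d)))
}

#' Replicate-coherence QC report for one two-group contrast
#'
#' Runs [group_pca()], computes silhouette widths on the components explaining
#' at least `var_threshold` of the variance and the two-dimensional Mahalanobis
#' centroid separation, and flags the contrast as low-coherence when the mean
#' silhouette falls below `coherence_cutoff` or any sample has a negative
#' width. A low-coherence flag is the trigger for sample precision weights in
#' the downstream fit.
#'
#' @param x Expression object.
#' @param samples Sample table.
#' @param groups The two group labels.
#' @param contrast_id Label for the report row.
#' @param var_threshold Cumulative explained-variance threshold (default 0.95).
#' @param coherence_cutoff Mean-silhouette cutoff below which the contrast is
#'   flagged (default 0.25).
#' @return One-row data.frame: `contrast_id, n_components_95, mean_silhouette,
#'   min_silhouette, mahalanobis_2d, coherent`, with per-sample widths as an
#'   attribute `"silhouette"`.
#' @export
qc_report <- function(x, samples, groups, contrast_id = paste(groups, collapse = "_vs_"),
                      var_threshold = 0.95, coherence_cutoff = 0.25) {
  pca <- group_pca(x, samples, groups)
  k <- components_for_threshold(pca$fractions, var_threshold)
  sil <- silhouette_widths(pca$scores[, seq_len(k), drop = FALSE], pca$labels)
  k2 <- min(2L, ncol(pca$scores))
  s2 <- pca$scores[, seq_len(k2), drop = FALSE]
  if (k2 < 2) s2 <- cbind(s2, 0)
  mah <- mahalanobis_separation(s2, pca$labels)
  out <- data.frame(
    contrast_id = contrast_id,
    n_components_95 = k,
    mean_silhouette = mean(sil),
    min_silhouette = min(sil),
    mahalanobis_2d = mah$distance,
    coherent = mean(sil) >= coherence_cutoff && all(sil >= 0),
    stringsAsFactors = FALSE
  )
  attr(out, "silhouette") <- sil
  out
}
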