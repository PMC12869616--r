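#' Exact two-sided Wilcoxon signed-rank p-value
#'
#' Tests whether paired differences are symmetric about zero. Zero differences
#' are dropped (classic treatment; set `zero_method = "signed_rank_zero"` to
#' keep them with rank contribution zero in the statistic but in the
#' enumeration denominator via midranks). Ties receive midranks. For n <= 25
#' the p-value is exact, from the full conditional null distribution of the
#' positive-rank sum given the observed midranks (computed by generating-
#' function convolution, equivalent to enumerating all 2^n sign assignments);
#' above that a normal approximation with continuity and tie correction is
#' used.
#'
#' @param diffs Numeric vector of differences.
#' @param exact_max Largest n for which the exact distribution is used.
#' @param zero_method `"drop"` (default) or `"signed_rank_zero"`.
#' @return Two-sided p-value in (0, 1\]; all-zero input returns 1.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25L,
                                 zero_method = c("drop", "signed_rank_zero")) {
  zero_method <- match.arg(zero_method)
  diffs <- diffs[!is.na(diffs)]
  if (zero_method == "drop") diffs <- diffs[diffs != 0]
  if (length(diffs) == 0 || all(diffs == 0)) return(1)
  n <- length(diffs)
  r <- rank(abs(diffs))            # midranks for ties (zeros rank lowest if kept)
  wpos <- sum(r[diffs > 0])
  if (zero_method == "signed_rank_zero") {
    # zeros contribute no signed rank; remove their ranks from the sign flips
    keep <- diffs != 0
    r <- r[keep]
    wpos <- sum(r[diffs[keep] > 0])
    n <- sum(keep)
    if (n == 0) return(1)
  }
  if (n <= exact_max) {
    # distribution of W+ over all 2^n sign assignments, integerised midranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)     # index k+1 holds count of W+ (doubled) == k
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * wpos))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[seq.int(w2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (wpos - mu - sign(wpos - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}

#' Identify invariant total-protein probes
#'
#' An invariant probe is a total-protein probe whose estimated within-batch
#' log2 fold-change is confidently small: its 95% confidence interval lies
#' entirely within `[-bound, +bound]` (inclusive) in every one of the three
#' within-batch two-group comparisons. Probes on the perturbation-sensitivity
#' exclusion list (any plausible mechanism for acute sensitivity to the
#' treatment) are removed regardless of their intervals. The resulting set
#' anchors the inter-batch shift diagnostics.
#'
#' @param batch_results List of three `rppa_contrast` results, one per
#'   within-batch two-group comparison (confidence intervals required).
#' @param annot Probe annotation (used to restrict to total-protein probes).
#' @param sensitivity_list Character vector of probe ids to exclude.
#' @param bound Half-width of the tolerated interval (log2 units).
#' @return List of class `invariant_set`: `probe_ids`, `ci_table` (long
#'   data.frame probe x batch with lfc and CI), `excluded_for_sensitivity`.
#' @export
find_invariant_probes <- function(batch_results, annot,
                                  sensitivity_list = character(), bound = 0.1) {
  if (length(batch_results) < 1) stop("need at least one within-batch result")
  for (r in batch_results)
    if (!all(c("ci_low", "ci_high", "lfc") %in% names(r)))
      stop("batch results must carry lfc, ci_low and ci_high columns")
  total_ids <- annot$probe_id[!annot$is_phospho]
  probes <- Reduce(intersect, lapply(batch_results, `[[`, "probe_id"))
  probes <- intersect(probes, total_ids)
  ci_table <- do.call(rbind, lapply(seq_along(batch_results), function(i) {
    r <- batch_results[[i]]
    r <- r[r$probe_id %in% probes, c("probe_id", "lfc", "ci_low", "ci_high")]
    r$batch_contrast <- names(batch_results)[i] %||% paste0("batch", i)
    r
  }))
  qual <- tapply(ci_table$ci_low >= -bound & ci_table$ci_high <= bound,
                 ci_table$probe_id, all)
  inv <- names(qual)[qual]
  dropped <- intersect(inv, sensitivity_list)
  inv <- setdiff(inv, sensitivity_list)
  structure(list(probe_ids = sort(inv), ci_table = ci_table,
                 excluded_for_sensitivity = sort(dropped)),
            class = "invariant_set")
}

#' @export
print.invariant_set <- function(x, ...) {
  cat(sprintf("invariant_set: %d probes (%d removed by sensitivity list)\n",
              length(x$probe_ids), length(x$excluded_for_sensitivity)))
  invisible(x)
}

#' Inter-batch shift summary over the invariant probe set
#'
#' For one ordered pair of groups sitting in different batches, computes the
#' per-probe difference of group means (A - B) over the invariant set and
#' summarises its distribution by the two-sided Wilcoxon signed-rank p-value
#' against zero, the median log2 fold-change, and the (unscaled) median
#' absolute deviation. The pair is flagged `notable` when p < 0.20 and
#' |median| >= 0.01.
#'
#' @param x Expression object or log2 matrix.
#' @param samples Sample table.
#' @param invariants An `invariant_set` (or character vector of probe ids).
#' @param groupA,groupB Group labels (A - B orientation).
#' @param p_cut,med_cut Notability rule parameters.
#' @return One-row data.frame: `row_group, col_group, n_probes, wilcoxon_p,
#'   median_lfc, mad, notable`.
#' @export
interbatch_shift <- function(x, samples, invariants, groupA, groupB,
                             p_cut = 0.20, med_cut = 0.01) {
  ids <- if (inherits(invariants, "invariant_set")) invariants$probe_ids else invariants
  if (length(ids) == 0) stop("empty invariant probe set")
  if (length(ids) < 5) warning("fewer than 5 invariant probes; shift summary is fragile")
  v <- expr_values(x)
  ids <- intersect(ids, rownames(v))
  sa <- samples$sample_id[samples$group == groupA]
  sb <- samples$sample_id[samples$group == groupB]
  if (!length(sa) || !length(sb)) stop("unknown group label(s)")
  d <- rowMeans(v[ids, sa, drop = FALSE], na.rm = TRUE) -
       rowMeans(v[ids, sb, drop = FALSE], na.rm = TRUE)
  d <- d[is.finite(d)]
  med <- stats::median(d)
  madu <- stats::median(abs(d - med))
  p <- wilcoxon_signed_rank(d)
  data.frame(row_group = groupA, col_group = groupB, n_probes = length(d),
             wilcoxon_p = p, median_lfc = med, mad = madu,
             notable = p < p_cut & abs(med) >= med_cut,
             stringsAsFactors = FALSE)
}

#' All-pairs inter-batch shift matrix
#'
#' The tabular twin of an invariant-probe shift heatmap: every ordered pair of
#' the supplied groups (row minus column), with the diagonal marked as self.
#' Medians are antisymmetric and p-values symmetric by construction.
#'
#' @inheritParams interbatch_shift
#' @param group_list Character vector of >= 2 group labels.
#' @return Long data.frame with one row per ordered pair plus self rows
#'   (`self = TRUE`, statistics `NA`).
#' @export
shift_matrix <- function(x, samples, invariants, group_list,
                         p_cut = 0.20, med_cut = 0.01) {
  if (length(group_list) < 2) stop("need >= 2 groups")
  rows <- list()
  for (a in group_list) for (b in group_list) {
    if (a == b) {
      rows[[paste(a, b)]] <- data.frame(
        row_group = a, col_group = b, n_probes = NA_integer_,
        wilcoxon_p = NA_real_, median_lfc = NA_real_, mad = NA_real_,
        notable = NA, self = TRUE, stringsAsFactors = FALSE)
    } else {
      r <- interbatch_shift(x, samples, invariants, a, b, p_cut, med_cut)
      r$self <- FALSE
      rows[[paste(a, b)]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
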