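#' Default composite-score parameters
#'
#' Knot defaults: the effect-size ramp rises between |LFC| = log2(1.1)
#' (about 0.138) and log2(1.5) (about 0.585); the evidence ramp rises between
#' -log10(FDR) = 1 (FDR 0.10) and 3 (FDR 0.001). Scores are scaled to
#' \[-100, 100\].
#'
#' @param lfc_a,lfc_b Lower/upper |LFC| knots (log2 units).
#' @param fdr_a,fdr_b Lower/upper -log10(FDR) knots.
#' @param scale Score scale factor.
#' @return List of class `score_params`.
#' @export
score_params <- function(lfc_a = log2(1.1), lfc_b = log2(1.5),
                         fdr_a = 1, fdr_b = 3, scale = 100) {
  stopifnot(lfc_a >= 0, fdr_a >= 0, scale > 0)
  if (lfc_a >= lfc_b || fdr_a >= fdr_b) stop("ramp knots require a < b")
  structure(list(lfc_a = lfc_a, lfc_b = lfc_b, fdr_a = fdr_a, fdr_b = fdr_b,
                 scale = scale), class = "score_params")
}

#' Raised-cosine ramp
#'
#' Smooth monotone map equal to 0 at or below knot `a`, 1 at or above knot
#' `b`, and the half-cosine transition 0.5 * (1 - cos(pi * (x - a) / (b - a)))
#' between. Used to bound effect-size and FDR evidence in \[0, 1\].
#'
#' @param x Numeric vector.
#' @param a,b Ramp knots, `a < b`.
#' @return Values in \[0, 1\], continuous and nondecreasing in `x`.
#' @export
raised_cosine <- function(x, a, b) {
  if (a >= b) stop("raised_cosine requires a < b")
  xc <- pmin(pmax(x, a), b)       # clamp so infinite evidence stays finite
  y <- 0.5 * (1 - cos(pi * (xc - a) / (b - a)))
  y[x <= a] <- 0
  y[x >= b] <- 1
  y
}

#' Composite effect-size / evidence score
#'
#' Combines |log2 fold-change| and -log10(FDR), each passed through its
#' raised-cosine ramp, into a single bounded score: `scale` times the
#' geometric mean of the two components, signed by the direction of the fold
#' change. The geometric mean penalises imbalance: a probe needs both a
#' meaningful effect size and statistical support to score highly, and either
#' component at 0 annihilates the score.
#'
#' @param lfc Log2 fold-change(s).
#' @param fdr FDR value(s) in (0, 1\]; an exact 0 is treated as infinite
#'   evidence (component 1).
#' @param params A [score_params()] object.
#' @return Data.frame with `lfc_component`, `fdr_component` (each in \[0, 1\])
#'   and `score` (signed, in \[-scale, scale\]).
#' @export
composite_score <- function(lfc, fdr, params = score_params()) {
  if (any(!is.na(fdr) & (fdr < 0 | fdr > 1))) stop("fdr must lie in (0, 1]")
  nl <- ifelse(fdr == 0, Inf, -log10(fdr))
  lc <- raised_cosine(abs(lfc), params$lfc_a, params$lfc_b)
  fc <- raised_cosine(nl, params$fdr_a, params$fdr_b)
  score <- sign(lfc) * params$scale * sqrt(lc * fc)
  data.frame(lfc_component = lc, fdr_component = fc, score = score)
}

#' Signed score matrix across contrasts
#'
#' Builds the probes x contrasts matrix of signed composite scores and ranks
#' probes by their largest absolute score across contrasts (ties broken
#' deterministically by probe id), mirroring "top probes" score heatmaps.
#'
#' @param results Named list of `rppa_contrast` results over a shared probe
#'   universe.
#' @param params A [score_params()] object.
#' @param top_n Number of top-ranked probes to expose in the `top` attribute.
#' @return Numeric matrix (probes x contrasts) of signed scores, with
#'   attribute `"top"` holding the `top_n` highest-ranked probe ids.
#' @export
score_matrix <- function(results, params = score_params(), top_n = 10L) {
  if (!length(results)) stop("no results supplied")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(results, function(r)
      attr(r, "contrast_id") %||% "contrast", character(1))
  probes <- results[[1L]]$probe_id
  for (r in results)
    if (!setequal(r$probe_id, probes)) stop("results are over different probe universes")
  mat <- sapply(results, function(r) {
    r <- r[match(probes, r$probe_id), ]
    composite_score(r$lfc, r$fdr, params)$score
  })
  mat <- matrix(mat, nrow = length(probes),
                dimnames = list(probes, names(results)))
  rank_key <- apply(abs(mat), 1L, max)
  ord <- order(-rank_key, probes)
  attr(mat, "top") <- probes[utils::head(ord, top_n)]
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
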