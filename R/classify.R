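#' Assemble the contrast quartet for one perturbation isoform
#'
#' Joins the four stimulus-related contrasts — I (stimulus effect in untreated
#' cells), Ia (stimulus effect under the perturbation), L (final-level
#' difference) and S (the second-order shift, Ia - I) — plus the two baseline
#' perturbation contrasts (perturbation - vehicle, perturbation - untreated)
#' into one per-probe table ready for classification. When all contrasts come
#' from the same fit, S.lfc equals Ia.lfc - I.lfc to numerical precision.
#'
#' @param I,Ia,L,S `rppa_contrast` results over a shared probe universe.
#' @param Av,Au Optional baseline contrasts (perturbation - vehicle and
#'   perturbation - untreated); `NULL` disables the saturation co-annotation.
#' @return Data.frame of class `contrast_quartet` with `<name>_lfc` /
#'   `<name>_fdr` column pairs.
#' @export
contrast_quartet <- function(I, Ia, L, S, Av = NULL, Au = NULL) {
  probes <- I$probe_id
  pick <- function(r, nm) {
    if (is.null(r)) {
      out <- data.frame(a = NA_real_, b = NA_real_)[rep(1, length(probes)), ]
    } else {
      if (!setequal(r$probe_id, probes)) stop("contrasts cover different probe universes")
      r <- r[match(probes, r$probe_id), ]
      out <- data.frame(a = r$lfc, b = r$fdr)
    }
    names(out) <- paste0(nm, c("_lfc", "_fdr"))
    out
  }
  out <- cbind(data.frame(probe_id = probes, stringsAsFactors = FALSE),
               pick(I, "I"), pick(Ia, "Ia"), pick(L, "L"), pick(S, "S"),
               pick(Av, "Av"), pick(Au, "Au"))
  rownames(out) <- NULL
  class(out) <- c("contrast_quartet", class(out))
  out
}

#' Classify how the perturbation modulates the stimulus response
#'
#' Applies an explicit, priority-ordered rule table to the contrast quartet of
#' every stimulus-responsive probe (I significant at `alpha`):
#'
#' 1. `no_effect` - the shift S is not significant.
#' 2. S significant and opposite in sign to I:
#'    `reversal` when Ia is itself significant and opposite to I (the
#'    stimulus response flips direction under the perturbation); otherwise
#'    `attenuation` when |Ia| < |I| (the response shrinks), upgraded to
#'    `robust_attenuation` when both L and S exceed the robust tier (fold
#'    change beyond `robust_fc` with FDR below `robust_fdr`).
#' 3. `augmentation` - S significant with the same sign as I.
#' 4. Anything else is `ambiguous`.
#'
#' Attenuation calls additionally receive a `saturation_possible`
#' co-annotation when the perturbation alone already moved the probe in the
#' stimulus direction in both baseline contrasts (Av and Au significant,
#' same-signed as I) and the final levels do not differ (L not significant):
#' the baseline is plausibly elevated to the stimulated level, so loss of
#' dynamic range cannot be distinguished from true attenuation.
#'
#' @param quartet A [contrast_quartet()] (one or many probes).
#' @param alpha Significance gate for I, S, Ia, L and the baselines.
#' @param robust_fdr,robust_fc Robust-tier FDR and fold-change thresholds
#'   (defaults 0.001 and 1.5, i.e. |lfc| > log2(1.5)).
#' @return Data.frame: `probe_id, category, rationale, saturation_possible`.
#'   Every probe matches exactly one rule (the rationale names it).
#' @export
classify_response <- function(quartet, alpha = 0.05, robust_fdr = 0.001,
                              robust_fc = 1.5) {
  q <- quartet
  if (any(is.na(q$I_fdr)) || any(q$I_fdr >= alpha))
    stop("classify_response requires a significant base stimulus response (I) ",
         "for every probe; route non-responsive probes through classify_basal()")
  n <- nrow(q)
  category <- character(n)
  rationale <- character(n)
  satur <- logical(n)
  lfc_r <- log2(robust_fc)
  for (i in seq_len(n)) {
    sI <- sign(q$I_lfc[i])
    sigS <- !is.na(q$S_fdr[i]) && q$S_fdr[i] < alpha
    sS <- sign(q$S_lfc[i])
    if (!sigS) {
      category[i] <- "no_effect"; rationale[i] <- "R1_shift_not_significant"
    } else if (sS != 0 && sS == -sI) {
      sigIa <- !is.na(q$Ia_fdr[i]) && q$Ia_fdr[i] < alpha
      if (sigIa && sign(q$Ia_lfc[i]) == -sI) {
        category[i] <- "reversal"; rationale[i] <- "R2_response_sign_flipped"
      } else if (abs(q$Ia_lfc[i]) < abs(q$I_lfc[i])) {
        robust <- !is.na(q$L_fdr[i]) && !is.na(q$S_fdr[i]) &&
          abs(q$L_lfc[i]) > lfc_r && abs(q$S_lfc[i]) > lfc_r &&
          q$L_fdr[i] < robust_fdr && q$S_fdr[i] < robust_fdr
        category[i] <- if (robust) "robust_attenuation" else "attenuation"
        rationale[i] <- if (robust) "R3b_attenuation_robust_tier" else "R3_response_shrunk"
      } else {
        category[i] <- "ambiguous"; rationale[i] <- "R5_shift_opposes_but_response_not_reduced"
      }
    } else if (sS != 0 && sS == sI) {
      category[i] <- "augmentation"; rationale[i] <- "R4_shift_same_direction"
    } else {
      category[i] <- "ambiguous"; rationale[i] <- "R5_zero_sign_shift"
    }
    if (category[i] %in% c("attenuation", "robust_attenuation") &&
        !is.na(q$Av_fdr[i]) && !is.na(q$Au_fdr[i]) &&
        q$Av_fdr[i] < alpha && q$Au_fdr[i] < alpha &&
        sign(q$Av_lfc[i]) == sI && sign(q$Au_lfc[i]) == sI &&
        !is.na(q$L_fdr[i]) && q$L_fdr[i] >= alpha) {
      satur[i] <- TRUE
      rationale[i] <- paste0(rationale[i], "+R6_baseline_elevated_saturation_possible")
    }
  }
  data.frame(probe_id = q$probe_id, category = category, rationale = rationale,
             saturation_possible = satur, stringsAsFactors = FALSE)
}

#' Classify the basal (stimulus-free) perturbation effect
#'
#' A basal effect is called only when the perturbation moves the probe
#' consistently in both baseline contrasts (against vehicle and against
#' untreated), both significant.
#'
#' @param Av_lfc,Av_fdr Perturbation - vehicle effect and FDR.
#' @param Au_lfc,Au_fdr Perturbation - untreated effect and FDR.
#' @param alpha Significance gate.
#' @return Character vector: `concordant_up`, `concordant_down`, `discordant`
#'   (both significant, signs disagree) or `none`.
#' @export
classify_basal <- function(Av_lfc, Av_fdr, Au_lfc, Au_fdr, alpha = 0.05) {
  both <- !is.na(Av_fdr) & !is.na(Au_fdr) & Av_fdr < alpha & Au_fdr < alpha
  agree <- sign(Av_lfc) == sign(Au_lfc) & sign(Av_lfc) != 0
  ifelse(both & agree & Av_lfc > 0, "concordant_up",
    ifelse(both & agree & Av_lfc < 0, "concordant_down",
      ifelse(both & !agree, "discordant", "none")))
}

#' Summarise response calls into a probe x isoform grid
#'
#' @param calls Data.frame with columns `probe_id, isoform, category` (and
#'   optionally `rationale`, `saturation_possible`).
#' @return Wide data.frame, one row per probe, one category column per
#'   isoform (category suffixed with `*` when saturation is co-annotated).
#' @export
summarize_calls <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(probe_id = character(0), stringsAsFactors = FALSE))
  lab <- calls$category
  if (!is.null(calls$saturation_possible))
    lab <- paste0(lab, ifelse(calls$saturation_possible, "*", ""))
  isoforms <- unique(calls$isoform)
  probes <- unique(calls$probe_id)
  out <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  for (iso in isoforms) {
    sub <- calls[calls$isoform == iso, ]
    out[[iso]] <- lab[calls$isoform == iso][match(probes, sub$probe_id)]
  }
  out
}
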