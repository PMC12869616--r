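#' Pipeline configuration
#'
#' @param fdr FDR cutoff for DE counts and classification gates.
#' @param invariant_bound Half-width of the invariant-probe CI criterion
#'   (log2 units).
#' @param center_first If `TRUE`, median-center before probe filtering
#'   (reproducing a center-then-filter ordering); default filters first and
#'   centers on the analysis probe set.
#' @param weight_policy `"auto"` (estimate precision weights for contrasts
#'   flagged low-coherence by QC), `"all"`, or `"off"`.
#' @param coherence_cutoff Mean-silhouette cutoff for the QC coherence flag.
#' @param trend,robust Moderation settings passed to [ebayes_moderate()].
#' @param context Probe-filtering context label (or `NULL`).
#' @param sensitivity_list Probe ids excluded from the invariant set for
#'   plausible acute perturbation sensitivity (empty default; supply the
#'   curated list for real data).
#' @param score_params Composite-score parameters.
#' @param top_n Probes shown in score-matrix top views.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr = 0.05, invariant_bound = 0.1,
                            center_first = FALSE, weight_policy = c("auto", "all", "off"),
                            coherence_cutoff = 0.25, trend = TRUE, robust = TRUE,
                            context = NULL, sensitivity_list = character(),
                            score_params = rppashift::score_params(), top_n = 10L) {
  weight_policy <- match.arg(weight_policy)
  stopifnot(fdr > 0, fdr < 1, invariant_bound > 0)
  structure(list(fdr = fdr, invariant_bound = invariant_bound,
                 center_first = center_first, weight_policy = weight_policy,
                 coherence_cutoff = coherence_cutoff, trend = trend,
                 robust = robust, context = context,
                 sensitivity_list = sensitivity_list,
                 score_params = score_params, top_n = as.integer(top_n)),
            class = "pipeline_config")
}

# the eight headline two-group/shift contrast families over the study groups
study_contrasts <- function() {
  list(
    vehicle_vs_untreated = list(groups = c("vehicle", "untreated"),
                                coef = c(vehicle = 1, untreated = -1)),
    ab40_vs_vehicle = list(groups = c("ab40", "vehicle"),
                           coef = c(ab40 = 1, vehicle = -1)),
    ab42_vs_vehicle = list(groups = c("ab42", "vehicle"),
                           coef = c(ab42 = 1, vehicle = -1)),
    insulin_vs_untreated = list(groups = c("insulin", "untreated"),
                                coef = c(insulin = 1, untreated = -1)),
    ab40_insulin_shift = list(groups = c("ab40_insulin", "ab40", "insulin", "untreated"),
                              coef = c(ab40_insulin = 1, ab40 = -1,
                                       insulin = -1, untreated = 1)),
    ab40ins_vs_insulin = list(groups = c("ab40_insulin", "insulin"),
                              coef = c(ab40_insulin = 1, insulin = -1)),
    ab42_insulin_shift = list(groups = c("ab42_insulin", "ab42", "insulin", "untreated"),
                              coef = c(ab42_insulin = 1, ab42 = -1,
                                       insulin = -1, untreated = 1)),
    ab42ins_vs_insulin = list(groups = c("ab42_insulin", "insulin"),
                              coef = c(ab42_insulin = 1, insulin = -1))
  )
}

fit_one_contrast <- function(expr, samples, spec, cfg, contrast_id) {
  sub <- samples[samples$group %in% spec$groups, ]
  qc <- try(qc_report(expr, sub, spec$groups[1:2], contrast_id,
                      coherence_cutoff = cfg$coherence_cutoff), silent = TRUE)
  low <- if (inherits(qc, "try-error")) FALSE else !qc$coherent
  w <- NULL
  if (cfg$weight_policy == "all" || (cfg$weight_policy == "auto" && low)) {
    w <- suppressWarnings(
      estimate_sample_weights(expr, sub$group, sample_ids = sub$sample_id))
  }
  des <- design_spec(sub$group, sample_ids = sub$sample_id, weights = w)
  fit <- fit_cellmeans(expr, des)
  mod <- ebayes_moderate(fit, trend = cfg$trend, robust = cfg$robust)
  res <- apply_contrast(mod, spec$coef, contrast_id = contrast_id)
  list(result = res, qc = qc, modfit = mod, weights = w)
}

#' Run the full differential-signaling analysis end-to-end
#'
#' Orchestrates the study analysis on one dataset: probe filtering and
#' sample-wise median centering; per-contrast PCA coherence QC with
#' policy-driven precision weighting; moderated fits and the eight headline
#' contrasts; per-contrast DE counts and directional overlaps between the two
#' perturbation isoforms; composite score matrices; invariant-probe
#' identification from the three within-batch stimulus comparisons and the
#' inter-batch shift matrices (4x4 non-stimulus, 3x3 stimulus groups); and
#' per-isoform contrast quartets with response classification of the
#' stimulus-responsive probes. Deterministic given inputs and config.
#'
#' @param expr `rppa_expression` (log2) over the 21-sample study layout.
#' @param samples Sample table with the seven study groups and four batches.
#' @param annot Probe annotation.
#' @param config A [pipeline_config()].
#' @return List (class `rppa_report`): `expr` (processed matrix), `qc`,
#'   `de` (named list of contrast results), `counts` (DE count table),
#'   `overlap` (directional overlaps), `scores` (signed score matrix),
#'   `invariants`, `shift_nonstim`, `shift_stim`, `quartets`, `calls`,
#'   `call_grid`, `weights`, `config`.
#' @export
run_pipeline <- function(expr, samples, annot, config = pipeline_config()) {
  validate_sample_table(samples)
  missing_groups <- setdiff(study_groups(), samples$group)
  if (length(missing_groups))
    stop("sample table lacks group(s): ", paste(missing_groups, collapse = ", "))
  raw <- expr
  if (config$center_first) {
    expr <- median_center(expr)
    expr <- filter_probes(expr, annot, context = config$context)
  } else {
    expr <- filter_probes(expr, annot, context = config$context)
    expr <- median_center(expr)
  }

  specs <- study_contrasts()
  fits <- lapply(names(specs), function(id)
    fit_one_contrast(expr, samples, specs[[id]], config, id))
  names(fits) <- names(specs)
  de <- lapply(fits, `[[`, "result")
  qc <- do.call(rbind, lapply(fits, function(f)
    if (inherits(f$qc, "try-error")) NULL else f$qc))
  counts <- t(vapply(de, count_de, numeric(3), threshold = config$fdr))
  overlap <- rbind(
    ab40_vs_ab42 = directional_overlap(de$ab40_vs_vehicle, de$ab42_vs_vehicle,
                                       threshold = config$fdr))
  scores <- score_matrix(de, params = config$score_params, top_n = config$top_n)

  # invariant probes from the three within-batch stimulus comparisons
  within_batch <- list(
    batch1 = fit_one_contrast(expr, samples,
      list(groups = c("insulin", "untreated"), coef = c(insulin = 1, untreated = -1)),
      config, "wb_insulin_vs_untreated")$result,
    batch2 = fit_one_contrast(expr, samples,
      list(groups = c("ab40_insulin", "ab40"), coef = c(ab40_insulin = 1, ab40 = -1)),
      config, "wb_ab40ins_vs_ab40")$result,
    batch3 = fit_one_contrast(expr, samples,
      list(groups = c("ab42_insulin", "ab42"), coef = c(ab42_insulin = 1, ab42 = -1)),
      config, "wb_ab42ins_vs_ab42")$result
  )
  invariants <- find_invariant_probes(within_batch, annot,
                                      sensitivity_list = config$sensitivity_list,
                                      bound = config$invariant_bound)
  shift_nonstim <- shift_stim <- NULL
  if (length(invariants$probe_ids) >= 1) {
    shift_nonstim <- shift_matrix(raw, samples, invariants,
                                  c("untreated", "ab40", "ab42", "vehicle"))
    shift_stim <- shift_matrix(raw, samples, invariants,
                               c("insulin", "ab40_insulin", "ab42_insulin"))
  }

  # per-isoform quartets from a single four-group fit so S = Ia - I exactly
  quartets <- calls <- list()
  for (iso in c("ab40", "ab42")) {
    g4 <- c("untreated", "insulin", iso, paste0(iso, "_insulin"))
    sub <- samples[samples$group %in% g4, ]
    des <- design_spec(sub$group, sample_ids = sub$sample_id)
    mod <- ebayes_moderate(fit_cellmeans(expr, des),
                           trend = config$trend, robust = config$robust)
    ci <- function(co, id) apply_contrast(mod, co, contrast_id = id)
    ins <- paste0(iso, "_insulin")
    I <- ci(c(insulin = 1, untreated = -1), paste0(iso, ":I"))
    Ia <- ci(stats::setNames(c(1, -1), c(ins, iso)), paste0(iso, ":Ia"))
    L <- ci(stats::setNames(c(1, -1), c(ins, "insulin")), paste0(iso, ":L"))
    S <- ci(stats::setNames(c(1, -1, -1, 1), c(ins, iso, "insulin", "untreated")),
            paste0(iso, ":S"))
    Av <- de[[paste0(iso, "_vs_vehicle")]]
    Au <- fit_one_contrast(expr, samples,
      list(groups = c(iso, "untreated"),
           coef = stats::setNames(c(1, -1), c(iso, "untreated"))),
      config, paste0(iso, "_vs_untreated"))$result
    q <- contrast_quartet(I, Ia, L, S, Av = Av, Au = Au)
    responsive <- q[!is.na(q$I_fdr) & q$I_fdr < config$fdr, ]
    cl <- if (nrow(responsive))
      classify_response(responsive, alpha = config$fdr) else
      data.frame(probe_id = character(0), category = character(0),
                 rationale = character(0), saturation_possible = logical(0))
    cl$isoform <- rep(iso, nrow(cl))
    quartets[[iso]] <- q
    calls[[iso]] <- cl
  }
  all_calls <- do.call(rbind, calls)
  rownames(all_calls) <- NULL
  structure(list(expr = expr, qc = qc, de = de, counts = counts,
                 overlap = overlap, scores = scores, invariants = invariants,
                 shift_nonstim = shift_nonstim, shift_stim = shift_stim,
                 quartets = quartets, calls = all_calls,
                 call_grid = summarize_calls(all_calls),
                 weights = lapply(fits, `[[`, "weights"),
                 config = config),
            class = "rppa_report")
}

#' @export
print.rppa_report <- function(x, ...) {
  cat("rppa_report\n")
  cat(sprintf("  probes analysed: %d\n", length(x$expr$probe_ids)))
  cat("  DE counts (FDR <", x$config$fdr, "):\n")
  print(x$counts)
  cat(sprintf("  invariant probes: %d\n", length(x$invariants$probe_ids)))
  cat(sprintf("  response calls: %d\n", nrow(x$calls)))
  invisible(x)
}

#' Write the report bundle as CSV files
#'
#' One CSV per contrast (probe_id, lfc, se, t, p, fdr, ci_low, ci_high,
#' avg_expr), plus the count table, directional overlaps, score matrix,
#' shift matrices, and the response-call table. Payloads are deterministic
#' functions of the report (no timestamps).
#'
#' @param report An `rppa_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name, rn = FALSE) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = rn, quote = TRUE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  for (id in names(report$de))
    wr(report$de[[id]][, c("probe_id", "lfc", "se", "t", "p", "fdr",
                           "ci_low", "ci_high", "avg_expr")],
       paste0("de_", id, ".csv"))
  wr(data.frame(contrast = rownames(report$counts), report$counts,
                row.names = NULL), "de_counts.csv")
  wr(data.frame(pair = rownames(report$overlap), report$overlap,
                row.names = NULL), "directional_overlap.csv")
  wr(data.frame(probe_id = rownames(report$scores), report$scores,
                row.names = NULL, check.names = FALSE), "score_matrix.csv")
  if (!is.null(report$shift_nonstim)) {
    wr(report$shift_nonstim, "shift_nonstimulus.csv")
    wr(report$shift_stim, "shift_stimulus.csv")
  }
  wr(report$calls, "response_calls.csv")
  wr(report$call_grid, "response_call_grid.csv")
  if (!is.null(report$qc)) wr(report$qc, "qc_report.csv")
  invisible(paths)
}
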