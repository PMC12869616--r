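#' Treatment group labels of the emulated study design
#' @return Character vector of the seven treatment labels.
#' @export
study_groups <- function() {
  c("untreated", "vehicle", "insulin", "ab40", "ab42", "ab40_insulin", "ab42_insulin")
}

#' Batch (run) assignment of the emulated design
#'
#' Run 1 processed untreated and insulin, run 2 the ab40 pair, run 3 the ab42
#' pair, and run 4 vehicle alone, so each treatment group sits in exactly one
#' batch and every stimulus comparison is within-batch.
#' @return Named character vector group -> batch label.
#' @export
study_batch_map <- function() {
  c(untreated = "batch1", insulin = "batch1",
    ab40 = "batch2", ab40_insulin = "batch2",
    ab42 = "batch3", ab42_insulin = "batch3",
    vehicle = "batch4")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions the rest of the package assumes: 268
#' probes of which 62 are phospho-probes, seven treatment groups with three
#' replicates each (21 samples) across four runs, probe variances following a
#' decreasing mean-variance trend drawn from a scaled-inverse-chi-square prior
#' (d0 = 4, log s0^2 = log(0.0225) - 0.3 A, i.e. typical residual sd about
#' 0.15 log2 units), low-noise invariant anchor probes at sd 0.05, a -0.15
#' log2 offset on the vehicle-only run, and a base stimulus (insulin) effect
#' of 1.0 log2 with attenuation factor 0.3.
#'
#' @param n_probes Total probes.
#' @param n_phospho Number of phospho-probes (placed first).
#' @param n_rep Replicates per group.
#' @param baseline_mean_range Range for per-probe baseline log2 levels.
#' @param trend_params List `(intercept, slope)` of the log prior-variance
#'   line in average level A.
#' @param prior_df Prior df d0 of the variance distribution (`Inf` fixes every
#'   probe variance on the trend line).
#' @param anchor_sd Residual sd of invariant anchor probes.
#' @param sample_quality Named (or length-21) positive per-sample variance
#'   factors; noise variance is sigma2_probe / quality. Default all 1.
#' @param batch_offsets Named per-batch additive log2 offsets.
#' @param scenario_counts Named integer vector over scenarios
#'   `insulin_up, insulin_down, attenuated, reversed, saturated,
#'   invariant_anchor, batch_sensitive` (remaining probes are null;
#'   signaling scenarios are assigned to phospho-probes, anchors to
#'   total-protein probes).
#' @param effect_size_I Base stimulus effect (log2).
#' @param atten_factor Fraction of the stimulus effect retained under the
#'   perturbation in the attenuated scenario.
#' @param heavy_tail_prob Probability a measurement is drawn with 3x noise sd
#'   (contamination mixture exercising robust moderation); default 0.
#' @param seed Integer seed fully determining the dataset.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_probes = 268L, n_phospho = 62L, n_rep = 3L,
                       baseline_mean_range = c(-2, 2),
                       trend_params = list(intercept = log(0.0225), slope = -0.3),
                       prior_df = 4,
                       anchor_sd = 0.05,
                       sample_quality = NULL,
                       batch_offsets = c(batch1 = 0, batch2 = 0, batch3 = 0,
                                         batch4 = -0.15),
                       scenario_counts = c(insulin_up = 15L, insulin_down = 8L,
                                           attenuated = 10L, reversed = 6L,
                                           saturated = 6L,
                                           invariant_anchor = 40L,
                                           batch_sensitive = 20L),
                       effect_size_I = 1.0, atten_factor = 0.3,
                       heavy_tail_prob = 0, seed = 1L) {
  stopifnot(n_probes >= n_phospho, n_rep >= 2)
  known <- c("insulin_up", "insulin_down", "attenuated", "reversed",
             "saturated", "invariant_anchor", "batch_sensitive")
  bad <- setdiff(names(scenario_counts), known)
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  sig <- intersect(names(scenario_counts),
                   c("insulin_up", "insulin_down", "attenuated", "reversed", "saturated"))
  if (sum(scenario_counts[sig]) > n_phospho)
    stop("signaling scenario counts exceed the number of phospho probes")
  oth <- setdiff(names(scenario_counts), sig)
  if (sum(scenario_counts[oth]) > n_probes - n_phospho)
    stop("anchor/batch-sensitive counts exceed the number of total-protein probes")
  stopifnot(all(unlist(trend_params) == unlist(trend_params)),
            prior_df > 0, anchor_sd > 0)
  structure(list(n_probes = as.integer(n_probes), n_phospho = as.integer(n_phospho),
                 n_rep = as.integer(n_rep),
                 baseline_mean_range = baseline_mean_range,
                 trend_params = trend_params, prior_df = prior_df,
                 anchor_sd = anchor_sd, sample_quality = sample_quality,
                 batch_offsets = batch_offsets,
                 scenario_counts = scenario_counts,
                 effect_size_I = effect_size_I, atten_factor = atten_factor,
                 heavy_tail_prob = heavy_tail_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' True per-group mean offsets for one probe scenario
#'
#' Scenario semantics (effects in log2 units, stimulus effect `effect`):
#' `insulin_up`/`insulin_down` add +-effect to every insulin-containing group
#' (the stimulus response is intact under the perturbation); `attenuated`
#' shrinks the ab40-arm response to `atten * effect`; `reversed` flips it to
#' `-effect`; `saturated` elevates the ab40 baseline to `+effect` with no
#' further increment under insulin (so L = 0 and S = -effect);
#' `null`, `invariant_anchor` and `batch_sensitive` carry no group effects.
#' Modulation scenarios act on the ab40 arm only, leaving the ab42 arm with
#' the full response, so the same probe illustrates a modulated call for one
#' isoform and `no_effect` for the other.
#'
#' @param scenario One of the recognised scenario labels.
#' @param effect Base stimulus effect size (log2).
#' @param atten Attenuation factor.
#' @return Named numeric vector of true mean offsets over [study_groups()].
#' @export
make_scenario_effects <- function(scenario, effect = 1.0, atten = 0.3) {
  g <- stats::setNames(rep(0, 7), study_groups())
  switch(scenario,
    null = , invariant_anchor = , batch_sensitive = g,
    insulin_up = { g[c("insulin", "ab40_insulin", "ab42_insulin")] <- effect; g },
    insulin_down = { g[c("insulin", "ab40_insulin", "ab42_insulin")] <- -effect; g },
    attenuated = { g["insulin"] <- effect; g["ab42_insulin"] <- effect
                   g["ab40_insulin"] <- atten * effect; g },
    reversed = { g["insulin"] <- effect; g["ab42_insulin"] <- effect
                 g["ab40_insulin"] <- -effect; g },
    saturated = { g["insulin"] <- effect; g["ab42_insulin"] <- effect
                  g["ab40"] <- effect; g["ab40_insulin"] <- effect; g },
    stop("unknown scenario: ", scenario)
  )
}

#' Generate a synthetic RPPA dataset with known truth
#'
#' Draws value(probe, sample) = baseline + group effect + batch offset +
#' Gaussian noise with probe-specific variance from the configured
#' mean-variance trend, scaled by the per-sample quality factor
#' (Var = sigma2_probe / quality). `batch_sensitive` probes feel the batch
#' offsets doubled; all other probes feel them as configured. Identical seed
#' and config give bit-identical output; the caller's RNG state is restored.
#'
#' @param config A [sim_config()].
#' @return List: `expr` (`rppa_expression`, log2), `samples` (sample table),
#'   `annotation` (probe annotation data.frame), `truth` (per-probe scenario
#'   and true contrast effects for the ab40-arm quartet), `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  groups <- study_groups()
  bmap <- study_batch_map()
  n_rep <- config$n_rep
  p <- config$n_probes
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(length(groups) * n_rep)),
    group = rep(groups, each = n_rep),
    batch = bmap[rep(groups, each = n_rep)],
    replicate = rep(seq_len(n_rep), times = length(groups)),
    cf1 = round(stats::runif(length(groups) * n_rep, 0.8, 1.35), 3),
    cf2 = round(stats::runif(length(groups) * n_rep, 0.45, 1.10), 3),
    qc_flag = FALSE, row.names = NULL, stringsAsFactors = FALSE
  )
  quality <- config$sample_quality
  if (is.null(quality)) quality <- rep(1, nrow(samples))
  if (!is.null(names(quality))) {
    q <- rep(1, nrow(samples)); names(q) <- samples$sample_id
    q[names(quality)] <- quality; quality <- q
  }
  if (length(quality) != nrow(samples) || any(quality <= 0))
    stop("sample_quality must be positive, one per sample")

  probe_ids <- sprintf("probe_%03d", seq_len(p))
  is_phospho <- seq_len(p) <= config$n_phospho
  scenario <- rep("null", p)
  sc <- config$scenario_counts
  pool_ph <- which(is_phospho)
  pool_tot <- which(!is_phospho)
  for (s in intersect(names(sc), c("insulin_up", "insulin_down", "attenuated",
                                   "reversed", "saturated"))) {
    take <- utils::head(pool_ph, sc[[s]])
    scenario[take] <- s
    pool_ph <- setdiff(pool_ph, take)
  }
  for (s in intersect(names(sc), c("invariant_anchor", "batch_sensitive"))) {
    take <- utils::head(pool_tot, sc[[s]])
    scenario[take] <- s
    pool_tot <- setdiff(pool_tot, take)
  }

  baseline <- stats::runif(p, config$baseline_mean_range[1], config$baseline_mean_range[2])
  s0sq <- exp(config$trend_params$intercept + config$trend_params$slope * baseline)
  sigma2 <- if (is.finite(config$prior_df))
    s0sq * config$prior_df / stats::rchisq(p, df = config$prior_df) else s0sq
  sigma2[scenario == "invariant_anchor"] <- config$anchor_sd^2

  eff <- t(vapply(scenario, make_scenario_effects, numeric(7),
                  effect = config$effect_size_I, atten = config$atten_factor))
  colnames(eff) <- groups
  boff <- config$batch_offsets[samples$batch]
  bamp <- ifelse(scenario == "batch_sensitive", 2, 1)

  mu <- eff[, samples$group, drop = FALSE] +
    outer(rep(1, p), boff) * bamp + baseline
  sd_mat <- sqrt(outer(sigma2, quality, "/"))
  if (config$heavy_tail_prob > 0) {
    contam <- matrix(stats::runif(p * nrow(samples)) < config$heavy_tail_prob,
                     p, nrow(samples))
    sd_mat[contam] <- 3 * sd_mat[contam]
  }
  vals <- mu + matrix(stats::rnorm(p * nrow(samples)), p, nrow(samples)) * sd_mat
  dimnames(vals) <- list(probe_ids, samples$sample_id)

  annotation <- data.frame(
    probe_id = probe_ids,
    target = sprintf("target_%03d", seq_len(p)),
    phospho_site = ifelse(is_phospho, sprintf("site_%03d", seq_len(p)), ""),
    validated = TRUE, excluded = FALSE, stringsAsFactors = FALSE
  )
  annotation$is_phospho <- is_phospho
  annotation$context_tags <- replicate(p, character(0), simplify = FALSE)

  e_I <- eff[, "insulin"] - eff[, "untreated"]
  e_Ia <- eff[, "ab40_insulin"] - eff[, "ab40"]
  truth <- data.frame(
    probe_id = probe_ids, scenario = scenario,
    I = e_I, Ia = e_Ia, L = eff[, "ab40_insulin"] - eff[, "insulin"],
    S = e_Ia - e_I,
    Av = eff[, "ab40"] - eff[, "vehicle"],
    Au = eff[, "ab40"] - eff[, "untreated"],
    sigma = sqrt(sigma2), baseline = baseline,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(expr = expression_matrix(vals, scale = "log2"), samples = samples,
       annotation = annotation, truth = truth, config = config)
}

#' Synthetic antibody panel annotation mirroring a filtered RPPA panel
#'
#' Builds a synthetic stand-in for a full antibody panel plus curated
#' exclusion list: `n_total` probes of which `n_excluded` are marked excluded
#' (so `n_total - n_excluded` survive filtering), `n_phospho_retained` of the
#' retained probes are phospho-probes, and `n_context_readmit` of the excluded
#' probes carry the given context tag so they are re-admitted when that
#' context is analysed. This is a synthetic panel for exercising the filtering
#' rules, not the study's actual antibody list.
#'
#' @param n_total Panel size.
#' @param n_excluded Probes on the exclusion list.
#' @param n_phospho_retained Phospho-probes among the retained set.
#' @param n_context_readmit Excluded probes tagged with `context`.
#' @param context Context tag carried by the re-admitted probes.
#' @return Annotation data.frame in the format of [read_probe_annotation()].
#' @export
simulate_panel_annotation <- function(n_total = 306L, n_excluded = 38L,
                                      n_phospho_retained = 62L,
                                      n_context_readmit = 3L,
                                      context = "pericyte") {
  stopifnot(n_excluded < n_total, n_context_readmit <= n_excluded,
            n_phospho_retained <= n_total - n_excluded)
  probe_id <- sprintf("ab_%03d", seq_len(n_total))
  excluded <- c(rep(TRUE, n_excluded), rep(FALSE, n_total - n_excluded))
  phospho <- rep(FALSE, n_total)
  phospho[which(!excluded)[seq_len(n_phospho_retained)]] <- TRUE
  tags <- replicate(n_total, character(0), simplify = FALSE)
  for (i in seq_len(n_context_readmit)) tags[[i]] <- context
  ann <- data.frame(
    probe_id = probe_id, target = sprintf("t_%03d", seq_len(n_total)),
    phospho_site = ifelse(phospho, "site", ""),
    validated = TRUE, excluded = excluded, stringsAsFactors = FALSE
  )
  ann$is_phospho <- phospho
  ann$context_tags <- tags
  ann
}
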