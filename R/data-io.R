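#' Construct an expression matrix of relative protein levels
#'
#' The central container of the package: a probes x samples numeric matrix of
#' relative protein levels as delivered by an RPPA core facility (one value per
#' antibody probe per lysate, interpolated from the dilution series upstream of
#' this package). Values are carried on the log2 scale internally; linear-scale
#' input is converted on construction.
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   unique non-empty rownames (probe ids) and colnames (sample ids).
#' @param scale Either `"log2"` (values stored as-is) or `"linear"` (values are
#'   log2-transformed; non-positive values become `NA`).
#' @return An object of class `rppa_expression`: a list with elements `values`
#'   (the log2 matrix), `probe_ids`, `sample_ids` and `scale` (always `"log2"`
#'   after construction).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop("`values` must carry probe rownames and sample colnames")
  if (anyDuplicated(pid))
    stop("duplicate probe ids: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("`values` must be finite or NA")
  if (scale == "linear") {
    if (any(values <= 0, na.rm = TRUE))
      warning("non-positive linear values set to NA before log2 transform")
    values[values <= 0] <- NA_real_
    values <- log2(values)
  }
  structure(
    list(values = values, probe_ids = pid, sample_ids = sid, scale = "log2"),
    class = "rppa_expression"
  )
}

#' @export
print.rppa_expression <- function(x, ...) {
  cat(sprintf("rppa_expression: %d probes x %d samples (log2 scale)\n",
              length(x$probe_ids), length(x$sample_ids)))
  cat(sprintf("  missing values: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.rppa_expression <- function(x) dim(x$values)

#' Extract the log2 value matrix from an expression object
#'
#' @param x An `rppa_expression` object or a plain numeric matrix (returned
#'   unchanged, assumed log2).
#' @return Numeric matrix of log2 relative protein levels.
#' @export
expr_values <- function(x) {
  if (inherits(x, "rppa_expression")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an rppa_expression object or a numeric matrix")
}

#' Read a probe-by-sample expression table
#'
#' Reads a delimited text file with one header row of sample ids and a first
#' column of probe ids, as exported by RPPA cores (relative protein levels).
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from extension,
#'   or set `sep`).
#' @param scale Declared scale of the stored values; `"linear"` input is
#'   log2-transformed on read.
#' @param sep Field separator; default `","` for `.csv`, `"\t"` for `.tsv`/`.txt`.
#' @return An [expression_matrix()] object.
#' @export
read_expression_table <- function(path, scale = c("log2", "linear"), sep = NULL) {
  scale <- match.arg(scale)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a probe-id column plus >=1 sample column")
  pid <- df[[1L]]
  if (anyDuplicated(pid))
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  sid <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L, dimnames = list(pid, sid))
  for (j in seq_along(sid)) {
    raw <- df[[j + 1L]]
    raw[raw %in% c("", "NA", "na", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at probe '%s', sample column '%s'",
                   raw[bad[1L]], pid[bad[1L]], sid[j]))
    vals[, j] <- num
  }
  expression_matrix(vals, scale = scale)
}

#' Write an expression table to CSV
#'
#' Writes probes as rows with a leading `probe_id` column, RFC-4180-quoted,
#' UTF-8. Round-trips through [read_expression_table()] exactly.
#'
#' @param x An `rppa_expression` object or log2 matrix.
#' @param path Output path.
#' @export
write_expression_table <- function(x, path) {
  v <- expr_values(x)
  df <- data.frame(probe_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the sample metadata table
#'
#' Expected columns: `sample_id, group, batch, replicate, cf1, cf2`. `cf1` and
#' `cf2` are the core facility's protein-loading correction factors (`cf1`
#' within the submitted set, `cf2` across the whole slide).
#'
#' @param path CSV path.
#' @return A data.frame with a logical `qc_flag` column initialised to `FALSE`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("sample_id", "group", "batch", "replicate", "cf1", "cf2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample table")
  df$qc_flag <- FALSE
  validate_sample_table(df)
  df
}

validate_sample_table <- function(samples) {
  # a treatment group must sit inside exactly one batch (run)
  gb <- unique(samples[, c("group", "batch")])
  dup <- gb$group[duplicated(gb$group)]
  if (length(dup))
    stop("group(s) span multiple batches: ", paste(unique(dup), collapse = ", "))
  invisible(samples)
}

#' Flag protein-loading outlier samples
#'
#' Applies the RPPA core's loading rule: samples whose slide-wide correction
#' factor CF2 falls below 0.25 or above 2.5 are flagged as protein-loading
#' outliers. Inequalities are strict (CF2 exactly 0.25 or 2.5 is not flagged)
#' and samples are only flagged, never removed.
#'
#' @param samples Sample table with a positive `cf2` column.
#' @return The table with `qc_flag` set.
#' @export
flag_loading_outliers <- function(samples) {
  if (is.null(samples$cf2) || anyNA(samples$cf2))
    stop("cf2 must be present and non-missing for all samples")
  if (any(samples$cf2 <= 0)) stop("cf2 must be positive")
  samples$qc_flag <- samples$cf2 < 0.25 | samples$cf2 > 2.5
  samples
}

#' Read a probe annotation table
#'
#' Expected columns: `probe_id, target, phospho_site, validated, excluded,
#' context_tags` (tags semicolon-joined). A probe is a phospho-probe exactly
#' when `phospho_site` is non-empty.
#'
#' @param path CSV path.
#' @return A data.frame with a derived logical `is_phospho` column and
#'   `context_tags` as a list-column of character vectors.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "target", "phospho_site", "validated", "excluded", "context_tags")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in annotation")
  df$phospho_site[is.na(df$phospho_site)] <- ""
  df$is_phospho <- nzchar(df$phospho_site)
  df$validated <- as.logical(df$validated)
  df$excluded <- as.logical(df$excluded)
  tags <- df$context_tags
  tags[is.na(tags)] <- ""
  df$context_tags <- lapply(strsplit(tags, ";", fixed = TRUE),
                            function(t) t[nzchar(t)])
  df
}

#' Remove excluded probes, honouring a biological context
#'
#' Drops probes marked `excluded` in the annotation (e.g. proteins with no
#' functional abundance in the tissue of interest), unless a probe's context
#' tags contain the active context: probes relevant to another cell type in
#' the co-culture (say, pericytes) can be re-admitted when that context is
#' analysed.
#'
#' @param x `rppa_expression` object.
#' @param annot Annotation data.frame as from [read_probe_annotation()].
#' @param context Active context label, or `NULL` for no re-admission.
#' @return Filtered `rppa_expression`.
#' @export
filter_probes <- function(x, annot, context = NULL) {
  v <- expr_values(x)
  missing_ann <- setdiff(rownames(v), annot$probe_id)
  if (length(missing_ann))
    stop("probes lacking annotation: ", paste(utils::head(missing_ann, 5), collapse = ", "))
  ann <- annot[match(rownames(v), annot$probe_id), ]
  readmit <- if (is.null(context)) rep(FALSE, nrow(ann)) else
    vapply(ann$context_tags, function(t) context %in% t, logical(1))
  keep <- !ann$excluded | readmit
  expression_matrix(v[keep, , drop = FALSE], scale = "log2")
}

#' Sample-wise median centering
#'
#' Subtracts each sample's median over non-missing probes, the standard
#' normalisation for RPPA relative levels once on the log2 scale. Idempotent.
#'
#' @param x `rppa_expression` object (log2 scale enforced).
#' @return Centered `rppa_expression`; every sample's median is 0.
#' @export
median_center <- function(x) {
  if (inherits(x, "rppa_expression") && !identical(x$scale, "log2"))
    stop("median_center requires log2-scale values; convert with expression_matrix(scale='linear') first")
  v <- expr_values(x)
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  expression_matrix(sweep(v, 2L, med, "-"), scale = "log2")
}
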