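#' @importFrom jsonlite write_json read_json
NULL

write_run_manifest <- function(out_dir, step, config, inputs = character()) {
  checksums <- if (length(inputs) > 0L)
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  manifest <- list(tool = "txmodes",
                   version = as.character(packageVersion("txmodes")),
                   step = step, config = config, input_md5 = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

as_expression <- function(expression) {
  if (is.character(expression) && length(expression) == 1L) {
    if (!file.exists(expression)) stop("cannot read: ", expression)
    read_expression_tsv(expression)
  } else as.numeric_named(expression)
}

as.numeric_named <- function(x) {
  v <- as.numeric(x)
  names(v) <- names(x)
  v
}

#' Quantify expression from SAM and annotation files
#'
#' Runs read ingestion, the entire-length single-locus filter, base
#' counting, normalization and log2 transformation, and writes the
#' expression table plus a run manifest with read-fate counts.
#'
#' @param sam_path SAM file.
#' @param annotation_path FASTA or TSV locus annotation.
#' @param out_dir output directory (created if needed).
#' @param scale_constant see [normalize_coverage()].
#' @return invisibly, the [quantify_sam()] result plus `counts` (reads seen /
#'   retained / discarded by reason).
#' @export
run_quantify <- function(sam_path, annotation_path, out_dir,
                         scale_constant = 1e9) {
  if (!file.exists(sam_path)) stop("cannot read SAM file: ", sam_path)
  if (!file.exists(annotation_path))
    stop("cannot read annotation: ", annotation_path)
  ensure_dir(out_dir)
  q <- quantify_sam(sam_path, annotation_path, scale_constant)

  per_read <- q$records[!duplicated(q$records$read_id), ]
  multi <- per_read$n_loci_hit > 1L
  clipped <- !multi & per_read$is_clipped
  partial <- !multi & !clipped & per_read$aligned_span < per_read$read_length
  counts <- list(reads_seen = nrow(per_read),
                 retained = length(unique(q$retained$read_id)),
                 discarded_multi_locus = sum(multi),
                 discarded_clipped = sum(clipped),
                 discarded_partial = sum(partial))
  write_expression_tsv(q$table, file.path(out_dir, "expression.tsv"))
  write_run_manifest(out_dir, "quantify",
                     c(list(sam = sam_path, annotation = annotation_path,
                            scale_constant = scale_constant), counts),
                     inputs = c(sam_path, annotation_path))
  invisible(c(q, list(counts = counts)))
}

#' Fit and classify an expression-level distribution
#'
#' Selects the best normal mixture by BIC, summarizes peaks and main peaks,
#' and writes the BIC table, the modality row, the model parameters and
#' (optionally) the histogram-plus-density plot.
#'
#' @param expression path to an expression TSV (see [read_expression_tsv()])
#'   or a named numeric vector of log2 values.
#' @param out_dir output directory.
#' @param config a [fit_config()].
#' @param main_threshold main-peak threshold, default 0.15.
#' @param sample,condition labels for the modality row.
#' @param plot write `density.pdf`?
#' @param binwidth histogram bin width in log2 units (default 0.25).
#' @return invisibly, list with `model` (a `mixfit`) and `summary`
#'   (a `peak_summary`).
#' @export
run_fit <- function(expression, out_dir, config = fit_config(),
                    main_threshold = 0.15, sample = "sample",
                    condition = NA_character_, plot = TRUE,
                    binwidth = 0.25) {
  values <- as_expression(expression)
  ensure_dir(out_dir)
  model <- select_model(values, config)
  summary <- summarize_peaks(model, main_threshold)

  write.table(model$bic_table, file.path(out_dir, "bic_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  modality_table(list(summary),
                 data.frame(sample = sample, condition = condition,
                            stringsAsFactors = FALSE),
                 path = file.path(out_dir, "modality.tsv"))
  jsonlite::write_json(
    list(K = model$K, family = model$family, weights = model$weights,
         means = model$means, variances = model$variances,
         loglik = model$loglik, bic = model$bic, n = model$n,
         n_main_peaks = summary$n_main_peaks,
         main_threshold = main_threshold, label = summary$label),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (plot) {
    grDevices::pdf(file.path(out_dir, "density.pdf"), width = 7, height = 5)
    tryCatch(plot_mixture(model, values, binwidth = binwidth,
                          main = sample),
             finally = grDevices::dev.off())
  }
  write_run_manifest(out_dir, "fit",
                     list(k_range = range(config$k_range),
                          families = config$families, tol = config$tol,
                          max_iter = config$max_iter,
                          main_threshold = main_threshold,
                          binwidth = binwidth,
                          input = if (is.character(expression)) expression
                                  else "in-memory"),
                     inputs = if (is.character(expression)) expression
                              else character())
  invisible(list(model = model, summary = summary))
}

#' Run the Zipf's-law rank regression
#'
#' Ranks the expression vector, fits the log-log regression, assesses
#' linearity, and writes the rank series, the fit JSON and (optionally) the
#' Fig-3-style plot.
#'
#' @inheritParams run_fit
#' @param r2_min,curvature_max,window see [assess_linearity()].
#' @return invisibly, the assessed `zipf_fit`.
#' @export
run_zipf <- function(expression, out_dir, r2_min = 0.98,
                     curvature_max = 0.01, window = 0.9, plot = TRUE) {
  values <- as_expression(expression)
  ensure_dir(out_dir)
  series <- rank_expression(values)
  fit <- assess_linearity(fit_zipf(series), r2_min, curvature_max, window)

  write.table(series, file.path(out_dir, "rank_series.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(gradient = fit$gradient, intercept = fit$intercept,
         r_squared = fit$r_squared,
         quad_coefficient = fit$quad_coefficient, n = fit$n,
         is_zipf_consistent = fit$is_zipf_consistent,
         window = fit$linearity$window,
         full_range = fit$linearity$full_range),
    file.path(out_dir, "zipf.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (plot) {
    grDevices::pdf(file.path(out_dir, "zipf.pdf"), width = 6, height = 6)
    tryCatch(plot_zipf(fit), finally = grDevices::dev.off())
  }
  write_run_manifest(out_dir, "zipf",
                     list(r2_min = r2_min, curvature_max = curvature_max,
                          window = window,
                          input = if (is.character(expression)) expression
                                  else "in-memory"),
                     inputs = if (is.character(expression)) expression
                              else character())
  invisible(fit)
}

#' Generate a named synthetic scenario
#'
#' Writes the generated expression TSV and a ground-truth manifest for one
#' of the [preset_scenarios()], or for a spec object.
#'
#' @param scenario a scenario name (see [preset_scenarios()]), or a
#'   [mixture_spec()] / [zipf_spec()].
#' @param out_dir output directory.
#' @param n_genes,seed forwarded to [preset_scenarios()] when `scenario` is
#'   a name.
#' @return invisibly, list with `values` and `expected` (ground truth,
#'   `NULL` for bare specs).
#' @export
run_simulate <- function(scenario, out_dir, n_genes = 10000L, seed = 1L) {
  ensure_dir(out_dir)
  if (is.character(scenario)) {
    presets <- preset_scenarios(n_genes, seed)
    if (!scenario %in% names(presets))
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(presets), collapse = ", "))
    sc <- presets[[scenario]]
    spec <- sc$spec
    expected <- sc$expected
    type <- sc$type
  } else if (inherits(scenario, "mixture_spec")) {
    spec <- scenario; expected <- NULL; type <- "mixture"
  } else if (inherits(scenario, "zipf_spec")) {
    spec <- scenario; expected <- NULL; type <- "zipf"
  } else stop("scenario must be a name, mixture_spec or zipf_spec")

  values <- if (type == "mixture") simulate_mixture(spec)$values
            else simulate_zipf(spec)
  df <- data.frame(locus_tag = names(values), log2_value = as.numeric(values),
                   stringsAsFactors = FALSE)
  write.table(df, file.path(out_dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(type = type, spec = unclass(spec), expected = expected),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_run_manifest(out_dir, "simulate",
                     list(scenario = if (is.character(scenario)) scenario
                          else "custom_spec", seed = spec$seed))
  invisible(list(values = values, expected = expected))
}

#' Full report: mixture classification plus Zipf test
#'
#' Convenience wrapper running [run_fit()] and [run_zipf()] on the same
#' expression input into one output directory.
#'
#' @inheritParams run_fit
#' @param ... forwarded to [run_zipf()].
#' @return invisibly, list with `fit` and `zipf` results.
#' @export
run_report <- function(expression, out_dir, config = fit_config(),
                       main_threshold = 0.15, sample = "sample", ...) {
  values <- as_expression(expression)
  fit <- run_fit(values, out_dir, config, main_threshold, sample = sample)
  zipf <- run_zipf(values, out_dir, ...)
  invisible(list(fit = fit, zipf = zipf))
}
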