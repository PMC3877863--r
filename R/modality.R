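#' Summarize a fitted mixture as peaks and main peaks
#'
#' A "peak" is one fitted normal component; the number of peaks is the
#' selected K. A "main peak" is a component whose mixing proportion is at
#' least `main_threshold` of the clustered genes (inclusive: a weight
#' exactly at the threshold counts). Weights are fractions of the clustered,
#' i.e. nonzero-coverage, genes — zero-coverage loci never enter the fit.
#'
#' @param model a converged `mixfit`.
#' @param main_threshold minimum mixing proportion of a main peak,
#'   default 0.15.
#' @return object of class `peak_summary`: list with `n_peaks`,
#'   `n_main_peaks`, `main_threshold`, `per_component` (`data.frame(weight,
#'   mean, variance, is_main)` sorted by mean ascending) and `label`
#'   (`"unimodal"`, `"bimodal"`, `"multimodal"` for 1 / 2 / >= 3 main
#'   peaks; `"none"` if no component reaches the threshold).
#' @export
summarize_peaks <- function(model, main_threshold = 0.15) {
  stopifnot(main_threshold >= 0, main_threshold <= 1)
  if (!isTRUE(model$converged))
    warning("summarizing a non-converged mixture fit")
  is_main <- model$weights >= main_threshold
  n_main <- sum(is_main)
  label <- if (n_main == 0L) "none" else if (n_main == 1L) "unimodal"
           else if (n_main == 2L) "bimodal" else "multimodal"
  structure(list(
    n_peaks = model$K,
    n_main_peaks = as.integer(n_main),
    main_threshold = main_threshold,
    per_component = data.frame(weight = model$weights, mean = model$means,
                               variance = model$variances, is_main = is_main),
    label = label), class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("%d peak(s), %d main peak(s) at threshold %.0f%% -> %s\n",
              x$n_peaks, x$n_main_peaks, 100 * x$main_threshold, x$label))
  print(x$per_component)
  invisible(x)
}

#' Mixing proportion of the dominant component
#'
#' The largest mixing proportion of the fitted mixture; a single dominant
#' peak holding >= 70% of expressed genes is the shape reported for yeast
#' transcriptomes.
#'
#' @param model a `mixfit`.
#' @return numeric in (0, 1].
#' @export
dominant_peak_fraction <- function(model) max(model$weights)

#' Tabulate peak summaries across datasets
#'
#' One row per dataset with the headline modality columns, suitable for TSV
#' export.
#'
#' @param summaries list of `peak_summary` objects.
#' @param labels data frame with columns `sample` and `condition` (one row
#'   per summary), or a character vector of sample names (condition then
#'   `NA`).
#' @param path optional TSV output path.
#' @return `data.frame(sample, condition, n_peaks, n_main_peaks)`.
#' @export
modality_table <- function(summaries, labels, path = NULL) {
  if (length(summaries) == 0L) stop("no summaries to tabulate")
  if (is.character(labels))
    labels <- data.frame(sample = labels, condition = NA_character_,
                         stringsAsFactors = FALSE)
  stopifnot(nrow(labels) == length(summaries),
            all(c("sample", "condition") %in% names(labels)))
  out <- data.frame(
    sample = labels$sample,
    condition = labels$condition,
    n_peaks = vapply(summaries, function(s) s$n_peaks, integer(1)),
    n_main_peaks = vapply(summaries, function(s) s$n_main_peaks, integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Count density modes of a fitted mixture (diagnostic)
#'
#' Peaks are defined as mixture components, so strongly overlapping
#' components need not be distinct modes of the density. This diagnostic
#' counts the actual local maxima of the mixture density on a grid.
#'
#' @param model a `mixfit`.
#' @param n_grid grid resolution (default 2048).
#' @return integer number of local maxima.
#' @export
count_density_modes <- function(model, n_grid = 2048L) {
  s <- sqrt(max(model$variances))
  grid <- seq(min(model$means) - 5 * s, max(model$means) + 5 * s,
              length.out = n_grid)
  d <- mixture_density(model, grid)
  s <- sign(diff(d))
  s <- s[s != 0]               # collapse plateaus from symmetric grids
  sum(diff(s) == -2L) + as.integer(length(s) > 0L && s[1L] == -1L)
}
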