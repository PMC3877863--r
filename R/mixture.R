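#' Fit configuration for mixture decomposition
#'
#' Defaults mirror common univariate model-based clustering practice: the
#' number of components ranges over 1..9 (the data here show up to five
#' peaks, so the search range must exceed that), both the equal-variance
#' ("E") and varying-variance ("V") families compete, and BIC arbitrates.
#'
#' @param k_range inclusive integer range of component counts (default 1:9).
#' @param families subset of `c("E", "V")`: equal or component-specific
#'   variances.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per fit (default 1000).
#' @param variance_floor_frac variance floor as a fraction of the sample
#'   variance (default 1e-6); prevents singular collapse of a component
#'   onto a single point.
#' @param n_starts number of EM starts: 1 = deterministic quantile
#'   initialization only; more adds seeded jittered restarts.
#' @param seed seed for the jittered restarts (ignored when `n_starts = 1`).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(k_range = 1:9, families = c("E", "V"), tol = 1e-8,
                       max_iter = 1000L, variance_floor_frac = 1e-6,
                       n_starts = 1L, seed = 1L) {
  stopifnot(length(k_range) >= 1L, all(k_range >= 1L), tol > 0,
            max_iter >= 1L, variance_floor_frac > 0, n_starts >= 1L)
  families <- match.arg(families, c("E", "V"), several.ok = TRUE)
  structure(list(k_range = as.integer(sort(unique(k_range))),
                 families = families, tol = tol,
                 max_iter = as.integer(max_iter),
                 variance_floor_frac = variance_floor_frac,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit a K-component univariate normal mixture by EM
#'
#' Maximizes the mixture log-likelihood by expectation-maximization. The
#' E-step computes posterior responsibilities through log-sum-exp; the
#' M-step re-estimates weights, means and variances (component-specific for
#' family "V", pooled for family "E"). Iteration stops when the relative
#' log-likelihood change falls below `config$tol` or after
#' `config$max_iter` iterations.
#'
#' Initialization is deterministic and order-independent: component k's mean
#' starts at the (k - 0.5)/K sample quantile and is refined by Lloyd k-means
#' seeded from those quantiles; the k-means cluster shares and within-cluster
#' spreads seed the starting weights and variances. (A plain quantile start
#' systematically misses minor components when mixing weights are very
#' unequal.) Optional seeded jittered restarts
#' (`config$n_starts > 1`) guard against poor local maxima; the best
#' log-likelihood wins.
#'
#' A component whose variance collapses below the floor in two iterations,
#' or whose weight underflows, flags the fit `converged = FALSE` (such fits
#' are excluded from model selection). Data with zero sample variance yield
#' a flagged single-component model at the floor.
#'
#' @param x numeric vector of (log2) expression values, all finite.
#' @param K number of components, `1 <= K <= length(x)`.
#' @param family `"V"` (component-specific variances) or `"E"` (equal).
#' @param config a [fit_config()].
#' @return object of class `mixfit`: list with `K`, `family`, `weights`,
#'   `means`, `variances` (components sorted by mean ascending), `loglik`,
#'   `bic` (`2*loglik - n_params*log(n)`, larger is better), `n`,
#'   `n_params` (`3K-1` for "V", `2K` for "E"), `converged`, `n_iter`,
#'   `loglik_trace`, `degenerate`.
#' @export
em_fit <- function(x, K, family = c("V", "E"), config = fit_config()) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  K <- as.integer(K)
  if (n < K) stop("n < K: cannot fit ", K, " components to ", n, " points")

  xbar <- mean(x)
  svar <- mean((x - xbar)^2)
  if (svar == 0) {
    v <- .Machine$double.eps
    ll <- sum(dnorm(x, xbar, sqrt(v), log = TRUE))
    return(new_mixfit(1L, family, 1, xbar, v, ll, n,
                      converged = TRUE, n_iter = 0L, loglik_trace = ll,
                      degenerate = TRUE))
  }
  var_floor <- config$variance_floor_frac * svar

  run_one <- function(w0, mu0, v0) {
    .em_core(x, w0, mu0, v0, family == "E",
             config$tol, config$max_iter, var_floor)
  }
  # deterministic, order-independent start: quantile means refined by
  # Lloyd k-means, whose cluster shares and spreads seed weights/variances
  # (plain quantile init misses minor components when weights are unequal)
  mu0 <- as.numeric(quantile(x, probs = (seq_len(K) - 0.5) / K,
                             names = FALSE, type = 7))
  w0 <- rep(1 / K, K)
  v0 <- rep(svar, K)
  if (K > 1L) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = matrix(mu0, ncol = 1),
                                     iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0L)) {
      mu0 <- as.numeric(km$centers)
      w0 <- km$size / n
      v0 <- pmax(km$withinss / km$size, 1e-3 * svar)
      if (family == "E") v0 <- rep(sum(km$withinss) / n, K)
    }
  }
  best <- run_one(w0, mu0, v0)
  if (config$n_starts > 1L) {
    jitters <- with_local_rng(config$seed, {
      lapply(seq_len(config$n_starts - 1L),
             function(i) mu0 + rnorm(K, 0, sd(x) / K))
    })
    for (m0 in jitters) {
      fit <- run_one(rep(1 / K, K), m0, rep(svar, K))
      if (fit$converged &&
          (!best$converged || fit$loglik > best$loglik)) best <- fit
    }
  }
  new_mixfit(K, family, best$weights, best$means, best$variances,
             best$loglik, n, converged = best$converged,
             n_iter = best$n_iter, loglik_trace = best$loglik_trace,
             degenerate = FALSE)
}

new_mixfit <- function(K, family, weights, means, variances, loglik, n,
                       converged, n_iter, loglik_trace, degenerate) {
  ord <- order(means)
  n_params <- if (family == "V") 3L * K - 1L else 2L * K
  structure(list(K = K, family = family,
                 weights = as.numeric(weights[ord]),
                 means = as.numeric(means[ord]),
                 variances = as.numeric(variances[ord]),
                 loglik = loglik, n = as.integer(n), n_params = n_params,
                 bic = 2 * loglik - n_params * log(n),
                 converged = converged, n_iter = as.integer(n_iter),
                 loglik_trace = as.numeric(loglik_trace),
                 degenerate = degenerate),
            class = "mixfit")
}

# evaluate expr under a seeded RNG, restoring any prior RNG state
with_local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Mixture log-likelihood of data under a fitted model
#'
#' `sum_i log sum_k w_k N(x_i; mu_k, sigma_k^2)`, computed in log space
#' (log-sum-exp) for numerical stability.
#'
#' @param x numeric data vector.
#' @param model a `mixfit`.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(x, model) {
  lp <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) +
      dnorm(x, model$means[k], sqrt(model$variances[k]), log = TRUE)
  }, numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1L, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Bayesian information criterion of a fitted mixture
#'
#' Uses the maximize convention `BIC = 2*loglik - n_params*log(n)`: larger
#' is better. (Beware the opposite sign convention used elsewhere.)
#'
#' @param model a `mixfit`.
#' @return scalar BIC.
#' @export
model_bic <- function(model) 2 * model$loglik - model$n_params * log(model$n)

#' Posterior component responsibilities
#'
#' E-step posteriors `r_ik` proportional to `w_k N(x_i; mu_k, sigma_k^2)`,
#' normalized so each row sums to 1.
#'
#' @param x numeric data vector.
#' @param model a `mixfit`.
#' @return `length(x)` by `K` matrix.
#' @export
responsibilities <- function(x, model) {
  lp <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) +
      dnorm(x, model$means[k], sqrt(model$variances[k]), log = TRUE)
  }, numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1L, max)
  r <- exp(lp - m)
  r / rowSums(r)
}

#' Mixture density on a grid
#'
#' Total density `f(x) = sum_k w_k N(x; mu_k, sigma_k^2)` and, optionally,
#' the per-component curves `w_k N(x; mu_k, sigma_k^2)` used for
#' histogram-overlay plots.
#'
#' @param model a `mixfit`.
#' @param grid numeric vector of evaluation points.
#' @param components if `TRUE`, also return the per-component curves.
#' @return numeric vector of densities, or (with `components = TRUE`) a list
#'   with `total` and a `length(grid)` by `K` matrix `components`.
#' @export
mixture_density <- function(model, grid, components = FALSE) {
  comp <- vapply(seq_len(model$K), function(k) {
    model$weights[k] * dnorm(grid, model$means[k], sqrt(model$variances[k]))
  }, numeric(length(grid)))
  comp <- matrix(comp, nrow = length(grid))
  total <- rowSums(comp)
  if (components) list(total = total, components = comp) else total
}

#' Select the best mixture by BIC over component counts and families
#'
#' Fits every (K, family) combination in `config`, excludes non-converged
#' fits, and returns the model maximizing BIC. Ties break toward smaller K,
#' then family "E". The full BIC table is attached for reporting.
#'
#' @param x numeric vector of (log2) expression values.
#' @param config a [fit_config()].
#' @return the best `mixfit`, with the per-(K, family) results in
#'   `$bic_table` (columns `K`, `family`, `n_params`, `loglik`, `bic`,
#'   `converged`, `n_iter`).
#' @export
select_model <- function(x, config = fit_config()) {
  if (length(x) == 0L) stop("empty expression vector")
  ks <- config$k_range[config$k_range <= length(x)]
  fits <- list()
  rows <- list()
  for (K in ks) for (fam in config$families) {
    fit <- em_fit(x, K, fam, config)
    key <- paste0(fam, K)
    fits[[key]] <- fit
    rows[[key]] <- data.frame(K = K, family = fam, n_params = fit$n_params,
                              loglik = fit$loglik, bic = fit$bic,
                              converged = fit$converged, n_iter = fit$n_iter,
                              stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  ok <- table$converged
  if (!any(ok)) stop("all mixture fits failed to converge")
  cand <- table[ok, ]
  cand <- cand[order(-cand$bic, cand$K, cand$family != "E"), ]
  best <- fits[[paste0(cand$family[1L], cand$K[1L])]]
  best$bic_table <- table
  best
}

#' @export
print.mixfit <- function(x, ...) {
  cat(sprintf("%d-component normal mixture (family %s)%s\n", x$K, x$family,
              if (x$degenerate) " [degenerate data]" else ""))
  cat(sprintf("  n = %d, loglik = %.4f, BIC = %.4f, %s in %d iterations\n",
              x$n, x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(data.frame(weight = round(x$weights, 4),
                   mean = round(x$means, 4),
                   variance = round(x$variances, 4)))
  invisible(x)
}

#' Plot a fitted mixture over the data histogram
#'
#' Histogram of the data with the total mixture density and the individual
#' weighted component curves overlaid.
#'
#' @param x a `mixfit`.
#' @param data the numeric vector the model was fitted to.
#' @param binwidth histogram bin width in log2 units (default 0.25).
#' @param main plot title.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plot_mixture <- function(x, data, binwidth = 0.25, main = "Expression-level
 distribution", ...) {
  breaks <- seq(floor(min(data) / binwidth) * binwidth,
                ceiling(max(data) / binwidth) * binwidth, by = binwidth)
  h <- graphics::hist(data, breaks = breaks, freq = FALSE, main = main,
                      xlab = "log2 normalized expression", border = "grey40",
                      col = "grey90", ...)
  grid <- seq(min(data) - 1, max(data) + 1, length.out = 512)
  dens <- mixture_density(x, grid, components = TRUE)
  for (k in seq_len(x$K))
    graphics::lines(grid, dens$components[, k], col = "steelblue", lty = 2)
  graphics::lines(grid, dens$total, col = "red", lwd = 2)
  invisible(h)
}
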