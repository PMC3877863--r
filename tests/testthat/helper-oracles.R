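# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: a plain-R EM with random restarts, a naive
# mixture log-likelihood, and closed-form OLS normal equations.

# naive direct-summation mixture log-likelihood (no log-sum-exp)
naive_loglik <- function(x, weights, means, variances) {
  dens <- sapply(seq_along(weights), function(k)
    weights[k] * dnorm(x, means[k], sqrt(variances[k])))
  dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

# plain-R EM from a given start; mirrors the textbook updates only
r_em <- function(x, K, family = "V", mu0, v0, w0 = rep(1 / K, K),
                 tol = 1e-10, max_iter = 2000L) {
  n <- length(x)
  w <- w0; mu <- mu0; v <- v0
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- sapply(seq_len(K), function(k) w[k] * dnorm(x, mu[k], sqrt(v[k])))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    if (any(rs == 0) || any(!is.finite(rs))) return(list(loglik = -Inf))
    ll <- sum(log(rs))
    r <- dens / rs
    if (abs(ll - prev) < tol * (abs(prev) + tol)) break
    prev <- ll
    nk <- colSums(r)
    if (any(nk == 0)) return(list(loglik = -Inf))
    w <- nk / n
    mu <- colSums(r * x) / nk
    if (family == "V") {
      v <- sapply(seq_len(K), function(k) sum(r[, k] * (x - mu[k])^2) / nk[k])
    } else {
      v <- rep(sum(sapply(seq_len(K), function(k)
        sum(r[, k] * (x - mu[k])^2))) / n, K)
    }
    v <- pmax(v, 1e-8 * var(x))
  }
  list(loglik = ll, weights = w, means = mu, variances = v)
}

# best log-likelihood over n_restarts random EM starts (brute-force oracle)
oracle_best_loglik <- function(x, K, family = "V", n_restarts = 200L,
                               seed = 1L) {
  set.seed(seed)
  best <- -Inf
  for (i in seq_len(n_restarts)) {
    mu0 <- runif(K, min(x), max(x))
    v0 <- rep(var(x) * runif(1, 0.1, 2), K)
    fit <- r_em(x, K, family, mu0, v0)
    if (fit$loglik > best) best <- fit$loglik
  }
  best
}

# closed-form OLS via normal equations
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# hand-built mixfit object for modality tests that need exact weights
make_model <- function(weights, means, variances = rep(1, length(weights)),
                       family = "V", n = 1000L) {
  K <- length(weights)
  ord <- order(means)
  n_params <- if (family == "V") 3L * K - 1L else 2L * K
  structure(list(K = K, family = family, weights = weights[ord],
                 means = means[ord], variances = variances[ord],
                 loglik = NA_real_, n = as.integer(n), n_params = n_params,
                 bic = NA_real_, converged = TRUE, n_iter = 0L,
                 loglik_trace = numeric(0), degenerate = FALSE),
            class = "mixfit")
}

# SAM fixture for a two-class expression experiment: n_loci loci with
# varying lengths and read lengths, half lowly and half highly covered
two_class_fixture_spec <- function(n_loci = 40L, seed = 7L) {
  lens <- rep(c(300L, 600L, 900L, 1200L), length.out = n_loci)
  loci <- data.frame(locus_tag = sprintf("L%03d", seq_len(n_loci)),
                     length = lens, stringsAsFactors = FALSE)
  low <- rep(c(2L, 3L, 4L), length.out = n_loci %/% 2L)
  high <- rep(c(40L, 48L, 56L), length.out = n_loci - n_loci %/% 2L)
  counts <- c(low, high)
  reads <- do.call(rbind, lapply(seq_len(n_loci), function(i) {
    data.frame(read_id = sprintf("%s_r%03d", loci$locus_tag[i],
                                 seq_len(counts[i])),
               target = loci$locus_tag[i],
               read_length = rep(c(40L, 50L, 60L),
                                 length.out = counts[i]),
               stringsAsFactors = FALSE)
  }))
  sam_fixture_spec(loci, reads, seed = seed)
}
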