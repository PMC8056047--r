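#' Fit a power law y = a0 * x^a1
#'
#' Least-squares fit of the two-parameter power law. The default fits a
#' linear model to `log(y) ~ log(x)`, which is stable and exactly
#' scale-equivariant; `method = "direct"` refines the log-space estimates by
#' nonlinear least squares on the original scale.
#'
#' @param x,y Strictly positive numeric vectors of equal length (at least 3
#'   points).
#' @param method `"loglog"` (default) or `"direct"`.
#' @param weights Optional non-negative case weights (e.g. the number of
#'   nodes behind each degree-aggregated point).
#' @return An object of class `power_law_fit`: a list with elements `a0`
#'   (prefactor), `a1` (exponent), `r_squared`, `n`, `method` and `data`.
#'   `r_squared` is computed in the fitting space and is `NA` when the
#'   response is constant.
#' @export
fit_power_law <- function(x, y, method = c("loglog", "direct"),
                          weights = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  w <- if (is.null(weights)) rep(1, length(x)) else weights[ok]
  if (length(x) < 3) stop("power-law fitting needs >= 3 points")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fitting needs strictly positive values")

  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx, weights = w)
  a1 <- unname(stats::coef(fit)[2])
  a0 <- exp(unname(stats::coef(fit)[1]))
  ybar <- stats::weighted.mean(ly, w)
  sst <- sum(w * (ly - ybar)^2)
  r2 <- if (sst < .Machine$double.eps) NA_real_ else
    1 - sum(w * stats::resid(fit)^2) / sst

  if (method == "direct") {
    nls_fit <- tryCatch(
      stats::nls(y ~ a0 * x^a1, start = list(a0 = a0, a1 = a1),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(nls_fit)) {
      co <- stats::coef(nls_fit)
      a0 <- unname(co["a0"]); a1 <- unname(co["a1"])
      sst <- sum((y - mean(y))^2)
      r2 <- if (sst < .Machine$double.eps) NA_real_ else
        1 - sum(stats::resid(nls_fit)^2) / sst
    }
  }

  structure(
    list(a0 = a0, a1 = a1, r_squared = r2, n = length(x), method = method,
         data = tibble::tibble(x = x, y = y)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): y = %.4g * x^%.4g  (r^2 = %s, n = %d)\n",
              x$method, x$a0, x$a1,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              x$n))
  invisible(x)
}

# Hurwitz zeta for the discrete power-law normalizer, via the Riemann zeta.
hurwitz_zeta <- function(s, xmin) {
  z <- pracma::zeta(s)
  if (xmin > 1) z <- z - sum(seq_len(xmin - 1)^(-s))
  z
}

# Maximum-likelihood exponent of a discrete power law with fixed xmin.
fit_discrete_exponent <- function(values, xmin) {
  slx <- sum(log(values))
  n <- length(values)
  nll <- function(g) n * log(hurwitz_zeta(g, xmin)) + g * slx
  stats::optimize(nll, interval = c(1.001, 25))$minimum
}

# KS distance between the empirical CDF of integer-valued data and the
# fitted discrete power-law CDF, over the observed support.
ks_discrete_powerlaw <- function(values, exponent, xmin) {
  kmax <- max(values)
  ks <- xmin:kmax
  emp <- cumsum(tabulate(values - xmin + 1L, nbins = kmax - xmin + 1L)) /
    length(values)
  theo <- cumsum(ks^(-exponent)) / hurwitz_zeta(exponent, xmin)
  max(abs(emp - theo))
}

#' Sample from a discrete power law
#'
#' Draws integers from `P(X = k) propto k^-exponent` for `k >= xmin`, with
#' the support truncated at `kmax` (tail mass beyond `kmax` is negligible
#' for the exponents of interest).
#'
#' @param n Sample size.
#' @param exponent Power-law exponent (> 1).
#' @param xmin Smallest attainable value (default 1).
#' @param kmax Support truncation (default 1e5).
#' @return Integer vector of length `n`.
#' @export
sample_power_law <- function(n, exponent, xmin = 1L, kmax = 1e5L) {
  stopifnot(exponent > 1, xmin >= 1)
  support <- xmin:kmax
  sample(support, size = n, replace = TRUE, prob = support^(-exponent))
}

#' Bootstrap goodness of fit for a discrete power-law degree distribution
#'
#' Fits a discrete power law to the sample by maximum likelihood (with
#' `xmin` fixed at the sample minimum: full-range fit, no lower-cutoff
#' search), measures the Kolmogorov-Smirnov distance between the empirical
#' and fitted distributions, and compares it against the KS distances of
#' `n_resamples` synthetic samples drawn from the fitted law and refitted
#' the same way. The bootstrap p-value is the fraction of synthetic samples
#' whose KS distance exceeds the observed one; values above 0.1 are
#' conventionally read as "the power law is a plausible fit".
#'
#' @param values Positive integer sample (e.g. a degree sequence); at least
#'   two distinct values.
#' @param n_resamples Number of bootstrap resamples (default 2500).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `power_law_gof`: list with `ks_statistic`,
#'   `bootstrap_p`, `exponent` (fitted), `xmin`, `n`, `n_resamples`, `seed`.
#' @export
goodness_of_fit <- function(values, n_resamples = 2500, seed = 1L) {
  values <- as.integer(round(values))
  values <- values[values > 0]
  if (length(unique(values)) < 2) {
    stop("degenerate sample: need at least two distinct positive values")
  }
  stopifnot(n_resamples >= 1)
  xmin <- min(values)
  ghat <- fit_discrete_exponent(values, xmin)
  ks_obs <- ks_discrete_powerlaw(values, ghat, xmin)

  n <- length(values)
  set.seed(seed)
  ks_boot <- vapply(seq_len(n_resamples), function(i) {
    synth <- sample_power_law(n, ghat, xmin)
    g_b <- fit_discrete_exponent(synth, xmin)
    ks_discrete_powerlaw(synth, g_b, xmin)
  }, numeric(1))

  structure(
    list(ks_statistic = ks_obs,
         bootstrap_p = mean(ks_boot > ks_obs),
         exponent = ghat, xmin = xmin, n = n,
         n_resamples = n_resamples, seed = seed),
    class = "power_law_gof"
  )
}

#' @export
print.power_law_gof <- function(x, ...) {
  cat(sprintf(
    "Discrete power-law GOF: exponent = %.3f (xmin = %d), KS = %.4f, bootstrap p = %.3f (%d resamples)\n",
    x$exponent, x$xmin, x$ks_statistic, x$bootstrap_p, x$n_resamples))
  invisible(x)
}

#' Classify network topology from the six fitted exponents
#'
#' Reads the sign pattern of the six power-law exponents. A negative
#' degree-distribution exponent with a negative clustering exponent and
#' positive exponents for neighborhood connectivity and the three
#' centralities is the signature of a weakly hierarchical scale-free
#' network with assortative mixing. The sign of the neighborhood
#' connectivity exponent alone labels the mixing as assortative (positive)
#' or disassortative (negative).
#'
#' @param fits A tibble from [topology_exponents()] (columns `property` and
#'   `exponent`), or a named numeric vector of the six exponents.
#' @return A list with `label` (character), `assortativity`
#'   (`"assortative"`, `"disassortative"` or `"neutral"`), and `signs`
#'   (tibble of property/exponent/sign).
#' @export
classify_topology <- function(fits) {
  props <- c("degree_distribution", "clustering", "neighborhood_connectivity",
             "betweenness", "closeness", "eigenvector")
  if (is.data.frame(fits)) {
    ex <- stats::setNames(fits$exponent, fits$property)
  } else {
    ex <- fits
  }
  missing <- setdiff(props, names(ex))
  if (length(missing) > 0 || anyNA(ex[props])) {
    stop("classify_topology needs exponents for all six properties; missing/NA: ",
         paste(union(missing, props[is.na(ex[props])]), collapse = ", "))
  }
  ex <- ex[props]
  sgn <- sign(ex)
  assort <- if (sgn["neighborhood_connectivity"] > 0) {
    "assortative"
  } else if (sgn["neighborhood_connectivity"] < 0) {
    "disassortative"
  } else "neutral"

  label <- if (all(sgn == 0)) {
    "indeterminate"
  } else if (sgn["degree_distribution"] < 0 && sgn["clustering"] < 0 &&
             sgn["neighborhood_connectivity"] > 0 && sgn["betweenness"] > 0 &&
             sgn["closeness"] > 0 && sgn["eigenvector"] > 0) {
    "weak hierarchical scale-free, assortative"
  } else {
    paste0(
      if (sgn["degree_distribution"] < 0) "scale-free" else "non-scale-free",
      if (sgn["clustering"] < 0) ", hierarchical" else "",
      ", ", assort
    )
  }
  list(
    label = label,
    assortativity = assort,
    signs = tibble::tibble(property = props, exponent = unname(ex),
                           sign = unname(sgn))
  )
}
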