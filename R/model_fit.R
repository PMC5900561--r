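#' Half-life from a decay constant
#'
#' `hl = ln(2) / lambda` for a first-order decay constant in per-hour units.
#'
#' @param lam decay constant(s), per hour; must be > 0.
#' @return Half-life in hours.
#' @export
half_life <- function(lam) {
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("decay constant must be > 0")
  log(2) / lam
}

#' Growth-dilution rate from a doubling time
#'
#' `gamma = ln(2) / delta` converts a cellular doubling time into the
#' growth-dilution rate that adds to the decay constant in the bounded-growth
#' model. `delta = Inf` (non-dividing cells) gives `gamma = 0`.
#'
#' @param delta doubling time in hours; must be > 0 (Inf allowed).
#' @return Growth rate in per-hour units.
#' @export
growth_rate <- function(delta) {
  if (any(is.na(delta)) || any(delta <= 0)) stop("doubling time must be > 0")
  log(2) / delta
}

druid_fit_row <- function(gene_id, N0, lambda, gamma, converged, rss, n_points) {
  data.frame(
    gene_id = gene_id,
    N0 = N0,
    lambda = lambda,
    gamma = gamma,
    half_life = if (isTRUE(converged)) log(2) / lambda else NA_real_,
    converged = converged,
    rss = rss,
    n_points = n_points,
    stringsAsFactors = FALSE
  )
}

# One weighted Levenberg-Marquardt pass; returns NULL on optimizer failure.
nls_pass <- function(formula, data, start, lower, upper, w) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                           ptol = 1e-11)
    )),
    error = function(e) NULL
  )
}

#' Fit the bounded-growth labeling model to one gene
#'
#' Minimizes the weighted residual sum of squares of
#' `N(t) = N0 * (1 - exp(-(lambda + gamma) * t))` over `N0 > 0`,
#' `lambda > 0` for an approach-to-equilibrium labeling time course. `gamma`
#' is held fixed at the supplied growth-dilution rate (`ln(2)/doubling time`
#' for spike-in normalized data, 0 when the normalization already absorbs
#' growth). Measurements at `t = 0` are dropped: no labeled RNA exists before
#' labeling starts, so the protocol takes no measurement there.
#'
#' Failures are never raised per gene: if the optimizer fails, the decay
#' constant lands on a box bound, or the series carries no decay information
#' (the fitted curve is already above `saturation_limit` of its plateau at
#' the first sampled time), the result is flagged `converged = FALSE` and the
#' gene carries no half-life.
#'
#' The default weighting `w(t) = 1/max(fitted(t), 1e-8)` stabilizes the
#' Poisson-like variance of count-derived signal and is applied by iterated
#' reweighting (two reweighted passes after an unweighted one).
#'
#' @param times sampling times in hours.
#' @param values normalized abundances, same length as `times`, all >= 0.
#' @param gamma growth-dilution rate (per hour, >= 0) held fixed in the fit.
#' @param weights `"poisson"` (default) or `"uniform"`.
#' @param lambda_bounds box bounds for the decay constant, per hour.
#' @param saturation_limit identifiability guard: flag the fit non-converged
#'   when `1 - exp(-(lambda+gamma)*min(t))` exceeds this value, i.e. the
#'   curve saturates before the first time point and only a lower bound on
#'   `lambda` is determined.
#' @param gene_id optional id copied into the result.
#' @return One-row data frame: `gene_id`, `N0`, `lambda`, `gamma`,
#'   `half_life` (NA unless converged), `converged`, `rss` (weighted),
#'   `n_points`.
#' @export
fit_bounded_growth <- function(times, values, gamma = 0,
                               weights = c("poisson", "uniform"),
                               lambda_bounds = c(1e-5, 50),
                               saturation_limit = 0.99,
                               gene_id = NA_character_) {
  weights <- match.arg(weights)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be finite and >= 0")
  if (anyNA(values) || any(values < 0)) stop("series values must be non-negative")
  keep <- times > 0
  t <- as.numeric(times[keep])
  y <- as.numeric(values[keep])
  if (length(t) < 3) stop("bounded-growth fit needs >= 3 positive-time points")
  fail <- function() druid_fit_row(gene_id, NA_real_, NA_real_, gamma, FALSE,
                                   NA_real_, length(t))
  if (max(y) <= 0) return(fail())

  n0_init <- max(y)
  # log-linearization of 1 - y/N0 gives a deterministic lambda start
  lam_init <- {
    ok <- y > 0 & y < n0_init
    li <- NA_real_
    if (sum(ok) >= 2) {
      z <- -log(1 - y[ok] / (1.05 * n0_init))
      li <- sum(z * t[ok]) / sum(t[ok]^2) - gamma
    }
    if (!is.finite(li) || li <= 0) li <- log(2) / stats::median(t)
    min(max(li, lambda_bounds[1] * 10), lambda_bounds[2] / 10)
  }

  d <- data.frame(t = t, y = y)
  lower <- c(N0 = 1e-12, lam = lambda_bounds[1])
  upper <- c(N0 = 1e6 * max(y), lam = lambda_bounds[2])
  start <- c(N0 = n0_init, lam = lam_init)
  w <- rep(1, length(t))
  n_pass <- if (weights == "poisson") 3L else 1L
  fit <- NULL
  for (i in seq_len(n_pass)) {
    fit <- nls_pass(y ~ N0 * (1 - exp(-(lam + gamma) * t)), d, start, lower,
                    upper, w)
    if (is.null(fit)) return(fail())
    cf <- stats::coef(fit)
    if (weights == "poisson") {
      w <- 1 / pmax(cf[["N0"]] * (1 - exp(-(cf[["lam"]] + gamma) * t)), 1e-8)
      start <- cf
    }
  }
  cf <- stats::coef(fit)
  lam <- cf[["lam"]]
  n0 <- cf[["N0"]]
  at_bound <- lam <= lambda_bounds[1] * (1 + 1e-6) ||
    lam >= lambda_bounds[2] * (1 - 1e-6)
  saturated <- (1 - exp(-(lam + gamma) * min(t))) > saturation_limit
  converged <- !at_bound && !saturated && n0 > 0
  druid_fit_row(gene_id, n0, lam, gamma, converged, stats::deviance(fit),
                length(t))
}

#' Fit an exponential-decay model to one gene of a shutoff time course
#'
#' Nonlinear least squares for `N(t) = N0 * exp(-lambda * t)` over `N0 > 0`,
#' `lambda > 0`, for transcription-inhibition experiments (actinomycin D,
#' alpha-amanitin, temperature-sensitive polymerase). The series must include
#' a `t = 0` measurement anchoring `N0`. Convergence contract as in
#' [fit_bounded_growth()]: bound hits and optimizer failures are flagged, not
#' raised.
#'
#' @inheritParams fit_bounded_growth
#' @return One-row data frame as in [fit_bounded_growth()] (`gamma` is 0).
#' @export
fit_exponential_decay <- function(times, values,
                                  weights = c("poisson", "uniform"),
                                  lambda_bounds = c(1e-5, 50),
                                  gene_id = NA_character_) {
  weights <- match.arg(weights)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (anyNA(values) || any(values < 0)) stop("series values must be non-negative")
  if (length(times) < 3) stop("exponential-decay fit needs >= 3 time points")
  if (!any(times == 0)) stop("shutoff series must include a t = 0 measurement")
  t <- as.numeric(times)
  y <- as.numeric(values)
  fail <- function() druid_fit_row(gene_id, NA_real_, NA_real_, 0, FALSE,
                                   NA_real_, length(t))
  if (max(y) <= 0) return(fail())

  n0_init <- max(y[t == 0], max(y) * 0.5)
  lam_init <- {
    ok <- y > 0
    li <- NA_real_
    if (sum(ok) >= 2) {
      li <- -stats::coef(stats::lm(log(y[ok]) ~ t[ok]))[[2]]
    }
    if (!is.finite(li) || li <= 0) li <- log(2) / stats::median(t[t > 0])
    min(max(li, lambda_bounds[1] * 10), lambda_bounds[2] / 10)
  }

  d <- data.frame(t = t, y = y)
  lower <- c(N0 = 1e-12, lam = lambda_bounds[1])
  upper <- c(N0 = 1e6 * max(y), lam = lambda_bounds[2])
  start <- c(N0 = n0_init, lam = lam_init)
  w <- rep(1, length(t))
  n_pass <- if (weights == "poisson") 3L else 1L
  fit <- NULL
  for (i in seq_len(n_pass)) {
    fit <- nls_pass(y ~ N0 * exp(-lam * t), d, start, lower, upper, w)
    if (is.null(fit)) return(fail())
    cf <- stats::coef(fit)
    if (weights == "poisson") {
      w <- 1 / pmax(cf[["N0"]] * exp(-cf[["lam"]] * t), 1e-8)
      start <- cf
    }
  }
  cf <- stats::coef(fit)
  lam <- cf[["lam"]]
  at_bound <- lam <= lambda_bounds[1] * (1 + 1e-6) ||
    lam >= lambda_bounds[2] * (1 - 1e-6)
  converged <- !at_bound && cf[["N0"]] > 0
  druid_fit_row(gene_id, cf[["N0"]], lam, 0, converged, stats::deviance(fit),
                length(t))
}

#' Fit the kinetic model to every gene of a normalized series
#'
#' Vectorized driver over a [normalized_series()]. The growth-dilution rate
#' follows the experiment design: `gamma = ln(2)/doubling_time` for spike-in
#' normalized data, `gamma = 0` for intron-normalized data (the endogenous
#' factor already tracks the growing transcriptome). A `gamma` argument
#' overrides the design. Per-gene failures become `converged = FALSE` rows.
#'
#' @param series a `normalized_series`.
#' @param design optional [experiment_design()] supplying `gamma` and the
#'   model type.
#' @param gamma explicit growth-dilution rate; overrides `design`.
#' @param model `"bounded_growth"` (labeling course) or `"exponential_decay"`
#'   (shutoff course).
#' @param weights `"poisson"` or `"uniform"`.
#' @param quiet suppress the convergence summary message.
#' @return Data frame, one row per gene, columns as in [fit_bounded_growth()].
#' @export
fit_table <- function(series, design = NULL, gamma = NULL,
                      model = c("bounded_growth", "exponential_decay"),
                      weights = c("poisson", "uniform"), quiet = FALSE) {
  stopifnot(inherits(series, "normalized_series"))
  model <- match.arg(model)
  weights <- match.arg(weights)
  if (is.null(gamma)) {
    gamma <- if (!is.null(design)) design_gamma(design) else 0
  }
  t <- series$time_points
  rows <- lapply(rownames(series$values), function(g) {
    y <- series$values[g, ]
    res <- tryCatch({
      if (model == "bounded_growth") {
        fit_bounded_growth(t, y, gamma = gamma, weights = weights, gene_id = g)
      } else {
        fit_exponential_decay(t, y, weights = weights, gene_id = g)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      res <- druid_fit_row(g, NA_real_, NA_real_, gamma, FALSE, NA_real_,
                           length(t))
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!quiet) {
    message(sprintf("fit_table: %d/%d genes converged (%s, gamma = %.4g /h)",
                    sum(out$converged), nrow(out), model, gamma))
  }
  out
}
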