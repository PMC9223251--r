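# Calendar-time trend in the SMR: Bayesian Poisson regression with the
# yearly expected deaths as an offset,
#   observed_t ~ Poisson(expected_t * exp(f(year_t))),
# where f is linear or a B-spline in calendar year. Candidate bases are
# compared by DIC. Posteriors come from a blocked random-walk Metropolis
# sampler with weakly informative Normal(0, 10^2) priors; the proposal is
# scaled from the Poisson GLM curvature, so mixing is good for these small
# (2-4 coefficient) models.

#' Define a trend basis
#' @param kind "linear" or "bspline".
#' @param df degrees of freedom (1 for linear; 2 or 3 for B-splines).
#' @return object of class `trend_basis`.
#' @export
trend_basis <- function(kind = c("linear", "bspline"), df = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    if (is.null(df)) df <- 1L
    if (df != 1L) stop("linear basis has df = 1")
  } else {
    if (is.null(df)) df <- 3L
    if (!df %in% c(2L, 3L)) stop("bspline basis supports df = 2 or 3")
  }
  structure(list(kind = kind, df = as.integer(df)), class = "trend_basis")
}

#' @export
print.trend_basis <- function(x, ...) {
  cat("<trend_basis> ", x$kind, " (df=", x$df, ")\n", sep = ""); invisible(x)
}

basis_label <- function(basis) {
  if (basis$kind == "linear") "linear" else paste0("bspline-", basis$df)
}

# Design matrix: intercept + centred/scaled year term(s). B-splines of df 2
# use a quadratic basis (a cubic B-spline needs at least 3 df); df 3 is
# cubic with interior knots at quantiles of the observed years (the
# splines::bs default).
basis_matrix <- function(basis, year) {
  x <- (year - mean(year)) / stats::sd(year)
  if (basis$kind == "linear") {
    X <- cbind(1, x)
  } else {
    X <- cbind(1, splines::bs(x, df = basis$df,
                              degree = min(3L, basis$df)))
  }
  colnames(X) <- c("(Intercept)", paste0("b", seq_len(ncol(X) - 1L)))
  X
}

# Split-chain potential scale reduction factor (rank-normalization omitted;
# these are smooth unimodal posteriors).
split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (ch in draws_by_chain) {
    n <- length(ch)
    halves <- c(halves, list(ch[seq_len(n %/% 2)]),
                list(ch[(n %/% 2 + 1):n]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Poisson offset trend to yearly SMR data
#'
#' @param yearly data.table from [smr_by_year()] (one country). Years with
#'   zero expected deaths are dropped with a warning.
#' @param basis a [trend_basis()].
#' @param chains number of MCMC chains (default 4).
#' @param iter posterior draws per chain after warm-up (default 5000).
#' @param warmup adaptation iterations discarded per chain (default 1000).
#' @param prior_sd prior SD of the Normal(0, prior_sd^2) coefficient priors.
#' @param seed RNG seed.
#' @return object of class `trend_fit`: posterior coefficient draws, the
#'   fitted SMR curve (2.5/50/97.5 posterior percentiles per year), DIC and
#'   effective parameters pD, split-Rhat per coefficient, and a
#'   `converged` flag (all Rhat <= 1.05).
#' @export
fit_trend <- function(yearly, basis = trend_basis("bspline", 3),
                      chains = 4, iter = 5000, warmup = 1000,
                      prior_sd = 10, seed = 1) {
  yearly <- data.table::as.data.table(yearly)
  drop <- yearly$expected <= 0 | !is.finite(yearly$expected)
  if (any(drop)) {
    warning("dropping ", sum(drop), " year(s) with zero expected deaths")
    yearly <- yearly[!drop]
  }
  p_needed <- basis$df + 1L
  if (nrow(yearly) < p_needed + 1L) {
    stop("too few years with expected > 0 for a df=", basis$df, " basis")
  }
  y <- yearly$observed
  E <- yearly$expected
  X <- basis_matrix(basis, yearly$calendar_year)
  p <- ncol(X)
  logE <- log(E)

  log_post <- function(beta) {
    eta <- drop(X %*% beta) + logE
    sum(y * eta - exp(eta)) - sum(beta^2) / (2 * prior_sd^2)
  }
  deviance_of <- function(beta) {
    eta <- drop(X %*% beta) + logE
    -2 * sum(stats::dpois(y, exp(eta), log = TRUE))
  }

  # proposal from GLM curvature
  glm_fit <- suppressWarnings(
    stats::glm.fit(X, y, offset = logE, family = stats::poisson())
  )
  beta_hat <- glm_fit$coefficients
  eta_hat <- drop(X %*% beta_hat) + logE
  info <- crossprod(X * sqrt(exp(eta_hat)))
  Sigma <- solve(info + diag(1 / prior_sd^2, p))
  L <- chol(Sigma)

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = chains * iter, ncol = p)
  dev_draws <- numeric(chains * iter)
  acc_rates <- numeric(chains)
  chain_idx <- vector("list", chains)
  for (ch in seq_len(chains)) {
    scale <- 2.38 / sqrt(p)
    beta <- beta_hat + drop(crossprod(L, stats::rnorm(p, sd = 0.5)))
    lp <- log_post(beta)
    acc <- 0L
    for (it in seq_len(warmup + iter)) {
      prop <- beta + scale * drop(crossprod(L, stats::rnorm(p)))
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) < lp_prop - lp) {
        beta <- prop; lp <- lp_prop; acc <- acc + 1L
      }
      if (it <= warmup && it %% 50 == 0) {
        rate <- acc / it
        scale <- scale * exp(rate - 0.30)
      }
      if (it > warmup) {
        row <- (ch - 1L) * iter + (it - warmup)
        draws[row, ] <- beta
        dev_draws[row] <- deviance_of(beta)
      }
    }
    acc_rates[ch] <- acc / (warmup + iter)
    chain_idx[[ch]] <- (ch - 1L) * iter + seq_len(iter)
  }

  rhat <- vapply(seq_len(p), function(j) {
    split_rhat(lapply(chain_idx, function(ix) draws[ix, j]))
  }, numeric(1))
  converged <- all(rhat <= 1.05)
  if (!converged) {
    warning("trend fit flagged: split-Rhat > 1.05 on ",
            sum(rhat > 1.05), " coefficient(s)")
  }

  beta_bar <- colMeans(draws)
  d_bar <- mean(dev_draws)
  p_d <- d_bar - deviance_of(beta_bar)
  dic <- d_bar + p_d

  curve_draws <- exp(X %*% t(draws))  # years x draws
  qs <- t(apply(curve_draws, 1, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  curve <- data.table::data.table(
    calendar_year = yearly$calendar_year,
    smr_fit = qs[, 2], lo95 = qs[, 1], hi95 = qs[, 3]
  )

  structure(list(
    basis = basis, draws = draws, X = X, years = yearly$calendar_year,
    curve = curve, dic = dic, p_d = p_d, deviance_mean = d_bar,
    rhat = rhat, converged = converged, accept_rate = acc_rates,
    beta_mean = beta_bar
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> basis=", basis_label(x$basis),
      " DIC=", round(x$dic, 2), " pD=", round(x$p_d, 2),
      " max Rhat=", round(max(x$rhat), 4),
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Choose the trend basis by DIC
#'
#' Fits every candidate basis and returns the one with the smallest
#' deviance information criterion; DIC ties within 0.5 are broken in favour
#' of fewer degrees of freedom.
#'
#' @inheritParams fit_trend
#' @param bases list of [trend_basis()] candidates (default: linear,
#'   B-spline df 2, B-spline df 3).
#' @param ... passed to [fit_trend()].
#' @return list with `best` (a `trend_fit`) and `dic_table` (data.table of
#'   basis, df, DIC, pD, converged).
#' @export
select_model <- function(yearly,
                         bases = list(trend_basis("linear"),
                                      trend_basis("bspline", 2),
                                      trend_basis("bspline", 3)),
                         ...) {
  fits <- lapply(bases, function(b) fit_trend(yearly, basis = b, ...))
  dic_table <- data.table::data.table(
    basis = vapply(fits, function(f) basis_label(f$basis), character(1)),
    df = vapply(fits, function(f) f$basis$df, integer(1)),
    dic = vapply(fits, function(f) f$dic, numeric(1)),
    p_d = vapply(fits, function(f) f$p_d, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  best_dic <- min(dic_table$dic)
  near <- which(dic_table$dic <= best_dic + 0.5)
  pick <- near[which.min(dic_table$df[near])]
  list(best = fits[[pick]], dic_table = dic_table, fits = fits)
}
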