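#' Configure a synthetic TTO valuation simulation
#'
#' Defines the generating process for respondent-level time trade-off
#' (TTO) disutility observations: each respondent values each state, and
#' the observed disutility is the tariff's true disutility
#' (`1 - predicted utility`) plus independent Gaussian noise.
#'
#' Defaults emulate a desk-scale valuation exercise over the full design
#' space: the published US tariff as truth, all 242 impaired states
#' valued, 50 respondents per state, and noise standard deviation 0.2 on
#' the disutility scale (individual TTO responses scatter widely around
#' the mean value; 0.2 is a realistic per-response spread). No clipping
#' by default; real TTO disutilities are bounded, so an optional clip
#' range is available.
#'
#' @param tariff generating `eq_tariff`; default [us_d1o_tariff()].
#' @param states states to value; default the 242 impaired states.
#' @param n_respondents respondents per state (>= 1).
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   disutilities (>= 0).
#' @param seed integer random seed; a fixed seed makes the dataset
#'   byte-identical across runs.
#' @param clip optional length-2 numeric `c(lo, hi)`; observed
#'   disutilities are clamped into this range after noise is added.
#' @return An object of class `eq_sim_config`.
#' @seealso [simulate_tto()], [fit_ols()], [recovery_experiment()]
#' @export
sim_config <- function(tariff = us_d1o_tariff(),
                       states = enumerate_states(include_perfect = FALSE),
                       n_respondents = 50, noise_sd = 0.2, seed = 1,
                       clip = NULL) {
  stopifnot(inherits(tariff, "eq_tariff"))
  if (length(states) == 0L) stop("`states` must be non-empty")
  parse_state(states)  # validate codes
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stop("`n_respondents` must be at least 1")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(clip) && (length(clip) != 2L || clip[1] > clip[2])) {
    stop("`clip` must be NULL or c(lo, hi) with lo <= hi")
  }
  structure(
    list(tariff = tariff, states = states,
         n_respondents = as.integer(n_respondents),
         noise_sd = noise_sd, seed = as.integer(seed), clip = clip),
    class = "eq_sim_config"
  )
}

#' @export
print.eq_sim_config <- function(x, ...) {
  cat("TTO simulation config: ", length(x$states), " states x ",
      x$n_respondents, " respondents, noise sd ", x$noise_sd,
      ", seed ", x$seed,
      if (!is.null(x$clip)) paste0(", clip [", x$clip[1], ", ", x$clip[2], "]"),
      "\n  truth: ", x$tariff$spec$name, " tariff\n", sep = "")
  invisible(x)
}

#' Simulate respondent-level TTO disutility observations
#'
#' Draws `n_respondents` observations per state: true disutility under
#' the configured tariff plus iid Gaussian noise, clipped last if a clip
#' range is configured. Deterministic for a fixed seed.
#'
#' @param config an [sim_config()] object.
#' @return Data frame with one row per (state, respondent): columns
#'   `state`, `respondent`, `disutility`. The config is attached as
#'   attribute `config`.
#' @examples
#' d <- simulate_tto(sim_config(n_respondents = 2, noise_sd = 0))
#' head(d)
#' @export
simulate_tto <- function(config) {
  stopifnot(inherits(config, "eq_sim_config"))
  true_disutility <- 1 - predict_value(config$tariff, config$states)
  n <- config$n_respondents
  set.seed(config$seed)
  out <- data.frame(
    state = rep(config$states, each = n),
    respondent = rep(seq_len(n), times = length(config$states)),
    disutility = rep(unname(true_disutility), each = n) +
      rnorm(length(config$states) * n, mean = 0, sd = config$noise_sd),
    row.names = NULL
  )
  if (!is.null(config$clip)) {
    out$disutility <- pmin(pmax(out$disutility, config$clip[1]), config$clip[2])
  }
  attr(out, "config") <- config
  out
}

#' Fit a specification to TTO disutility data by OLS
#'
#' Ordinary least squares of observed disutility on the specification's
#' design (no added intercept beyond the specification's own). Estimates
#' are reported back on the tariff's signed "add to 1" scale (the
#' negative of the disutility-scale coefficients), so the result
#' converts directly to a tariff via [as_tariff()].
#'
#' Rows for state 11111, if present, are dropped with a message: the
#' perfect state carries the axiomatic value 1 and is outside the
#' prediction scope of every specification.
#'
#' R-squared is centered (`1 - RSS/TSS` about the mean response) for all
#' specifications, including the no-intercept `"D1O"`: its column space
#' contains the constant over the impaired states, so the centered
#' quantity is well defined and identical between equivalent
#' specifications.
#'
#' @param data data frame with columns `state` and `disutility`
#'   (typically from [simulate_tto()]).
#' @param spec a specification name or [model_spec()] object.
#' @return An object of class `eq_fit`: list with `spec`,
#'   `coefficients` (tariff scale), `se`, `vcov`, `sigma2`,
#'   `df_residual`, `rss`, `r_squared`, `n_obs`, `states` (unique
#'   states fitted), `fitted_utility` (per unique state).
#' @examples
#' d <- simulate_tto(sim_config(n_respondents = 2, noise_sd = 0))
#' fit <- fit_ols(d, "D1O")
#' all.equal(fit$coefficients, us_d1o_tariff()$coefficients)
#' @export
fit_ols <- function(data, spec) {
  stopifnot(is.data.frame(data), all(c("state", "disutility") %in% names(data)))
  spec <- model_spec(spec)
  perfect <- data$state == "11111"
  if (any(perfect)) {
    message("dropping ", sum(perfect),
            " observation(s) of state 11111 (axiomatic value, outside prediction scope)")
    data <- data[!perfect, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no impaired-state observations to fit")
  X <- build_design(spec, data$state)
  y <- data$disutility
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dependent <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design is rank deficient; linearly dependent column(s): ",
         paste(dependent, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  residuals <- y - as.vector(X %*% beta)
  rss <- sum(residuals^2)
  df_residual <- nrow(X) - ncol(X)
  sigma2 <- rss / df_residual
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  vcov <- sigma2 * xtx_inv
  se <- sqrt(diag(vcov))
  unique_states <- unique(data$state)
  Xu <- build_design(spec, unique_states)
  fitted_utility <- setNames(1 - as.vector(Xu %*% beta), unique_states)
  structure(
    list(
      spec = spec,
      coefficients = setNames(-beta, colnames(X)),
      se = se, vcov = vcov, sigma2 = sigma2,
      df_residual = df_residual, rss = rss,
      r_squared = 1 - rss / sum((y - mean(y))^2),
      n_obs = nrow(X), states = unique_states,
      fitted_utility = fitted_utility
    ),
    class = "eq_fit"
  )
}

#' @export
print.eq_fit <- function(x, digits = 4, ...) {
  cat("OLS fit: specification ", x$spec$name, ", ", x$n_obs,
      " observations over ", length(x$states), " states\n",
      "R-squared ", round(x$r_squared, digits),
      ", residual sd ", round(sqrt(x$sigma2), digits), "\n", sep = "")
  print(data.frame(coefficient = round(x$coefficients, digits),
                   se = round(x$se, digits)))
  invisible(x)
}

#' Convert an OLS fit to a tariff
#'
#' @param fit an `eq_fit`.
#' @return An `eq_tariff` with the fit's coefficients and SEs.
#' @export
as_tariff <- function(fit) {
  stopifnot(inherits(fit, "eq_fit"))
  tariff(fit$spec, fit$coefficients, se = fit$se)
}

#' Standard error of a predicted state value
#'
#' Propagates the coefficient covariance of a fit to the predicted value
#' of a state, whose design row is `x`:
#' * `"full_covariance"`: `sqrt(x' V x)` with `V` the full coefficient
#'   covariance -- the correct delta-method SE. Equivalent
#'   re-parameterizations of the same fit give identical values.
#' * `"diagonal_only"`: `sqrt(sum(x^2 * diag(V)))`, ignoring coefficient
#'   covariances -- the naive accounting in which a term's SE is
#'   "invoked" once per unit of its predictor value (so for a
#'   five-impairment state the D1 term's variance enters with multiplier
#'   4^2, while the constant's enters once). Under this accounting the
#'   two parameterizations genuinely differ.
#'
#' State 11111 has prediction SE 0 in both modes (axiomatic value; its
#' design row, intercept included, is all zero).
#'
#' @param fit an `eq_fit`.
#' @param states character vector of state codes.
#' @param mode `"full_covariance"` (default) or `"diagonal_only"`.
#' @return Named numeric vector of prediction SEs.
#' @export
prediction_se <- function(fit, states,
                          mode = c("full_covariance", "diagonal_only")) {
  stopifnot(inherits(fit, "eq_fit"))
  mode <- match.arg(mode)
  X <- build_design(fit$spec, states)
  if ("(Intercept)" %in% colnames(X)) {
    X[rownames(X) == "11111", "(Intercept)"] <- 0
  }
  V <- fit$vcov[colnames(X), colnames(X)]
  variance <- if (mode == "full_covariance") {
    rowSums((X %*% V) * X)
  } else {
    as.vector(X^2 %*% diag(V))
  }
  setNames(sqrt(pmax(variance, 0)), states)
}

#' Monte-Carlo coefficient recovery experiment
#'
#' Repeatedly simulates a TTO dataset under the configured truth and
#' refits the requested specifications, summarizing per coefficient the
#' mean estimate, bias against the generating value, the Monte-Carlo SE
#' of that bias, the empirical SD of the estimates across replicates,
#' and the mean reported (OLS) SE. The generating value for a
#' specification other than the truth's is obtained through the exact
#' re-parameterization where one exists (D1O <-> D1C), and is `NA`
#' otherwise.
#'
#' Replicate `i` uses seed `config$seed + i` (deterministic counter
#' derivation from the master seed).
#'
#' @param config an [sim_config()].
#' @param replicates number of Monte-Carlo replicates (>= 2).
#' @param specs specifications to refit each replicate.
#' @return An object of class `eq_recovery`: list with `summaries` (one
#'   data frame per specification: `predictor`, `true`,
#'   `mean_estimate`, `bias`, `mc_se`, `empirical_sd`,
#'   `mean_reported_se`), `replicates`, `config`.
#' @examples
#' \donttest{
#' r <- recovery_experiment(sim_config(n_respondents = 5), replicates = 20)
#' r$summaries$D1O
#' }
#' @export
recovery_experiment <- function(config, replicates = 200,
                                specs = c("D1O", "D1C")) {
  stopifnot(inherits(config, "eq_sim_config"))
  if (replicates < 2) stop("`replicates` must be at least 2")
  specs <- vapply(specs, function(s) model_spec(s)$name, character(1))
  estimates <- reported_se <- setNames(vector("list", length(specs)), specs)
  for (i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + i
    dat <- simulate_tto(cfg)
    for (s in specs) {
      fit <- fit_ols(dat, s)
      estimates[[s]] <- rbind(estimates[[s]], fit$coefficients)
      reported_se[[s]] <- rbind(reported_se[[s]], fit$se)
    }
  }
  truth_for <- function(s) {
    truth <- config$tariff
    if (truth$spec$name == s) return(truth$coefficients)
    if (truth$spec$name == "D1O" && s == "D1C") {
      return(reparameterize(truth)$coefficients)
    }
    if (truth$spec$name == "D1C" && s == "D1O") {
      return(inverse_reparameterize(truth)$coefficients)
    }
    NULL
  }
  summaries <- lapply(specs, function(s) {
    est <- estimates[[s]]
    true <- truth_for(s)
    mean_est <- colMeans(est)
    emp_sd <- apply(est, 2L, sd)
    data.frame(
      predictor = colnames(est),
      true = if (is.null(true)) NA_real_ else unname(true[colnames(est)]),
      mean_estimate = unname(mean_est),
      bias = if (is.null(true)) NA_real_ else unname(mean_est - true[colnames(est)]),
      mc_se = unname(emp_sd / sqrt(replicates)),
      empirical_sd = unname(emp_sd),
      mean_reported_se = unname(colMeans(reported_se[[s]])),
      row.names = NULL
    )
  })
  structure(list(summaries = setNames(summaries, specs),
                 replicates = replicates, config = config),
            class = "eq_recovery")
}

#' @export
print.eq_recovery <- function(x, digits = 4, ...) {
  cat("Coefficient recovery over", x$replicates, "replicates\n")
  for (s in names(x$summaries)) {
    cat("\nSpecification ", s, ":\n", sep = "")
    tab <- x$summaries[[s]]
    tab[-1L] <- lapply(tab[-1L], round, digits)
    print(tab)
  }
  invisible(x)
}
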