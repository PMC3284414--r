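#' Construct a tariff
#'
#' A tariff is a model specification plus one coefficient per predictor
#' (and the constant, for intercept specifications), on the signed
#' "add to 1" scale: the predicted utility of an impaired state is
#' `1 + sum(coefficient * predictor value)`, so dummy coefficients are
#' negative and the D1 coefficient positive. State 11111 carries the
#' axiomatic value 1 and sits outside the prediction scope: the constant
#' of an intercept specification applies only to the 242 impaired states.
#'
#' @param spec a specification name or [model_spec()] object.
#' @param coefficients named numeric vector covering exactly the
#'   specification's predictors, plus `"(Intercept)"` when the
#'   specification has one.
#' @param se optional named numeric vector of standard errors for (a
#'   subset of) the same names.
#' @return An object of class `eq_tariff`.
#' @seealso [us_d1o_tariff()], [predict_value()], [reparameterize()]
#' @export
tariff <- function(spec, coefficients, se = NULL) {
  spec <- model_spec(spec)
  needed <- c(if (spec$intercept) "(Intercept)", spec$predictors)
  if (is.null(names(coefficients))) stop("`coefficients` must be named")
  missing <- setdiff(needed, names(coefficients))
  if (length(missing) > 0L) {
    stop("missing coefficient for predictor(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(coefficients), needed)
  if (length(extra) > 0L) {
    stop("coefficient(s) not in specification \"", spec$name, "\": ",
         paste(extra, collapse = ", "))
  }
  coefficients <- coefficients[needed]
  if (!is.null(se)) {
    if (is.null(names(se)) || !all(names(se) %in% needed)) {
      stop("`se` names must be a subset of the coefficient names")
    }
    se <- se[needed]
    names(se) <- needed
  }
  structure(list(spec = spec, coefficients = coefficients, se = se),
            class = "eq_tariff")
}

#' @export
print.eq_tariff <- function(x, digits = 3, ...) {
  cat("EQ-5D-3L tariff (specification ", x$spec$name, ")\n", sep = "")
  tab <- data.frame(coefficient = round(x$coefficients, digits))
  if (!is.null(x$se)) tab$se <- round(x$se, digits)
  print(tab)
  invisible(x)
}

#' The published US D1 tariff
#'
#' The coefficients (and standard errors) of the original US EQ-5D-3L
#' valuation model in its D1 specification, on the signed "add to 1"
#' scale. Stored at the published 3-decimal precision; these constants
#' are the package's reference tariff.
#'
#' @return An `eq_tariff` with specification `"D1O"`.
#' @examples
#' predict_value(us_d1o_tariff(), c("11111", "22222"))
#' @export
us_d1o_tariff <- function() {
  tariff(
    "D1O",
    coefficients = c(
      M2 = -0.146, S2 = -0.175, U2 = -0.140, P2 = -0.173, A2 = -0.156,
      M3 = -0.558, S3 = -0.471, U3 = -0.374, P3 = -0.537, A3 = -0.450,
      I3 = 0.122, I22 = -0.011, I32 = 0.015, D1 = 0.140
    ),
    se = c(
      M2 = 0.008, S2 = 0.008, U2 = 0.008, P2 = 0.008, A2 = 0.008,
      M3 = 0.016, S3 = 0.016, U3 = 0.013, P3 = 0.020, A3 = 0.015,
      I3 = 0.018, I22 = 0.002, I32 = 0.003, D1 = 0.010
    )
  )
}

#' Predict state utilities under a tariff
#'
#' Utility on the scale anchored at 1 (perfect health) and 0 (death):
#' `1 + sum(coefficient * predictor value)` over the state's features.
#' State 11111 always scores exactly 1 -- all its features are zero and
#' the constant, when the specification has one, is out of scope for it.
#'
#' @param tariff an `eq_tariff`.
#' @param states character vector of state codes.
#' @return Named numeric vector of utilities.
#' @examples
#' t <- us_d1o_tariff()
#' predict_value(t, c("22222", "33133"))  # 0.594, -0.095
#' @export
predict_value <- function(tariff, states) {
  stopifnot(inherits(tariff, "eq_tariff"))
  X <- build_design(tariff$spec, states)
  if ("(Intercept)" %in% colnames(X)) {
    X[rownames(X) == "11111", "(Intercept)"] <- 0
  }
  b <- tariff$coefficients[colnames(X)]
  if (anyNA(b)) {
    stop("missing coefficient for predictor(s): ",
         paste(colnames(X)[is.na(b)], collapse = ", "))
  }
  setNames(1 + as.vector(X %*% b), states)
}

#' Value table over the full state space
#'
#' @param tariff an `eq_tariff`.
#' @param include_perfect include state 11111 (utility exactly 1)?
#' @return Data frame with columns `state` and `utility`, one row per
#'   state in lexicographic order.
#' @export
predict_all <- function(tariff, include_perfect = TRUE) {
  states <- enumerate_states(include_perfect = include_perfect)
  data.frame(state = states,
             utility = unname(predict_value(tariff, states)),
             row.names = NULL)
}

#' Re-parameterize a D1 tariff into its constant-term equivalent
#'
#' Over the 242 impaired states the identity
#' `1 = (M2 + ... + A3) - D1` holds row by row, so the D1 term can be
#' traded exactly for a constant: the constant is the negative of the D1
#' coefficient, each of the ten dummy coefficients is shifted by the D1
#' coefficient, and I3, I22, I32 are unchanged. Predicted values are
#' identical for all 243 states.
#'
#' Standard errors are not carried over: transforming them requires the
#' coefficient covariance of the original fit (see [fit_ols()]).
#'
#' @param tariff an `eq_tariff` with specification `"D1O"`.
#' @return The equivalent `eq_tariff` with specification `"D1C"`.
#' @examples
#' reparameterize(us_d1o_tariff())  # constant -0.140, M2 -0.006, ...
#' @export
reparameterize <- function(tariff) {
  stopifnot(inherits(tariff, "eq_tariff"))
  if (tariff$spec$name != "D1O") {
    stop("reparameterize() expects a \"D1O\" tariff, got \"", tariff$spec$name, "\"")
  }
  co <- tariff$coefficients
  d1 <- co[["D1"]]
  tariff("D1C", c(
    "(Intercept)" = -d1,
    co[eq_dummy_names] + d1,
    co[c("I3", "I22", "I32")]
  ))
}

#' Invert the constant-term re-parameterization
#'
#' Exact inverse of [reparameterize()]: the D1 coefficient is the
#' negative of the constant and the dummies are shifted back.
#'
#' @param tariff an `eq_tariff` with specification `"D1C"`.
#' @return The equivalent `eq_tariff` with specification `"D1O"`.
#' @export
inverse_reparameterize <- function(tariff) {
  stopifnot(inherits(tariff, "eq_tariff"))
  if (tariff$spec$name != "D1C") {
    stop("inverse_reparameterize() expects a \"D1C\" tariff, got \"",
         tariff$spec$name, "\"")
  }
  co <- tariff$coefficients
  const <- co[["(Intercept)"]]
  tariff("D1O", c(
    co[eq_dummy_names] - (-const),
    co[c("I3", "I22", "I32")],
    D1 = -const
  ))
}

#' Read or write a tariff as JSON
#'
#' The JSON object carries the specification name, a coefficient map,
#' and an optional standard-error map; see
#' `system.file("extdata", "us_d1o_tariff.json", package = "eqtariff")`
#' for an example.
#'
#' @param path file path.
#' @return `read_tariff()` returns an `eq_tariff`; `write_tariff()`
#'   returns `path` invisibly.
#' @export
read_tariff <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$spec) || is.null(obj$coefficients)) {
    stop("tariff JSON must contain \"spec\" and \"coefficients\" fields: ", path)
  }
  tariff(obj$spec, unlist(obj$coefficients),
         se = if (!is.null(obj$se)) unlist(obj$se))
}

#' @param tariff an `eq_tariff`.
#' @rdname read_tariff
#' @export
write_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "eq_tariff"))
  obj <- list(spec = tariff$spec$name,
              coefficients = as.list(tariff$coefficients))
  if (!is.null(tariff$se)) obj$se <- as.list(tariff$se)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
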