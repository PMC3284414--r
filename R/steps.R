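#' Count tariff calculation steps for states
#'
#' Formalizes the informal accounting of how much arithmetic scoring a
#' state takes under a given specification. A "calculation step" is
#' either an invoked additive term (a term whose predictor value is
#' nonzero -- including the constant, when the specification has one, the
#' state is impaired, and the start point is perfect health) or a
#' nontrivial multiplication (a term whose predictor value is neither 0
#' nor 1). The perfect state 11111 takes zero steps.
#'
#' With `start_point = "any_impaired"`, scoring starts from the common
#' value of any impaired state (1 - constant, i.e. 0.860 under the
#' published tariff), so the constant is pre-absorbed and never counted;
#' this start point only exists for intercept specifications.
#'
#' Under this rule the published comparisons hold exactly: from perfect
#' health the constant-term form needs one step more for the 10
#' single-impairment states, the same number for the 40 two-impairment
#' states, and strictly fewer for all 192 states impaired in three or
#' more dimensions; from the any-impaired start it needs fewer steps for
#' all 232 states with two or more impairments.
#'
#' @param tariff an `eq_tariff`.
#' @param states character vector of state codes.
#' @param start_point `"perfect_health"` (default) or `"any_impaired"`.
#' @return Named integer vector of step counts.
#' @examples
#' t <- us_d1o_tariff()
#' count_steps(t, "11211")                     # 1
#' count_steps(reparameterize(t), "11211")     # 2
#' @export
count_steps <- function(tariff, states,
                        start_point = c("perfect_health", "any_impaired")) {
  stopifnot(inherits(tariff, "eq_tariff"))
  start_point <- match.arg(start_point)
  spec <- tariff$spec
  if (start_point == "any_impaired" && !spec$intercept) {
    stop("start_point \"any_impaired\" requires an intercept specification; \"",
         spec$name, "\" has none")
  }
  feats <- state_features(states)
  X <- as.matrix(feats[spec$predictors])
  invoked <- rowSums(X != 0)
  multiplications <- rowSums(X != 0 & X != 1)
  steps <- invoked + multiplications
  if (spec$intercept && start_point == "perfect_health") {
    steps <- steps + (feats$n_impaired > 0L)
  }
  setNames(as.integer(steps), states)
}
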