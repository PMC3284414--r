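#' Enumerate tied state pairs under a single-dimension level move
#'
#' Considers every pair of states that are identical except that one
#' named dimension moves between two levels, restricted to pairs where no
#' *other* dimension is at level 2 in either state, and reports which
#' pairs receive equal tariff values.
#'
#' Under the published US tariff the usual-activities 1 -> 2 move has a
#' zero net effect whenever the state is already impaired: the U2
#' coefficient (-0.140) is exactly cancelled by the D1 increment
#' (+0.140). Of the 16 candidate pairs (the other four dimensions free
#' over levels 1 and 3), the 15 with at least one other impairment are
#' tied; the remaining pair (11111, 11211) differs by 0.140, the
#' magnitude of the constant.
#'
#' @param tariff an `eq_tariff`.
#' @param dimension dimension that moves; one of `"mobility"`,
#'   `"self_care"`, `"usual_activities"`, `"pain_discomfort"`,
#'   `"anxiety_depression"`.
#' @param from_level,to_level the two levels of the move (each in 1:3).
#' @param tolerance values closer than this count as tied. Default
#'   `5e-4`: half a unit in the last printed decimal of the published
#'   coefficients, i.e. ties at printed precision.
#' @param tied_only return only the tied pairs (default), or all
#'   candidate pairs with their differences?
#' @return Data frame, in lexicographic order of `state_from`, with
#'   columns `state_from`, `state_to`, `value_from`, `value_to`,
#'   `difference` and logical `tied`.
#' @examples
#' nrow(find_tied_pairs(us_d1o_tariff()))  # 15
#' @export
find_tied_pairs <- function(tariff, dimension = "usual_activities",
                            from_level = 1, to_level = 2,
                            tolerance = 5e-4, tied_only = TRUE) {
  stopifnot(inherits(tariff, "eq_tariff"))
  j <- match(dimension, names(eq_dimensions))
  if (is.na(j)) {
    stop("unknown dimension \"", dimension, "\"; use one of ",
         paste(names(eq_dimensions), collapse = ", "))
  }
  if (!from_level %in% 1:3 || !to_level %in% 1:3 || from_level == to_level) {
    stop("`from_level` and `to_level` must be distinct levels in 1:3")
  }
  levels <- parse_state(enumerate_states())
  at_from <- levels[, j] == from_level
  others <- levels[, -j, drop = FALSE]
  no_other_level2 <- rowSums(others == 2L) == 0L
  base <- levels[at_from & no_other_level2, , drop = FALSE]
  partner <- base
  partner[, j] <- to_level
  from_codes <- format_state(base)
  to_codes <- format_state(partner)
  v_from <- predict_value(tariff, from_codes)
  v_to <- predict_value(tariff, to_codes)
  out <- data.frame(
    state_from = from_codes, state_to = to_codes,
    value_from = unname(v_from), value_to = unname(v_to),
    difference = unname(v_from - v_to),
    tied = unname(abs(v_from - v_to) < tolerance),
    row.names = NULL
  )
  out <- out[order(out$state_from), , drop = FALSE]
  rownames(out) <- NULL
  if (tied_only) out[out$tied, , drop = FALSE] else out
}
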