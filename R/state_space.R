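#' Parse EQ-5D-3L state codes
#'
#' An EQ-5D-3L health state is written as a five-digit code giving the
#' level (1 = no problems, 2 = some problems, 3 = extreme problems) of
#' each dimension in the fixed order mobility, self-care, usual
#' activities, pain/discomfort, anxiety/depression. "11111" is the best
#' state and "33333" the worst.
#'
#' @param code character vector of five-digit state codes.
#' @return An integer matrix with one row per code and five columns named
#'   after the dimensions; row names are the input codes.
#'   [format_state()] on the result reproduces the input.
#' @examples
#' parse_state("33133")
#' format_state(parse_state(c("11111", "21323")))
#' @seealso [format_state()], [enumerate_states()], [state_features()]
#' @export
parse_state <- function(code) {
  if (!is.character(code) || length(code) == 0L) {
    stop("`code` must be a non-empty character vector of five-digit state codes")
  }
  bad_len <- which(nchar(code) != 5L)
  if (length(bad_len) > 0L) {
    stop(sprintf(
      "invalid state code \"%s\": expected exactly 5 characters, got %d",
      code[bad_len[1L]], nchar(code[bad_len[1L]])
    ))
  }
  chars <- matrix(
    unlist(strsplit(code, "", fixed = TRUE), use.names = FALSE),
    ncol = 5L, byrow = TRUE
  )
  bad <- which(matrix(!(chars %in% c("1", "2", "3")), nrow = nrow(chars)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[order(bad[, 1L], bad[, 2L])[1L], , drop = TRUE]
    stop(sprintf(
      "invalid state code \"%s\": level \"%s\" at position %d (%s) is not 1, 2 or 3",
      code[i[1L]], chars[i[1L], i[2L]], i[2L], names(eq_dimensions)[i[2L]]
    ))
  }
  levels <- matrix(as.integer(chars), ncol = 5L,
                   dimnames = list(code, names(eq_dimensions)))
  levels
}

#' Format dimension levels as state codes
#'
#' @param levels an integer matrix with five columns (one row per state),
#'   or a single vector of five levels, each in 1:3, in the order
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression.
#' @return Character vector of five-digit codes.
#' @examples
#' format_state(c(3, 3, 1, 3, 3))
#' @export
format_state <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  if (ncol(levels) != 5L || !all(levels %in% 1:3)) {
    stop("`levels` must have five columns with every level in 1:3")
  }
  unname(apply(levels, 1L, paste0, collapse = ""))
}

#' Enumerate the EQ-5D-3L state space
#'
#' Three levels on five dimensions give 3^5 = 243 distinct states; 242 of
#' them have at least one dimension above level 1 ("impaired" states).
#' Tariff regressions are defined over the 242 impaired states because
#' state 11111 carries the axiomatic value 1.
#'
#' @param include_perfect include state "11111"? Default `TRUE`.
#' @return Character vector of state codes in lexicographic order
#'   (deterministic; "11111" first when present, "33333" last).
#' @examples
#' length(enumerate_states())                       # 243
#' length(enumerate_states(include_perfect = FALSE)) # 242
#' @export
enumerate_states <- function(include_perfect = TRUE) {
  g <- expand.grid(A = 1:3, P = 1:3, U = 1:3, S = 1:3, M = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  codes <- sort(sprintf("%d%d%d%d%d", g$M, g$S, g$U, g$P, g$A))
  if (!include_perfect) codes <- codes[codes != "11111"]
  codes
}

#' Derived regressors for EQ-5D-3L states
#'
#' Computes, for each state, every quantity used by the tariff model
#' specifications:
#' * the ten level dummies `M2,S2,U2,P2,A2,M3,S3,U3,P3,A3` (dimension at
#'   level 2 resp. 3);
#' * `n2`, `n3`, `n_impaired`: counts of dimensions at level 2, level 3,
#'   and above level 1;
#' * `I2 = max(n2 - 1, 0)` and `I3 = max(n3 - 1, 0)`: dimensions at that
#'   level beyond the first, with squares `I22`, `I32`;
#' * `D1 = max(n_impaired - 1, 0)`: impaired dimensions beyond the first,
#'   the variable the original US model uses in place of a constant;
#' * `N3`: indicator of any level-3 problem (UK-model-style term).
#'
#' All features are zero exactly for state 11111, and the identity
#' `D1 = I2 + I3 + (n2 > 0 && n3 > 0)` holds for every state.
#'
#' @param states character vector of five-digit state codes.
#' @return A data frame with one row per state and columns `state`, the
#'   ten dummies, `n2`, `n3`, `n_impaired`, `I2`, `I3`, `I22`, `I32`,
#'   `D1`, `N3`.
#' @examples
#' state_features(c("22222", "33133"))
#' @export
state_features <- function(states) {
  levels <- parse_state(states)
  n2 <- as.integer(rowSums(levels == 2L))
  n3 <- as.integer(rowSums(levels == 3L))
  d2 <- matrix(as.integer(levels == 2L), ncol = 5L)
  d3 <- matrix(as.integer(levels == 3L), ncol = 5L)
  colnames(d2) <- paste0(eq_dimensions, "2")
  colnames(d3) <- paste0(eq_dimensions, "3")
  I2 <- pmax(n2 - 1L, 0L)
  I3 <- pmax(n3 - 1L, 0L)
  out <- data.frame(
    state = unname(states), d2, d3,
    n2 = n2, n3 = n3, n_impaired = n2 + n3,
    I2 = I2, I3 = I3, I22 = I2^2, I32 = I3^2,
    D1 = pmax(n2 + n3 - 1L, 0L),
    N3 = as.integer(n3 > 0L),
    row.names = NULL, check.names = FALSE
  )
  out
}

#' Impairment group of a state
#'
#' The 243 states split by number of impaired dimensions into 1 perfect
#' state, 10 states impaired in a single dimension, 40 impaired in two,
#' and 192 impaired in three or more. Calculation-step comparisons
#' between the tariff specifications are made per group.
#'
#' @param states character vector of five-digit state codes.
#' @return Factor with levels `perfect`, `one`, `two`, `three_plus`.
#' @examples
#' table(impairment_group(enumerate_states()))
#' @export
impairment_group <- function(states) {
  n <- state_features(states)$n_impaired
  factor(c("perfect", "one", "two", "three_plus")[pmin(n, 3L) + 1L],
         levels = c("perfect", "one", "two", "three_plus"))
}
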