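# The three model specifications. D1O is the original US specification
# (no intercept, D1 in its place); D1C is its exact constant-term
# re-parameterization; D1C_N3 swaps the I3 count for the N3 indicator.
eq_specs <- list(
  D1O = list(
    name = "D1O",
    predictors = c(eq_dummy_names, "I3", "I22", "I32", "D1"),
    intercept = FALSE
  ),
  D1C = list(
    name = "D1C",
    predictors = c(eq_dummy_names, "I3", "I22", "I32"),
    intercept = TRUE
  ),
  D1C_N3 = list(
    name = "D1C_N3",
    predictors = c(eq_dummy_names, "N3", "I22", "I32"),
    intercept = TRUE
  )
)

#' Model specifications for the US EQ-5D-3L tariff
#'
#' Three named predictor sets over the state features:
#' * `"D1O"` -- the original US specification: the ten level dummies,
#'   `I3`, `I22`, `I32`, and `D1`; no intercept (14 predictors). `I2` was
#'   dropped from the published model as nonsignificant.
#' * `"D1C"` -- the mathematically equivalent constant-term form:
#'   intercept plus the ten dummies, `I3`, `I22`, `I32` (13 predictors).
#' * `"D1C_N3"` -- `D1C` with the `N3` any-level-3 indicator in place of
#'   the `I3` count.
#'
#' @param name one of `"D1O"`, `"D1C"`, `"D1C_N3"` (or an existing
#'   `eq_model_spec`, returned unchanged).
#' @return An object of class `eq_model_spec`: a list with elements
#'   `name`, `predictors` (ordered character vector), `intercept` (flag).
#' @examples
#' model_spec("D1C")
#' @export
model_spec <- function(name) {
  if (inherits(name, "eq_model_spec")) {
    return(name)
  }
  if (!is.character(name) || length(name) != 1L || !name %in% names(eq_specs)) {
    stop("unknown model specification; use one of ",
         paste0('"', names(eq_specs), '"', collapse = ", "))
  }
  structure(eq_specs[[name]], class = "eq_model_spec")
}

#' @export
print.eq_model_spec <- function(x, ...) {
  cat("EQ-5D-3L model specification:", x$name, "\n")
  cat(if (x$intercept) "intercept + " else "no intercept; ",
      length(x$predictors), " predictors:\n  ", sep = "")
  cat(paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Build the design matrix of a specification over a state set
#'
#' Evaluates the specification's predictors from [state_features()] for
#' each state. When the specification has an intercept, an all-ones
#' `"(Intercept)"` column comes first (stable coefficient indexing).
#' Every entry is a non-negative integer at most 16 (`I22`/`I32` at
#' `I2`/`I3` = 4).
#'
#' @param spec a specification name or [model_spec()] object.
#' @param states non-empty character vector of state codes.
#' @return Numeric matrix with state codes as row names and predictor
#'   names as column names; attribute `spec_name` records the
#'   specification.
#' @examples
#' X <- build_design("D1C", enumerate_states(include_perfect = FALSE))
#' dim(X)  # 242 x 14
#' @export
build_design <- function(spec, states) {
  spec <- model_spec(spec)
  if (length(states) == 0L) stop("`states` must be a non-empty vector of state codes")
  feats <- state_features(states)
  X <- as.matrix(feats[spec$predictors])
  storage.mode(X) <- "double"
  if (spec$intercept) {
    X <- cbind("(Intercept)" = 1, X)
  }
  rownames(X) <- states
  attr(X, "spec_name") <- spec$name
  X
}

#' Write a design matrix as CSV
#'
#' Writes the matrix with a leading `state` column of codes and a header
#' row of predictor names.
#'
#' @param design matrix from [build_design()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  df <- data.frame(state = rownames(design), design,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
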