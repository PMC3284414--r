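# R-squared values above this are treated as exact collinearity and the
# VIF is reported as infinite.
eq_singular_r2 <- 1 - 1e-12

resolve_vif_method <- function(design, method = c("auto", "centered", "uncentered")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if ("(Intercept)" %in% colnames(design)) "centered" else "uncentered"
  }
  method
}

#' Auxiliary-regression R-squared of one predictor on the rest
#'
#' First step of the two-step VIF calculation: regress the predictor in
#' question on all other predictors and take the coefficient of
#' determination; the VIF is `1/(1 - R^2)`.
#'
#' Two conventions are available, matching how statistical software
#' defines R-squared for models with and without an intercept:
#' * `"centered"` -- the auxiliary regression includes an intercept and
#'   R-squared is centered (the usual convention for intercept models);
#' * `"uncentered"` -- the auxiliary regression uses exactly the other
#'   design columns (no added intercept) and R-squared is computed about
#'   zero (the convention for no-intercept models; this is the one under
#'   which the published D1O VIFs arise -- with an added intercept the
#'   D1O design is exactly collinear, because
#'   `1 = (M2 + ... + A3) - D1` on every impaired state).
#'
#' `"auto"` picks `"centered"` when the design has an intercept column
#' and `"uncentered"` otherwise.
#'
#' @param design matrix from [build_design()].
#' @param predictor name of a non-intercept column.
#' @param method `"auto"` (default), `"centered"`, or `"uncentered"`.
#' @return R-squared in `[0, 1]`. A perfectly collinear predictor
#'   returns 1 (its VIF is then reported as infinite, not an error).
#' @export
aux_r2 <- function(design, predictor, method = c("auto", "centered", "uncentered")) {
  method <- resolve_vif_method(design, method)
  if (identical(predictor, "(Intercept)")) {
    stop("the intercept has no VIF; pick a non-intercept predictor")
  }
  if (!predictor %in% colnames(design)) {
    stop("predictor \"", predictor, "\" is not a column of the design")
  }
  if (ncol(design) < 2L) stop("design must have at least two columns")
  y <- design[, predictor]
  others <- design[, setdiff(colnames(design), predictor), drop = FALSE]
  if (method == "centered") {
    others <- others[, setdiff(colnames(others), "(Intercept)"), drop = FALSE]
    Z <- cbind(1, others)
    tss <- sum((y - mean(y))^2)
  } else {
    Z <- others
    tss <- sum(y^2)
  }
  if (tss == 0) {
    return(1)
  }
  fit <- stats::lm.fit(Z, y)
  r2 <- 1 - sum(fit$residuals^2) / tss
  min(max(r2, 0), 1)
}

#' Variance inflation factors of a specification
#'
#' Computes, for every non-intercept predictor of the specification, the
#' auxiliary-regression R-squared and the VIF `1/(1 - R^2)` over a state
#' set (by default the 242 impaired states, each with equal weight --
#' the design space of the tariff, not any valuation study's sampled
#' subset). Predictors with auxiliary R-squared above `1 - 1e-12` are
#' reported as infinite.
#'
#' Under the default (`"auto"`) convention the published VIF table is
#' reproduced exactly at its printed precision: for `"D1O"` the level-2
#' dummies share 5.336, the level-3 dummies 5.038, I3 38.529, I22 5.384,
#' I32 9.773, and D1 113.184; for `"D1C"` the level-2 dummies share
#' 1.913, the level-3 dummies 3.591, I3 21.211, I22 3.893, I32 7.066;
#' for `"D1C_N3"`, N3 has 3.010.
#'
#' @param spec a specification name or [model_spec()] object.
#' @param method see [aux_r2()].
#' @param states state set defining the design space; default the 242
#'   impaired states.
#' @return A data frame of class `eq_vif_report` with columns
#'   `predictor`, `r_squared`, `vif`; attributes `spec_name`,
#'   `n_states`, `method` (resolved).
#' @examples
#' vif_all("D1C")
#' @export
vif_all <- function(spec, method = c("auto", "centered", "uncentered"),
                    states = enumerate_states(include_perfect = FALSE)) {
  spec <- model_spec(spec)
  X <- build_design(spec, states)
  method <- resolve_vif_method(X, method)
  r2 <- vapply(spec$predictors, function(p) aux_r2(X, p, method), numeric(1))
  vif <- ifelse(r2 > eq_singular_r2, Inf, 1 / (1 - r2))
  structure(
    data.frame(predictor = spec$predictors, r_squared = unname(r2),
               vif = unname(vif), row.names = NULL),
    class = c("eq_vif_report", "data.frame"),
    spec_name = spec$name, n_states = length(states), method = method
  )
}

#' @export
print.eq_vif_report <- function(x, digits = 3, ...) {
  cat("VIF report: specification ", attr(x, "spec_name"),
      " over ", attr(x, "n_states"), " states (",
      attr(x, "method"), " R-squared)\n", sep = "")
  print(data.frame(predictor = x$predictor,
                   r_squared = round(x$r_squared, digits + 2L),
                   vif = round(x$vif, digits)))
  invisible(x)
}

#' Inverse-correlation-matrix VIFs (independent cross-check)
#'
#' Computes VIFs by the matrix route rather than by auxiliary
#' regressions: for the centered convention, the diagonal of the inverse
#' of the predictor correlation matrix; for the uncentered convention,
#' the diagonal of the inverse of the cosine-normalized cross-product
#' matrix `D^-1 X'X D^-1` (with `D = sqrt(diag(X'X))`), restricted to
#' the non-intercept columns. Both routes compute the same quantity as
#' [aux_r2()]-based VIFs; the package uses the agreement as an internal
#' consistency check.
#'
#' @param design matrix from [build_design()].
#' @param method see [aux_r2()].
#' @return Named numeric vector of VIFs for the non-intercept columns.
#'   A singular (exactly collinear) matrix gives `Inf` for every entry.
#' @export
vif_oracle <- function(design, method = c("auto", "centered", "uncentered")) {
  method <- resolve_vif_method(design, method)
  cols <- setdiff(colnames(design), "(Intercept)")
  if (method == "centered") {
    R <- cor(design[, cols, drop = FALSE])
    inv <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(inv)) return(setNames(rep(Inf, length(cols)), cols))
    setNames(diag(inv), cols)
  } else {
    X <- design
    XtX <- crossprod(X)
    d <- sqrt(diag(XtX))
    S <- XtX / tcrossprod(d)
    inv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(inv)) return(setNames(rep(Inf, length(cols)), cols))
    diag(inv)[cols]
  }
}

#' Compare two VIF reports predictor by predictor
#'
#' @param a,b `eq_vif_report` objects sharing at least one predictor.
#' @return Data frame with columns `predictor`, `vif_a`, `vif_b`,
#'   `ratio` (`vif_a / vif_b`), over the shared predictors in the order
#'   of `a`.
#' @examples
#' compare_vif(vif_all("D1O"), vif_all("D1C"))
#' @export
compare_vif <- function(a, b) {
  stopifnot(inherits(a, "eq_vif_report"), inherits(b, "eq_vif_report"))
  shared <- intersect(a$predictor, b$predictor)
  if (length(shared) == 0L) stop("the two reports share no predictor")
  va <- setNames(a$vif, a$predictor)[shared]
  vb <- setNames(b$vif, b$predictor)[shared]
  data.frame(predictor = shared, vif_a = unname(va), vif_b = unname(vb),
             ratio = unname(va / vb), row.names = NULL)
}

#' Write a VIF report as CSV
#'
#' @param report an `eq_vif_report` (or the data frame from
#'   [compare_vif()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vif_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
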