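round_if <- function(x, digits) {
  if (is.null(digits)) x else round(x, digits)
}

#' Regenerate the coefficient/VIF table and the worked examples
#'
#' Writes two CSV files to `outdir`:
#' * `table1.csv` -- one row per model parameter: the published D1O
#'   coefficient and SE, the computed D1O VIF, the re-parameterization
#'   formula, the computed D1C coefficient, and the computed D1C VIF.
#' * `table2.csv` -- per-term calculation examples for states 11111,
#'   22222, 33133 and 33233: for each state the predictor multiplier and
#'   the D1O and D1C contributions, with a final `sum` row holding the
#'   predicted utilities (identical between the two specifications).
#'
#' Output is deterministic: rerunning with the same arguments produces
#' byte-identical files.
#'
#' @param outdir writable output directory (created if missing).
#' @param digits round numeric output to this many decimals (`3`
#'   reproduces the published formatting); `NULL` writes full floating
#'   point precision.
#' @param tariff the D1O tariff to tabulate; default [us_d1o_tariff()].
#' @return Named character vector of the two file paths, invisibly.
#' @examples
#' paths <- reproduce_tables(tempdir())
#' read.csv(paths[["table2"]])
#' @export
reproduce_tables <- function(outdir, digits = 3, tariff = us_d1o_tariff()) {
  stopifnot(inherits(tariff, "eq_tariff"), tariff$spec$name == "D1O")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tc <- reparameterize(tariff)
  vif_o <- setNames(vif_all("D1O")$vif, vif_all("D1O")$predictor)
  vif_c <- setNames(vif_all("D1C")$vif, vif_all("D1C")$predictor)

  params <- c("Constant", "D1", eq_dummy_names, "I3", "I22", "I32")
  co <- tariff$coefficients
  cc <- tc$coefficients
  se <- if (is.null(tariff$se)) setNames(rep(NA_real_, length(co)), names(co)) else tariff$se
  recalc <- c("-D1", "D1-D1", paste0(eq_dummy_names, "+D1"), "I3", "I22", "I32")
  table1 <- data.frame(
    parameter = params,
    d1o_coeff = round_if(unname(co[c(NA, "D1", eq_dummy_names, "I3", "I22", "I32")]), digits),
    d1o_se = round_if(unname(se[c(NA, "D1", eq_dummy_names, "I3", "I22", "I32")]), digits),
    d1o_vif = round_if(unname(vif_o[c(NA, "D1", eq_dummy_names, "I3", "I22", "I32")]), digits),
    recalculation = recalc,
    d1c_coeff = round_if(unname(cc[c("(Intercept)", NA, eq_dummy_names, "I3", "I22", "I32")]), digits),
    d1c_vif = round_if(unname(c(NA, NA, vif_c[c(eq_dummy_names, "I3", "I22", "I32")])), digits),
    row.names = NULL
  )
  p1 <- file.path(outdir, "table1.csv")
  write.csv(table1, p1, row.names = FALSE, quote = FALSE, na = "")

  example_states <- c("11111", "22222", "33133", "33233")
  terms <- c("perfect_health", "constant", eq_dummy_names, "I3", "I22", "I32", "D1", "sum")
  table2 <- data.frame(term = terms)
  for (s in example_states) {
    f <- state_features(s)
    impaired <- f$n_impaired > 0L
    mult <- c(1, as.integer(impaired),
              unlist(f[c(eq_dummy_names, "I3", "I22", "I32", "D1")]), NA)
    d1o_contrib <- c(1, NA, unname(co[c(eq_dummy_names, "I3", "I22", "I32", "D1")]) *
                       mult[3:16], unname(predict_value(tariff, s)))
    d1c_contrib <- c(1, cc[["(Intercept)"]] * mult[2],
                     unname(cc[c(eq_dummy_names, "I3", "I22", "I32")]) * mult[3:15],
                     NA, unname(predict_value(tc, s)))
    table2[[paste0("mult_", s)]] <- mult
    table2[[paste0("d1o_", s)]] <- round_if(d1o_contrib, digits)
    table2[[paste0("d1c_", s)]] <- round_if(d1c_contrib, digits)
  }
  p2 <- file.path(outdir, "table2.csv")
  write.csv(table2, p2, row.names = FALSE, quote = FALSE, na = "")

  invisible(c(table1 = p1, table2 = p2))
}

#' Write the full value table of a tariff as CSV
#'
#' @param tariff an `eq_tariff`.
#' @param path output file path.
#' @param digits optional rounding (default full precision).
#' @param include_perfect include state 11111?
#' @return `path`, invisibly.
#' @export
write_value_table <- function(tariff, path, digits = NULL,
                              include_perfect = TRUE) {
  values <- predict_all(tariff, include_perfect = include_perfect)
  values$utility <- round_if(values$utility, digits)
  write.csv(values, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file may set any of `n_respondents`, `noise_sd`, `seed`, `clip`,
#' `states` (vector of codes), and `tariff` (path to a tariff JSON,
#' relative to the config file's directory); unset fields take the
#' [sim_config()] defaults. YAML files require the `yaml` package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the `yaml` package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  if (!is.null(obj$tariff)) {
    tariff_path <- obj$tariff
    if (!file.exists(tariff_path)) {
      tariff_path <- file.path(dirname(path), obj$tariff)
    }
    args$tariff <- read_tariff(tariff_path)
  }
  for (field in c("states", "n_respondents", "noise_sd", "seed", "clip")) {
    if (!is.null(obj[[field]])) args[[field]] <- obj[[field]]
  }
  do.call(sim_config, args)
}
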