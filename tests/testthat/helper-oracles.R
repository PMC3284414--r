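# Independent oracles used across the tests: everything here works from
# the raw digit strings, without going through the package's feature or
# design machinery.

# Count digits equal to `level` in a code string.
count_level <- function(code, level) {
  vapply(strsplit(code, ""), function(d) sum(d == as.character(level)), integer(1))
}

# Brute-force utility of a state under the published coefficients,
# summed by hand from the digit string.
oracle_utility <- function(code) {
  co <- c(M2 = -0.146, S2 = -0.175, U2 = -0.140, P2 = -0.173, A2 = -0.156,
          M3 = -0.558, S3 = -0.471, U3 = -0.374, P3 = -0.537, A3 = -0.450)
  digits <- strsplit(code, "")[[1]]
  letters5 <- c("M", "S", "U", "P", "A")
  total <- 0
  for (k in 1:5) {
    if (digits[k] != "1") total <- total + co[[paste0(letters5[k], digits[k])]]
  }
  n2 <- sum(digits == "2"); n3 <- sum(digits == "3")
  i3 <- max(n3 - 1, 0); i2 <- max(n2 - 1, 0)
  total <- total + 0.122 * i3 - 0.011 * i2^2 + 0.015 * i3^2 +
    0.140 * max(n2 + n3 - 1, 0)
  1 + total
}

# A random valid D1O tariff (coefficients uniform in [-1, 1]).
random_d1o_tariff <- function() {
  spec <- model_spec("D1O")
  tariff("D1O", setNames(round(runif(length(spec$predictors), -1, 1), 3),
                         spec$predictors))
}

published_d1o <- us_d1o_tariff()

# Table 1, D1c coefficient column exactly as printed ("-.000" read as 0).
printed_d1c_column <- c(
  "(Intercept)" = -0.140,
  M2 = -0.006, S2 = -0.035, U2 = 0.000, P2 = -0.032, A2 = -0.016,
  M3 = -0.418, S3 = -0.331, U3 = -0.234, P3 = -0.397, A3 = -0.310,
  I3 = 0.122, I22 = -0.011, I32 = 0.015
)

# Table 1 VIF columns exactly as printed.
printed_vif_d1o <- c(
  M2 = 5.336, S2 = 5.336, U2 = 5.336, P2 = 5.336, A2 = 5.336,
  M3 = 5.038, S3 = 5.038, U3 = 5.038, P3 = 5.038, A3 = 5.038,
  I3 = 38.529, I22 = 5.384, I32 = 9.773, D1 = 113.184
)
printed_vif_d1c <- c(
  M2 = 1.913, S2 = 1.913, U2 = 1.913, P2 = 1.913, A2 = 1.913,
  M3 = 3.591, S3 = 3.591, U3 = 3.591, P3 = 3.591, A3 = 3.591,
  I3 = 21.211, I22 = 3.893, I32 = 7.066
)

vif_named <- function(report) setNames(report$vif, report$predictor)
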