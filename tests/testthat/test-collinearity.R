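impaired <- enumerate_states(include_perfect = FALSE)

test_that("auxiliary R-squared behaves on degenerate designs", {
  # orthogonal two-column design -> R2 = 0, VIF 1
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(aux_r2(X, "a"), 0)
  expect_equal(aux_r2(X, "a", method = "uncentered"), 0)

  # duplicated column -> R2 = 1, infinite VIF rather than an error
  Xd <- build_design("D1C", impaired)
  Xd <- cbind(Xd, M2_copy = Xd[, "M2"])
  expect_equal(aux_r2(Xd, "M2"), 1)

  expect_error(aux_r2(Xd, "(Intercept)"), "no VIF")
  expect_error(aux_r2(Xd, "nope"), "not a column")
})

test_that("two correlated predictors give the closed-form VIF", {
  # closed form: VIF = 1/(1-r^2) for both columns of a bivariate design
  set.seed(7)
  for (r in c(0.3, 0.8)) {
    z1 <- rnorm(500)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(500)
    X <- cbind("(Intercept)" = 1, x1 = z1, x2 = z2)
    r_obs <- cor(z1, z2)
    v <- vif_oracle(X)
    expect_equal(unname(v), rep(1 / (1 - r_obs^2), 2), tolerance = 1e-10)
    expect_equal(1 / (1 - aux_r2(X, "x1")), v[["x1"]], tolerance = 1e-10)
  }
  # identity correlation -> all VIFs 1
  expect_equal(unname(vif_oracle(cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1)),
                                 method = "centered")),
               c(1, 1))
})

test_that("auxiliary-regression and inverse-matrix VIFs agree on every spec", {
  for (s in c("D1O", "D1C", "D1C_N3")) {
    report <- vif_all(s)
    oracle <- vif_oracle(build_design(s, impaired))
    expect_equal(vif_named(report), oracle[report$predictor], tolerance = 1e-8)
  }
})

test_that("VIFs reproduce the published table at printed precision", {
  vo <- vif_named(vif_all("D1O"))
  vc <- vif_named(vif_all("D1C"))
  expect_equal(vo, printed_vif_d1o, tolerance = 1e-3)
  expect_equal(vc, printed_vif_d1c, tolerance = 1e-3)
  expect_equal(vif_named(vif_all("D1C_N3"))[["N3"]], 3.010, tolerance = 1e-3)
  # fundamentals: VIF = 1/(1-R2) exactly, and VIF >= 1
  for (rep in list(vif_all("D1O"), vif_all("D1C"))) {
    expect_equal(rep$vif, 1 / (1 - rep$r_squared))
    expect_true(all(rep$vif >= 1))
    expect_false("(Intercept)" %in% rep$predictor)
  }
})

test_that("dimension symmetry makes the dummies share VIFs", {
  for (s in c("D1O", "D1C")) {
    v <- vif_named(vif_all(s))
    level2 <- v[paste0(c("M", "S", "U", "P", "A"), "2")]
    level3 <- v[paste0(c("M", "S", "U", "P", "A"), "3")]
    expect_lt(max(level2) - min(level2), 1e-10)
    expect_lt(max(level3) - min(level3), 1e-10)
  }
})

test_that("with an added intercept the D1O design is exactly collinear", {
  # 1 = sum(dummies) - D1 over the impaired states, so under the centered
  # convention every column involved in that identity is perfectly
  # predictable from the rest
  report <- vif_all("D1O", method = "centered")
  v <- vif_named(report)
  involved <- c(paste0(c("M", "S", "U", "P", "A"), "2"),
                paste0(c("M", "S", "U", "P", "A"), "3"), "D1")
  expect_true(all(is.infinite(v[involved])))
  expect_true(all(is.finite(v[c("I3", "I22", "I32")])))
})

test_that("specification comparisons match the published contrasts", {
  cmp <- compare_vif(vif_all("D1O"), vif_all("D1C"))
  expect_equal(nrow(cmp), 13)
  expect_true(all(cmp$vif_a > cmp$vif_b))  # D1O worse for every shared predictor

  self <- compare_vif(vif_all("D1C"), vif_all("D1C"))
  expect_equal(self$ratio, rep(1, 13))

  # N3-for-I3 swap: level-2 dummies and the squared terms keep their
  # VIFs; the level-3 dummies do not (they drop from 3.591 to 3.245)
  cmp_n3 <- compare_vif(vif_all("D1C"), vif_all("D1C_N3"))
  unchanged <- c(paste0(c("M", "S", "U", "P", "A"), "2"), "I22", "I32")
  expect_equal(cmp_n3$ratio[match(unchanged, cmp_n3$predictor)],
               rep(1, 7), tolerance = 1e-10)
  level3 <- paste0(c("M", "S", "U", "P", "A"), "3")
  expect_true(all(cmp_n3$ratio[match(level3, cmp_n3$predictor)] > 1))
})

test_that("VIF reports export as CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_vif_csv(vif_all("D1C"), path)
  back <- read.csv(path)
  expect_equal(back$vif, vif_all("D1C")$vif, tolerance = 1e-12)
})
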