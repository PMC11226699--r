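test_that("fit_calibration recovers exact coefficients on noiseless points", {
  conc <- c(7.81, 15.63, 31.25, 62.5, 125)
  resp <- 566488 * conc + 2302.2
  cur <- fit_calibration(conc, resp)
  expect_equal(cur$slope, 566488)
  expect_equal(cur$intercept, 2302.2)
  expect_equal(cur$r_squared, 1.0)
  expect_error(fit_calibration(rep(10, 3), c(1, 2, 3)), "variance")
})

test_that("LOD/LOQ follow the 3x / 10x signal-to-noise rule", {
  conc <- c(10, 50, 100); resp <- 2 * conc + 1
  cur <- fit_calibration(conc, resp, noise_sd = 0.6)
  expect_equal(cur$loq / cur$lod, 10 / 3)
  expect_equal(cur$lod, 3 * 0.6 / 2)
})

test_that("noisy calibration keeps the slope near truth with R^2 < 1", {
  set.seed(12)
  conc <- rep(c(7.81, 15.63, 31.25, 62.5, 125), each = 3)
  resp <- 566488 * conc + 2302.2 + rnorm(length(conc), sd = 5e4)
  cur <- fit_calibration(conc, resp)
  expect_lt(cur$r_squared, 1)
  expect_equal(cur$slope, 566488, tolerance = 0.02)
})

test_that("invert_calibration: boundary, forced arithmetic, round-trip", {
  conc <- c(7.81, 15.63, 31.25, 62.5, 125)
  cur <- fit_calibration(conc, 566488 * conc + 2302.2, noise_sd = 1000)
  expect_equal(invert_calibration(cur, cur$intercept)$ng_ml, 0)
  y50 <- 566488 * 50 + 2302.2
  inv <- invert_calibration(cur, y50, concentration_factor = 1)
  expect_equal(inv$ng_ml, 50)
  expect_equal(inv$mg_l, 0.05)
  # round-trip on synthetic data within 1%
  set.seed(3)
  resp <- 566488 * conc + 2302.2 + rnorm(5, sd = 2e4)
  cur2 <- fit_calibration(conc, resp)
  back <- invert_calibration(cur2, 566488 * 40 + 2302.2)$ng_ml
  expect_equal(back, 40, tolerance = 0.01)
  # below-LOD responses are reported as "<LOD", not a number
  low <- invert_calibration(cur, cur$intercept + 566488 * 0.001)
  expect_true(low$below_lod)
  expect_identical(low$display, "<LOD")
})

test_that("molar_ratio normalizes detected components only", {
  expect_equal(molar_ratio(c(Q8 = 3.7, DMK8 = NA, MK8 = NA)),
               c(Q8 = 100, DMK8 = NA, MK8 = NA))
  expect_equal(unname(molar_ratio(c(a = 1, b = 1, c = 1))),
               rep(100 / 3, 3))
  expect_equal(unname(molar_ratio(c(a = 2, b = 1, c = 1))), c(50, 25, 25))
  expect_error(molar_ratio(c(a = 0, b = 0)), "undefined")
})

test_that("profile_correlation reproduces every printed coefficient", {
  fix <- quinone_fixture()
  pd <- fix$profiles[["PD-1"]]
  expect_equal(profile_correlation(pd, pd, fix$pairing), 1.0)
  for (k in seq_len(nrow(fix$reference_r))) {
    s <- fix$reference_r$strain[k]
    r <- profile_correlation(pd, fix$profiles[[s]], fix$pairing)
    if (is.na(fix$reference_r$r[k])) {
      expect_true(is.na(r))                       # printed ND
    } else {
      expect_equal(round(r, 3), fix$reference_r$r[k])
    }
  }
  # undefined on zero variance
  flat <- chem_profile("flat", stats::setNames(rep(50, 6), fix$pairing))
  expect_true(is.na(profile_correlation(flat, pd, fix$pairing)))
  expect_error(profile_correlation(pd, pd, fix$pairing[1:2]), "at least 3")
})

test_that("profile_correlation is symmetric and affine-invariant", {
  fix <- quinone_fixture()
  pd <- fix$profiles[["PD-1"]]
  mt <- fix$profiles[["M.tenebrionis KCTC 72449"]]
  r1 <- profile_correlation(pd, mt, fix$pairing)
  expect_equal(profile_correlation(mt, pd, fix$pairing), r1)
  scaled <- chem_profile("sc", 3 * mt$values + 7)
  expect_equal(profile_correlation(pd, scaled, fix$pairing), r1)
  expect_true(abs(r1) <= 1)
})

test_that("fame_similarity fills missing components with zero", {
  a <- chem_profile("a", c(`C16:0` = 30, `C18:1` = 50, `C14:0` = 20))
  expect_equal(fame_similarity(a, a), 1.0)
  b <- chem_profile("b", c(`C16:0` = 30, `C18:1` = 50, `C12:0` = 20))
  # oracle: plain cor over the 4-component union with zeros filled in
  x <- c(30, 50, 20, 0); y <- c(30, 50, 0, 20)
  expect_equal(fame_similarity(a, b), stats::cor(x, y))
  expect_error(fame_similarity(chem_profile("x", c(a = 1, b = 2)),
                               chem_profile("y", c(a = 1, b = 2))),
               "3 components")
})

test_that("api_similarity excludes V/ND and matches hand counts", {
  a <- rep("+", 10)
  expect_equal(api_similarity(a, a), 1.0)
  b <- c(rep("+", 10), rep("-", 10))
  c_ <- c(rep("+", 5), rep("-", 10), rep("+", 5))
  expect_equal(api_similarity(b, c_), 0.5)
  withV <- c("+", "V", "ND", "-")
  expect_equal(api_similarity(withV, c("+", "-", "+", "-")), 1.0)
  expect_error(api_similarity(c("V", "ND"), c("+", "-")), "no comparable")

  # packaged phenotype table: frozen hand counts (matches/compared)
  api <- api_fixture()
  expect_equal(api_similarity(api[["PD-1.48h"]], api[["P.beijingensis"]]),
               9 / 19)
  expect_equal(api_similarity(api[["PD-1.24h"]], api[["P.beijingensis"]]),
               13 / 19)
  expect_gt(api_similarity(api[["PD-1.24h"]], api[["P.beijingensis"]]), 0.6)
})

test_that("quinone fixture rows sum to 100 within 0.5", {
  fix <- quinone_fixture()
  for (p in fix$profiles) {
    conds <- unique(sub("\\..*$", "", names(p$values)))
    for (cn in conds) {
      v <- p$values[startsWith(names(p$values), paste0(cn, "."))]
      if (all(is.na(v))) next
      expect_equal(sum(v, na.rm = TRUE), 100, tolerance = 0.5 / 100)
    }
  }
})
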