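test_that("conc_profile enforces its invariants", {
  expect_error(conc_profile("s", "x", 0, 1, 1), "dose")
  expect_error(conc_profile("s", "x", 1, c(1, 1), c(1, 2)), "strictly increasing")
  expect_error(conc_profile("s", "x", 1, c(2, 1), c(1, 2)), "strictly increasing")
  expect_error(conc_profile("s", "x", 1, c(1, 2), c(1, -2)), ">= 0")
  expect_error(conc_profile("s", "x", 1, c(1, 2), 1), "equal length")
  p <- conc_profile("s", "x", 1, c(0, 1, 2), c(0, 8, 0.5), lloq = 1)
  expect_identical(p$blq, c(FALSE, FALSE, TRUE))  # pre-dose zero never BLQ
})

test_that("temp_profile requires exactly one of temp/delta_t", {
  expect_error(temp_profile("s", "MTG", 1), "exactly one")
  expect_error(temp_profile("s", "MTG", 1, temp = 38, delta_t = 0.1), "exactly one")
  expect_error(temp_profile("s", "MTG", 1, temp = 38), "baseline")
  expect_error(temp_profile("s", "BAD", 1, delta_t = 0.1))
  expect_silent(temp_profile("s", "MCG", c(1, 2), delta_t = c(0.1, 0.2)))
})

test_that("delta_t implements the baseline- and control-corrected change", {
  trt <- temp_profile("m", "MTG", 1, temp = 38.5, baseline = 38.0)
  ctl <- temp_profile("m", "MCG", 1, temp = 39.2, baseline = 38.1)
  expect_equal(delta_t(trt, ctl)$delta_t, -0.6)
  # treated identical to control -> identically zero
  t2 <- temp_profile("m", "MTG", c(0.5, 1, 2), temp = c(38.2, 38.9, 39.0), baseline = 38.0)
  c2 <- temp_profile("m", "MCG", c(0.5, 1, 2), temp = c(38.2, 38.9, 39.0), baseline = 38.0)
  expect_equal(delta_t(t2, c2)$delta_t, c(0, 0, 0))
  # antisymmetry up to sign
  c3 <- temp_profile("m", "MCG", c(0.5, 1, 2), temp = c(38.5, 39.3, 39.1), baseline = 38.2)
  expect_equal(delta_t(t2, c3)$delta_t, -delta_t(c3, t2)$delta_t)
  # mismatched grids are an error, never interpolated
  c4 <- temp_profile("m", "MCG", c(0.5, 1.5, 2), temp = c(38.5, 39.3, 39.1), baseline = 38.2)
  expect_error(delta_t(t2, c4), "time grid")
})

test_that("per-group temperatures constructed to invert the fixture reproduce its deltaT", {
  fx <- qkl_fixture()
  dT <- fx$delta_t$delta_t
  times <- fx$delta_t$times
  # hand-inverted: arbitrary control course r(t); treated = baseline + r(t) + dT
  r <- 0.3 * times                       # any control drift
  ctl <- temp_profile("m", "MCG", times, temp = 38.1 + r, baseline = 38.1)
  trt <- temp_profile("m", "MTG", times, temp = 38.0 + r + dT, baseline = 38.0)
  expect_equal(delta_t(trt, ctl)$delta_t, dT)
})

test_that("the embedded fixture matches the printed study table cell-for-cell", {
  fx <- qkl_fixture()
  expect_length(fx$delta_t$times, 13)
  expect_identical(fx$conc_baicalin$times, fx$conc_geniposide$times)
  expect_equal(max(fx$delta_t$delta_t), 1.082)
  expect_equal(fx$delta_t$times[which.max(fx$delta_t$delta_t)], 1.0)
  expect_equal(max(fx$conc_baicalin$conc), 56117.21)
  expect_equal(fx$conc_baicalin$conc[fx$conc_baicalin$times == 0.033], 23053)
  expect_equal(fx$conc_geniposide$conc[13], 36.64)
  expect_equal(unname(fx$doses), c(23.04, 2.38))
  expect_equal(fx$references$max_increment, 1.38)
})

test_that("write/read round trip reproduces profiles exactly", {
  fx <- qkl_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_conc_table(list(fx$conc_baicalin, fx$conc_geniposide), tmp)
  back <- read_conc_table(tmp, dose = fx$doses)
  expect_length(back, 2)
  b <- back[["mean-MTG:baicalin"]]
  expect_identical(b$times, fx$conc_baicalin$times)
  expect_identical(b$conc, fx$conc_baicalin$conc)
  expect_equal(b$dose, 23.04)
})

test_that("reader sorts by time, groups profiles and rejects bad cells", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,analyte,time,conc",
               "r1,x,2,5", "r1,x,1,10", "r1,x,0.5,20",
               "r2,x,1,7"), tmp)
  out <- read_conc_table(tmp, dose = 1)
  expect_length(out, 2)
  expect_equal(out[["r1:x"]]$times, c(0.5, 1, 2))
  expect_equal(out[["r1:x"]]$conc, c(20, 10, 5))

  writeLines(c("subject,analyte,time,conc", "r1,x,1,5", "r1,x,1,6"), tmp)
  expect_error(read_conc_table(tmp, dose = 1), "duplicate")
  writeLines(c("subject,analyte,time,conc", "r1,x,1,5", "r1,x,2,oops"), tmp)
  expect_error(read_conc_table(tmp, dose = 1), "row 2")
})
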