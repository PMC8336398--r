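test_that("well-formed life tables round-trip through CSV and validation", {
  lt <- flat_life_table(0.003)
  expect_s3_class(lt, "life_table")
  expect_equal(range(lt$age), c(0, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(lt, path)
  expect_equal(as.data.frame(read_life_table(path)), as.data.frame(lt))
})

test_that("malformed life tables are rejected with the offending row named", {
  expect_error(life_table(data.frame(age = c(0, 1, 2), qx = c(0.1, 1.2, 1))),
               "age 1", class = "ahpfisc_format_error")
  expect_error(life_table(data.frame(age = c(30, 32, 33), qx = c(0, 0, 1))),
               "contiguous", class = "ahpfisc_format_error")
  expect_error(life_table(data.frame(age = 0:2, qx = c(0, 0, 0.5))),
               "closed", class = "ahpfisc_format_error")
  expect_error(life_table(data.frame(age = 0:2, mortality = c(0, 0, 1))),
               "qx", class = "ahpfisc_format_error")
})

test_that("conditional survival follows the product rule and conditioning", {
  lt <- flat_life_table(0.1)
  s <- conditional_survival(lt, 30, 40)
  expect_equal(s$survival[1], 1)                      # S(base) = 1
  expect_equal(s$survival[s$age == 32], 0.81)         # (1 - 0.1)^2
  expect_true(all(diff(s$survival) <= 0))
  # immortal limit
  s0 <- conditional_survival(flat_life_table(0), 30, 100)
  expect_true(all(s0$survival == 1))
  expect_error(conditional_survival(lt, 30, 200), class = "ahpfisc_range_error")
  expect_error(conditional_survival(lt, 50, 40), class = "ahpfisc_range_error")
})

test_that("survival is monotone non-increasing for arbitrary valid tables", {
  set.seed(42)
  for (i in 1:20) {
    qx <- c(runif(100, 0, 0.3), 1)
    s <- conditional_survival(life_table(tibble::tibble(age = 0:100, qx = qx)),
                              30, 100)
    expect_true(all(diff(s$survival) <= 1e-15))
    expect_true(all(s$survival >= 0 & s$survival <= 1))
  }
})

test_that("expected work years: full-employment count and closed-form annuity", {
  act <- tibble::tibble(age = 18:100, value = 1)
  s0 <- conditional_survival(flat_life_table(0), 30, 100)
  expect_equal(expected_work_years(act, s0, 0, 30, 65, 30), 35)
  # brute-force sum over 35 start-of-year cashflows at 3%, frozen from the
  # loop oracle, cross-checked against the annuity-due closed form
  brute <- sum(1.03^-(0:34))
  expect_equal(brute, (1 - 1.03^-35) / 0.03 * 1.03, tolerance = 1e-12)
  expect_equal(expected_work_years(act, s0, 0.03, 30, 65, 30), 22.1318371,
               tolerance = 1e-7)
  # constant participation p scales the annuity linearly (closed-form oracle)
  act$value <- 0.7
  expect_equal(expected_work_years(act, s0, 0.03, 30, 65, 30), 0.7 * brute,
               tolerance = 1e-9)
  act$value <- 0
  expect_equal(expected_work_years(act, s0, 0.03, 30, 65, 30), 0)
})

test_that("pre-base work years are counted undiscounted", {
  act <- tibble::tibble(age = 18:100, value = 1)
  s0 <- conditional_survival(flat_life_table(0), 30, 100)
  # ages 18..29 carry discount factor 1, ages 30..64 the annuity
  expect_equal(expected_work_years(act, s0, 0.03, 18, 65, 30),
               12 + sum(1.03^-(0:34)), tolerance = 1e-9)
})

test_that("raising mortality weakly decreases expected work years", {
  set.seed(7)
  act <- tibble::tibble(age = 18:100, value = 0.8)
  base_qx <- c(runif(100, 0, 0.05), 1)
  wy <- function(qx) {
    s <- conditional_survival(life_table(tibble::tibble(age = 0:100, qx = qx)),
                              30, 100)
    expected_work_years(act, s, 0.03, 18, 65, 30)
  }
  w0 <- wy(base_qx)
  for (i in sample(30:64, 5)) {
    qx2 <- base_qx
    qx2[i + 1] <- min(1, qx2[i + 1] + 0.1)
    expect_lte(wy(qx2), w0)
  }
})

test_that("empty overlap between activity and the work window errors", {
  act <- tibble::tibble(age = 70:80, value = 1)
  s0 <- conditional_survival(flat_life_table(0), 30, 100)
  expect_error(expected_work_years(act, s0, 0.03, 18, 65, 30),
               class = "ahpfisc_range_error")
})
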