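make_peaks <- function(...) {
  rows <- list(...)
  peak_table(do.call(rbind, lapply(rows, function(r)
    data.frame(species_i = r[[1]], species_j = r[[2]],
               mu = as.numeric(r[[3]]),
               sigma = if (length(r) > 3) as.numeric(r[[4]]) else NA_real_,
               stringsAsFactors = FALSE))))
}

test_that("a_i estimation from anchor peak ratios", {
  pk <- make_peaks(list("At", "Vv", 1.2), list("At", "X", 1.0),
                   list("Ef", "Vv", 1.5), list("Ef", "X", 1.25))
  expect_equal(estimate_a(pk, "X"), 1.2)
  pk2 <- make_peaks(list("At", "Vv", 1.2), list("At", "X", 1.0),
                    list("Ef", "Vv", 1.2), list("Ef", "X", 1.0))
  expect_equal(estimate_a(pk2, "X"), 1.2)
  # all anchor peaks equal -> a = 1; baseline itself is exactly 1
  pk3 <- make_peaks(list("At", "Vv", 1.0), list("At", "X", 1.0),
                    list("Ef", "Vv", 1.0), list("Ef", "X", 1.0))
  expect_equal(estimate_a(pk3, "X"), 1)
  expect_identical(estimate_a(pk3, "Vv"), 1)
  expect_error(estimate_a(make_peaks(list("At", "Vv", 1.2)), "X"),
               "At-X")
})

test_that("lambda solving pins the slowest species at 1", {
  m <- solve_lambda(c(Vv = 1.0, X = 1.2))
  expect_equal(m$lambda[["Vv"]], 0.8333, tolerance = 1e-4)
  expect_equal(m$lambda[["X"]], 1)
  expect_equal(m$lambda[["At"]], 1)

  m2 <- solve_lambda(c(Vv = 1, X = 1, Y = 1))
  expect_true(all(m2$lambda == 1))

  m3 <- solve_lambda(c(Vv = 1.0, X = 2.0, Y = 0.5))
  expect_equal(unname(m3$lambda[c("Vv", "X", "Y")]), c(0.5, 1, 0.25))
  expect_equal(max(m3$lambda[names(m3$a)]), 1)
  expect_error(solve_lambda(c(Vv = -1)), "nonpositive")
})

test_that("peak correction scales mean and sd linearly", {
  p <- list(mu = 1.0, sigma = 0.1)
  expect_equal(correct_distribution(p, 1, 1),
               list(mu_corrected = 1.0, sigma_corrected = 0.1))
  c2 <- correct_distribution(p, 0.8, 0.5)
  expect_equal(c2$mu_corrected, 0.40)
  expect_equal(c2$sigma_corrected, 0.04)
  # within-genome peak: lambda_i squared
  expect_equal(correct_distribution(p, 0.5, 0.5)$mu_corrected, 0.25)
})

test_that("dating scales the calibration window linearly", {
  cal <- ks_calibration(mu_ref = 1.0)
  expect_equal(date_event(1.0, cal)[c("age_low", "age_high")],
               list(age_low = 115, age_high = 130))
  expect_equal(date_event(0.5, cal)$age_low_raw, 57.5)
  expect_equal(date_event(0.5, cal)$age_high_raw, 65)
  d <- date_event(0.15, cal)
  expect_equal(d$age_low, 17)
  expect_equal(d$age_high, 20)
  expect_error(date_event(-0.1, cal), "nonpositive")
  expect_error(ks_calibration(1, 130, 115))
})

test_that("corrected peaks are consistent across anchors", {
  # construction with exactly consistent ratios -> zero deviation
  pk <- make_peaks(list("At", "Vv", 1.2), list("At", "X", 1.0),
                   list("Ef", "Vv", 1.8), list("Ef", "X", 1.5))
  model <- fit_rate_model(pk)
  chk <- consistency_check(pk, model)
  expect_equal(chk$max_deviation, 0, tolerance = 1e-12)

  # 5% discordance between the two anchor-derived ratios stays <= 5%
  pk2 <- make_peaks(list("At", "Vv", 1.2), list("At", "X", 1.0),
                    list("Ef", "Vv", 1.8 * 1.05), list("Ef", "X", 1.5))
  model2 <- fit_rate_model(pk2)
  expect_lte(consistency_check(pk2, model2)$max_deviation, 0.05 + 1e-9)
})

test_that("the correction is scale equivariant", {
  pk <- make_peaks(list("At", "Vv", 1.2), list("At", "X", 0.9),
                   list("Ef", "Vv", 1.4), list("Ef", "X", 1.0),
                   list("Vv", "Vv", 0.8))
  scale_by <- function(pt, c) {
    for (k in names(pt)) pt[[k]]$mu <- pt[[k]]$mu * c
    pt
  }
  m1 <- fit_rate_model(pk)
  m2 <- fit_rate_model(scale_by(pk, 3))
  expect_equal(m1$lambda, m2$lambda)
  cal1 <- ks_calibration(m1$lambda[["Vv"]]^2 * pk[["Vv-Vv"]]$mu)
  cal2 <- ks_calibration(m2$lambda[["Vv"]]^2 * 3 * pk[["Vv-Vv"]]$mu)
  ev1 <- m1$lambda[["At"]] * m1$lambda[["X"]] * pk[["At-X"]]$mu
  expect_equal(date_event(ev1, cal1)$age_low_raw,
               date_event(3 * ev1, cal2)$age_low_raw)
})
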