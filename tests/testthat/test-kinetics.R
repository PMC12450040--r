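test_that("Hill curve has the half-saturation and saturation properties", {
  p <- hill_params(5, 80)
  expect_identical(hill_eval(p, 0), 0)
  expect_equal(hill_eval(p, 80), 2.5)
  expect_equal(hill_eval(p, 720), 4.5)       # 5 * 720 / 800
  expect_error(hill_eval(p, -1), class = "deswax_domain_error")

  # f(b) = a/2 holds for every shape parameter
  for (cc in c(0.5, 1, 2, 3.7)) {
    expect_equal(hill_eval(hill_params(3, 55, cc), 55), 1.5)
  }

  # c = 1 is identically the Michaelis-Menten form
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 1, 500); t <- runif(1, 0, 1000)
    expect_equal(hill_eval(hill_params(a, b), t), a * t / (b + t),
                 tolerance = 1e-12)
  }
})

test_that("the c = 1 rate law is the quadratic-deficit form", {
  p <- hill_params(5, 80)
  expect_equal(hill_rate(p, 0), 5 / 80)
  expect_equal(hill_rate(p, 2.5), 5 / (4 * 80))
  expect_error(hill_rate(p, 5), class = "deswax_domain_error")

  # general rate reduces exactly to the quadratic law at c = 1
  f <- seq(0.01, 4.99, length.out = 40)
  p1 <- hill_params(5, 80, 1)
  expect_equal(hill_rate(p1, f), (5 / 80) * (1 - f / 5)^2,
               tolerance = 1e-12)
})

test_that("general-c rate matches the numerical derivative of the curve", {
  p <- hill_params(4, 120, 2)
  t <- 120  # f = a/2
  h <- 1e-4
  num <- (hill_eval(p, t + h) - hill_eval(p, t - h)) / (2 * h)
  expect_equal(hill_rate(p, hill_eval(p, t)), num, tolerance = 1e-8)

  for (cc in c(0.7, 1.6, 3)) {
    pp <- hill_params(2.5, 60, cc)
    for (t in c(20, 60, 300)) {
      num <- (hill_eval(pp, t + h) - hill_eval(pp, t - h)) / (2 * h)
      expect_equal(hill_rate(pp, hill_eval(pp, t)), num,
                   tolerance = 1e-6)
    }
  }
})

test_that("Noyes-Whitney comparison: quadratic law = first-order law with fading K", {
  a <- 5; b <- 80
  f <- seq(0, 5, length.out = 21)
  expect_equal(noyes_whitney_rate(0.3, a, a), 0)
  expect_equal(noyes_whitney_rate(0.3, a, 0), 0.3)
  # ratio of Hill to Noyes-Whitney rate at K = a/b is the remaining deficit
  fi <- f[f < a]
  ratio <- hill_rate(hill_params(a, b), fi) /
    noyes_whitney_rate(a / b, a, fi)
  expect_equal(ratio, 1 - fi / a, tolerance = 1e-12)
  # the effective-K form reproduces the quadratic law
  expect_equal(noyes_whitney_rate(NULL, a, fi, b = b),
               hill_rate(hill_params(a, b), fi), tolerance = 1e-12)
})

test_that("integrating the rate law reproduces the closed form", {
  sweep <- list(c(5, 80, 1), c(0.1, 1, 1), c(10, 500, 1),
                c(5, 80, 0.5), c(2, 40, 2), c(0.5, 300, 4),
                c(8, 15, 3), c(1, 120, 0.8))
  for (abc in sweep) {
    p <- hill_params(abc[1], abc[2], abc[3])
    sol <- integrate_hill(p, protocol_grid)
    expect_lt(max(abs(sol$values - hill_eval(p, protocol_grid))),
              1e-6 * p$a)
  }
})

test_that("large shape parameters approach the logistic rate law", {
  a <- 5; k <- 30
  cc <- 200
  p <- hill_params(a, b = cc * k, c = cc)
  f <- seq(0.5, 4.5, length.out = 17)
  logistic <- (a / k) * (f / a) * (1 - f / a)
  expect_equal(hill_rate(p, f), logistic, tolerance = 0.05)
  # midpoint slope agrees exactly in the limit and already at finite c
  expect_equal(hill_rate(p, a / 2), (a / k) / 4, tolerance = 1e-3)
})

test_that("kinetic series validate their invariants", {
  expect_error(kinetic_series(c(0, 10), c(1, 2)),
               class = "deswax_domain_error")          # n < 3
  expect_error(kinetic_series(c(0, 10, 5), c(1, 2, 3)),
               class = "deswax_domain_error")          # not increasing
  expect_error(kinetic_series(c(0, 10, 20), c(1, -2, 3)),
               class = "deswax_domain_error")          # negative response
  s <- kinetic_series(c(0, 10, 20), c(0, 1, 2), kind = "turbidity")
  expect_identical(s$kind, "turbidity")
})

test_that("time-series files average replicates per time point", {
  path <- tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(time_min = c(0, 30, 60), value = c(0, 1, 2),
               kind = "mass", replicate = 1),
    data.frame(time_min = c(0, 30, 60), value = c(0, 3, 4),
               kind = "mass", replicate = 2))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  series <- read_kinetic_series(path)
  expect_length(series, 1)
  expect_equal(series[[1]]$values, c(0, 2, 3))
  expect_equal(series[[1]]$sd[2], sd(c(1, 3)))

  writeLines("time_min,value,kind", path)
  expect_error(read_kinetic_series(path), class = "deswax_format_error")
})
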