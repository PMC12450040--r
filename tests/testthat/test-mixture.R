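make_pair <- function() {
  list(lauric = fatty_acid(10, 200.32, 0.883),
       capric = fatty_acid(8, 172.26, 0.893))
}

test_that("volume fractions follow the molar-ratio/molar-volume rule", {
  a <- des_component("a", c(CH3 = 1), molar_mass = 1, molar_volume = 120)
  b <- des_component("b", c(CH3 = 1), molar_mass = 1, molar_volume = 120)
  expect_equal(unname(volume_fractions(des_mixture(list(a, b), c(1, 1)))),
               c(0.5, 0.5))

  p <- make_pair()  # V = 226.9 / 192.9 cm3/mol
  phi <- volume_fractions(des_mixture(list(p$lauric, p$capric), c(1, 2)))
  expect_equal(unname(phi[1]), 0.370, tolerance = 1e-3)
  expect_equal(sum(phi), 1)

  # vanishing partner volume concentrates the mixture on the other one
  tiny <- des_component("tiny", c(CH3 = 1), molar_mass = 1,
                        molar_volume = 1e-9)
  phi2 <- volume_fractions(des_mixture(list(a, tiny), c(1, 1)))
  expect_equal(unname(phi2[1]), 1, tolerance = 1e-6)
  expect_error(des_mixture(list(a, b), c(1, 0)),
               class = "deswax_domain_error")
})

test_that("mixing two identical components leaves the triplet unchanged", {
  p <- make_pair()
  mix <- des_mixture(list(p$lauric, p$lauric), c(2, 5))
  expect_equal(unclass(mixture_hansen(mix)),
               unclass(component_hansen(p$lauric)), tolerance = 1e-12)
})

test_that("mixture parameters are symmetric and convex in the components", {
  p <- make_pair()
  groups <- hvk_table()
  m12 <- mixture_hansen(des_mixture(list(p$lauric, p$capric), c(1, 2)),
                        groups)
  m21 <- mixture_hansen(des_mixture(list(p$capric, p$lauric), c(2, 1)),
                        groups)
  expect_equal(unclass(m12), unclass(m21), tolerance = 1e-12)

  h1 <- unclass(component_hansen(p$lauric, groups))
  h2 <- unclass(component_hansen(p$capric, groups))
  for (w in c(0.2, 1, 7)) {
    m <- unclass(mixture_hansen(
      des_mixture(list(p$lauric, p$capric), c(w, 1)), groups))
    expect_true(all(m >= pmin(h1, h2) - 1e-12 & m <= pmax(h1, h2) + 1e-12))
  }
})

test_that("Teas fractions normalize, rescale-invariantly, to 100", {
  f <- teas_fractions(hansen(16.0, 2.1, 7.0))
  expect_equal(sum(unclass(f)), 100)
  expect_equal(unname(round_teas(f)), c(64L, 8L, 28L))

  expect_equal(unname(round_teas(teas_fractions(hansen(11.0, 4.8, 9.3)))),
               c(44L, 19L, 37L))
  expect_equal(unname(unclass(teas_fractions(hansen(1, 0, 0)))),
               c(100, 0, 0))

  base <- unclass(teas_fractions(hansen(3.1, 1.7, 0.4)))
  scaled <- unclass(teas_fractions(c(3.1, 1.7, 0.4) * 17.3))
  expect_equal(base, scaled, tolerance = 1e-12)

  expect_error(teas_fractions(c(0, 0, 0)), class = "deswax_domain_error")
})

test_that("largest-remainder rounding always totals 100", {
  set.seed(7)
  for (i in 1:50) {
    f <- teas_fractions(hansen(runif(1, 1, 20), runif(1, 0, 8),
                               runif(1, 0, 12)))
    expect_identical(sum(round_teas(f, "largest_remainder")), 100L)
  }
})

test_that("Teas chart projection places the dispersive apex at the origin side", {
  f <- teas_fractions(hansen(1, 0, 0))           # pure dispersion
  expect_equal(unname(teas_coordinates(f)), c(0, 0))
  fh <- teas_fractions(hansen(0, 0, 1))          # pure hydrogen bonding
  expect_equal(unname(teas_coordinates(fh)), c(50, 50 * sqrt(3)),
               tolerance = 1e-12)
})

test_that("the shipped mixture table resolves to twelve binary eutectics", {
  components <- read_component_table(
    system.file("extdata", "components.csv", package = "deswax"))
  mixtures <- read_mixture_table(
    system.file("extdata", "mixtures.csv", package = "deswax"), components)
  expect_length(mixtures, 12)
  report <- hansen_report(mixtures)
  expect_identical(nrow(report), 12L)
  expect_true(all(abs(report$F_d + report$F_p + report$F_h - 100) < 1e-9))

  bad <- tempfile(fileext = ".csv")
  writeLines("des_name,component1,component2,n1,n2", bad)
  expect_error(read_mixture_table(bad, components),
               class = "deswax_format_error")
  writeLines(c("des_name,component1,component2,n1,n2",
               "DES X,thymol,unobtainium,1,1"), bad)
  expect_error(read_mixture_table(bad, components), "unobtainium",
               class = "deswax_lookup_error")
})
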