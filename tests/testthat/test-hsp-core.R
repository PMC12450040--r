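test_that("molar volume comes from the stated value or M/rho", {
  lauric <- des_component("dodecanoic acid", c(CH3 = 1, CH2 = 10, COOH = 1),
                          molar_mass = 200.32, density = 0.883)
  expect_equal(molar_volume(lauric), 226.9, tolerance = 1e-3)

  stated <- des_component("x", c(CH3 = 1), molar_mass = 50,
                          molar_volume = 100)
  expect_identical(molar_volume(stated), 100)

  waterish <- des_component("w", c(OH = 1), molar_mass = 18, density = 1)
  expect_identical(molar_volume(waterish), 18)

  expect_error(des_component("bare", c(CH3 = 1), molar_mass = 50),
               class = "deswax_config_error")
})

test_that("single-group component reduces to the direct ratios", {
  tab <- make_group_table(data.frame(group = "X", F_d = 420, F_p = 0,
                                     E_h = 0))
  comp <- des_component("mono", c(X = 1), molar_mass = 1,
                        molar_volume = 100)
  h <- component_hansen(comp, tab)
  expect_equal(unclass(h),
               c(delta_d = 4.2, delta_p = 0, delta_h = 0))
})

test_that("fatty-acid Hansen parameters match hand accumulation", {
  groups <- hvk_table()
  # dodecanoic acid at the V = 226.9 cm3/mol of a 0.883 g/cm3 density
  lauric <- des_component("dodecanoic acid", c(CH3 = 1, CH2 = 10, COOH = 1),
                          molar_mass = 200.32, molar_volume = 226.9)
  h <- component_hansen(lauric, groups)
  # hand sums: F_d = 420 + 10*270 + 530 = 3650; F_p = 420; E_h = 10000
  expect_equal(h[["delta_d"]], 3650 / 226.9, tolerance = 1e-12)
  expect_equal(h[["delta_d"]], 16.1, tolerance = 0.01)
  expect_equal(h[["delta_p"]], 420 / 226.9, tolerance = 1e-12)
  expect_equal(h[["delta_h"]], sqrt(10000 / 226.9), tolerance = 1e-12)

  capric <- des_component("decanoic acid", c(CH3 = 1, CH2 = 8, COOH = 1),
                          molar_mass = 172.26, molar_volume = 192.9)
  expect_equal(component_hansen(capric, groups)[["delta_p"]], 2.2,
               tolerance = 0.03)
})

test_that("Hansen parameters scale correctly and vanish without polar groups", {
  groups <- hvk_table()
  base <- des_component("acid", c(CH3 = 1, CH2 = 6, COOH = 1),
                        molar_mass = 144.21, molar_volume = 158.5)
  doubled <- des_component("acid2", c(CH3 = 2, CH2 = 12, COOH = 2),
                           molar_mass = 288.42, molar_volume = 317)
  h1 <- unclass(component_hansen(base, groups))
  h2 <- unclass(component_hansen(doubled, groups))
  # delta_d and delta_h are intensive under formal dimerization; delta_p
  # sums *squared* constants per occurrence, so it scales by sqrt(n)/n
  # (the well-known non-additivity of the polar term)
  expect_equal(h2[["delta_d"]], h1[["delta_d"]], tolerance = 1e-12)
  expect_equal(h2[["delta_h"]], h1[["delta_h"]], tolerance = 1e-12)
  expect_equal(h2[["delta_p"]], h1[["delta_p"]] / sqrt(2),
               tolerance = 1e-12)

  alkane <- des_component("octane", c(CH3 = 2, CH2 = 6),
                          molar_mass = 114.23, density = 0.703)
  h <- component_hansen(alkane, groups)
  expect_identical(h[["delta_p"]], 0)
  expect_identical(h[["delta_h"]], 0)
})

test_that("vectorized evaluation agrees with per-occurrence oracle on random bags", {
  groups <- hvk_table()
  set.seed(101)
  for (i in 1:25) {
    labels <- sample(groups$group, sample(2:6, 1))
    counts <- setNames(sample(1:4, length(labels), replace = TRUE), labels)
    v <- runif(1, 50, 400)
    comp <- des_component("rand", counts, molar_mass = 1, molar_volume = v)
    expect_equal(as.numeric(unclass(component_hansen(comp, groups))),
                 hansen_oracle(groups, as.list(counts), v),
                 tolerance = 1e-10)
  }
})

test_that("unknown groups and malformed tables are reported by name", {
  groups <- hvk_table()
  comp <- des_component("bad", c(CH3 = 1, XX9 = 2), molar_mass = 50,
                        molar_volume = 80)
  expect_error(component_hansen(comp, groups), "XX9",
               class = "deswax_lookup_error")
  expect_error(
    make_group_table(data.frame(group = c("A", "A"), F_d = 1, F_p = 0,
                                E_h = 0)),
    class = "deswax_format_error")
})

test_that("component table round-trips through the label:count format", {
  components <- read_component_table(
    system.file("extdata", "components.csv", package = "deswax"))
  expect_length(components, 10)
  expect_equal(components[["dodecanoic acid"]]$groups,
               c(CH3 = 1, CH2 = 10, COOH = 1))
  expect_s3_class(components[["thymol"]], "des_component")
})
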