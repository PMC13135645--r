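std_lengths <- c(feeding = 100, vein = 100, distal = 50)
std_radii <- c(feeding = 2.5, vein = 3.5, distal = 2.5)

test_that("single-tube pressure drop equals the Hagen-Poiseuille closed form", {
  dp <- poiseuille_pressure_drop(100, 2.5, 600)
  expect_equal(dp, 8 * 3.5e-3 * 0.1 * 1e-5 / (pi * 0.0025^4), tolerance = 1e-10)
  expect_lt(abs(dp - 228), 1)
})

test_that("network keeps the maturation pressure ordering at nominal resistance", {
  net <- lumped_pressure_network(std_lengths, std_radii, 600)
  p <- net$pressures
  expect_true(p["inlet"] > p["anastomosis"])
  expect_true(p["anastomosis"] > 0)
  expect_false(net$distal_reversal)
  expect_gt(net$flows["distal"], 0)
})

test_that("a very large anastomotic area drives distal flow reversal (steal)", {
  net <- lumped_pressure_network(std_lengths, std_radii, 600,
                                 anastomosis_scale = 1e-3)
  expect_true(net$distal_reversal)
  expect_lt(net$flows["distal"], 0)
  expect_lt(net$pressures["anastomosis"], net$pressures["distal"])
})

test_that("zero inflow equalises all node pressures with no reversal", {
  net <- lumped_pressure_network(std_lengths, std_radii, 0)
  expect_equal(unname(net$pressures), c(0, 0, 0))
  expect_false(net$distal_reversal)
})

test_that("invalid network geometry is rejected", {
  expect_error(lumped_pressure_network(c(feeding = -1, vein = 100, distal = 50),
                                       std_radii, 600), "positive")
  expect_error(lumped_pressure_network(std_lengths, std_radii[-1], 600),
               "must name")
  expect_error(lumped_pressure_network(std_lengths, std_radii, 600,
                                       anastomosis_scale = 0), "> 0")
})
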