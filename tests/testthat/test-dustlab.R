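test_that("gravimetric mass is the weighing difference with an LOD flag", {
  g <- gravimetric_mass(250.0, 253.2)
  expect_equal(g$mass_mg, 3.2)
  expect_false(g$below_detection)

  # a faint wipe is flagged for the volumetric route
  faint <- gravimetric_mass(250.0, 250.1)
  expect_true(faint$below_detection)
  expect_equal(faint$mass_mg, 0.1)

  # small negative difference is weighing noise, reported as 0 with the flag
  noise <- gravimetric_mass(250.0, 249.9)
  expect_true(noise$below_detection)
  expect_equal(noise$mass_mg, 0)

  # a large negative difference is a weighing blunder
  expect_error(gravimetric_mass(250.0, 248.0), "blunder")
})

test_that("surface loading divides mass by the sampled area", {
  expect_equal(stencil_area("25x25"), 625)
  expect_equal(stencil_area("25x5"), 125)
  expect_equal(stencil_area(c(25, 15)), 375)
  expect_error(stencil_area("30x30"), "unknown stencil")

  expect_equal(surface_loading(3.2, stencil_area("25x25")), 0.00512)
  expect_equal(surface_loading(0, 625), 0)
  expect_error(surface_loading(3.2, 0), "positive")
})

test_that("coulter total volume sums spherical bin volumes with rinse scaling", {
  # 1000 particles at 10 um, aliquot = rinse: 1000 * (pi/6) * (1e-3 cm)^3
  v <- coulter_total_volume(list(
    bin_mid_um = 10, counts = 1000, aliquot_mL = 1, rinse_mL = 1
  ))
  expect_equal(v, 1000 * pi / 6 * 1e-9, tolerance = 1e-12)
  expect_equal(v, 5.236e-7, tolerance = 1e-4)

  # empty bins -> 0
  expect_equal(
    coulter_total_volume(list(
      bin_mid_um = c(5, 10), counts = c(0, 0),
      aliquot_mL = 1, rinse_mL = 150
    )),
    0
  )

  # analyzing 1 mL of a 150 mL rinse scales the volume by 150
  unscaled <- coulter_total_volume(list(
    bin_mid_um = 10, counts = 1000, aliquot_mL = 1, rinse_mL = 1
  ))
  scaled <- coulter_total_volume(list(
    bin_mid_um = 10, counts = 1000, aliquot_mL = 1, rinse_mL = 150
  ))
  expect_equal(scaled, 150 * unscaled)

  # bin edges: midpoints are geometric means
  v_edges <- coulter_total_volume(list(
    bin_edges_um = c(5, 20), counts = 1000, aliquot_mL = 1, rinse_mL = 1
  ))
  expect_equal(v_edges, unscaled) # sqrt(5 * 20) = 10
})

test_that("volume is invariant to splitting a bin preserving count x d^3", {
  base <- coulter_total_volume(list(
    bin_mid_um = 10, counts = 1000, aliquot_mL = 1, rinse_mL = 1
  ))
  # split into two sub-bins whose count-weighted d^3 total is preserved
  split <- coulter_total_volume(list(
    bin_mid_um = c(8, 12), counts = c(500 * 1000 / 512, 500 * 1000 / 1728),
    aliquot_mL = 1, rinse_mL = 1
  ))
  expect_equal(split, base, tolerance = 1e-12)
})

test_that("volumetric mass is M = V x rho and linear in both arguments", {
  expect_equal(volumetric_mass(5.236e-7, 2.65), 1.388e-6, tolerance = 1e-3)
  expect_equal(volumetric_mass(0, 2.65), 0)
  expect_equal(volumetric_mass(2e-6, 2.65), 2 * volumetric_mass(1e-6, 2.65))
  expect_equal(volumetric_mass(1e-6, 5.3), 2 * volumetric_mass(1e-6, 2.65))
  expect_error(volumetric_mass(1e-6, NA), "density")
})

test_that("pycnometer calibration divides water mass by water density", {
  # empty 10.0000 g, filled 11.0021 g at 20 C
  v <- pycnometer_volume(10.0000, 11.0021, 20)
  expect_equal(v, 1.0039, tolerance = 1e-4)

  # replicate mean: two identical runs equal the single-run value
  v2 <- pycnometer_volume(c(10, 10), c(11.0021, 11.0021), 20)
  expect_equal(v2, v)

  expect_error(pycnometer_volume(10, 11, 50), "10-35")
})

test_that("pure-water self-test recovers the nominal volume within 0.5%", {
  # synthetic runs generated with the same water-density table
  for (t in c(12, 20, 28, 34)) {
    filled <- 10 + 1.0 * water_density(t) # exactly 1 mL of water
    expect_lt(abs(pycnometer_volume(10, filled, t) - 1) / 1, 0.005)
  }
})

test_that("dust density by water displacement matches the hand example", {
  # 1 mL vessel, 0.5000 g dust, 0.8113 g water added at 20 C
  res <- dust_density(data.frame(
    empty_g = 10.0000, dust_g = 0.5000,
    filled_g = 10.0000 + 0.5000 + 0.8113,
    temp_c = 20, volume_mL = 1.0000
  ))
  expect_equal(res$density_g_cm3, 2.670, tolerance = 1e-3)
  # water volume 0.81276 mL -> dust volume 0.18724 mL
  expect_equal(0.8113 / water_density(20), 0.81276, tolerance = 1e-4)

  # replicates average; a single run is its own value
  two <- dust_density(data.frame(
    empty_g = c(10, 10), dust_g = c(0.5, 0.5),
    filled_g = 10.5 + c(0.8113, 0.8120),
    temp_c = 20, volume_mL = 1
  ))
  expect_equal(two$density_g_cm3, mean(two$per_run))
  expect_equal(length(two$per_run), 2)

  expect_error(
    dust_density(data.frame(
      empty_g = 10, dust_g = 0, filled_g = 11, temp_c = 20, volume_mL = 1
    )),
    "dust mass"
  )
  # dust volume <= 0 (too much water for the vessel) is an error
  expect_error(
    dust_density(data.frame(
      empty_g = 10, dust_g = 0.5, filled_g = 10.5 + 1.1, temp_c = 20,
      volume_mL = 1
    )),
    "non-positive"
  )
})

test_that("hand area counts filled 1 cm2 cells over both hands", {
  left2 <- matrix(0, 10, 10); left2[seq_len(85)] <- 1
  right2 <- matrix(0, 10, 10); right2[seq_len(83)] <- 1
  expect_equal(hand_area_from_trace(left2, right2), 168)
  expect_equal(hand_area_from_trace(matrix(c(1, 0, 0, 0), 2, 2)), 1)
  # checkerboard 10x10: 50 filled cells
  cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  expect_equal(hand_area_from_trace(cb), 50)
  expect_error(hand_area_from_trace(matrix(0, 3, 3)), "no filled cells")
  expect_error(hand_area_from_trace(matrix(0.5, 2, 2)), "binary")
})

test_that("hand traces read from text grids and CSV", {
  grid_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0110", "1111", "0110"), grid_path)
  m <- read_hand_trace(grid_path)
  expect_equal(sum(m), 8)

  csv_path <- withr::local_tempfile(fileext = ".csv")
  write.table(matrix(c(1, 1, 0, 1), 2, 2),
    csv_path,
    sep = ",",
    row.names = FALSE, col.names = FALSE
  )
  expect_equal(sum(read_hand_trace(csv_path)), 3)
})

test_that("hand rinse loading is the pre/post mass gain over traced area", {
  post <- generate_coulter_fixture(0.0015, 2.65) # 1.5 mg in the post rinse
  pre <- generate_coulter_fixture(0, 2.65)
  res <- hand_rinse_loading(pre, post, area_cm2 = 150)
  expect_equal(res$loading_mg_cm2, 0.01, tolerance = 0.01)
  expect_false(res$negative_gain)

  # post below pre floors at zero with the flag
  res2 <- hand_rinse_loading(post, pre, area_cm2 = 150)
  expect_equal(res2$loading_mg_cm2, 0)
  expect_true(res2$negative_gain)
  expect_error(hand_rinse_loading(pre, post, 0), "positive")
})

test_that("gravimetric and volumetric pipelines agree on synthetic samples", {
  # construct a wipe well above both detection limits: known true mass
  for (true_mg in c(2, 5, 20)) {
    fx <- generate_coulter_fixture(true_mg / 1000, 2.65)
    vol_mg <- volumetric_mass(coulter_total_volume(fx), 2.65) * 1000
    grav <- gravimetric_mass(250, 250 + true_mg)
    expect_false(grav$below_detection)
    expect_lt(abs(vol_mg - grav$mass_mg) / grav$mass_mg, 0.10)
  }
})
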