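test_that("a dermal contact moves hand loading toward the surface loading", {
  h <- hand_state("right", area = 150)
  h <- dermal_contact_step(h, 0.01, 0.2, 0.5)
  expect_equal(hand_loading(h), 0.001) # 0 + 0.2 * 0.5 * (0.01 - 0)

  # equilibrium: hand at the surface loading is unchanged
  h2 <- hand_state("right", area = 150, loading_dust = 0.01)
  h2 <- dermal_contact_step(h2, 0.01, 0.3, 0.8)
  expect_equal(hand_loading(h2), 0.01)

  # a dirtier hand off-loads back to the surface
  h3 <- hand_state("right", area = 150, loading_dust = 0.05)
  h3 <- dermal_contact_step(h3, 0.01, 0.5, 1)
  expect_equal(hand_loading(h3), 0.05 + 0.5 * 1 * (0.01 - 0.05))
})

test_that("the contact step stays within physical bounds over a parameter grid", {
  grid <- expand.grid(
    L = c(0, 0.001, 0.01, 0.1, 0.5),
    L_surf = c(0, 0.005, 0.05, 0.5),
    TF = c(0, 0.2, 1),
    fSA = c(0, 0.5, 1),
    L_max = c(0.02, 0.2, Inf)
  )
  grid <- grid[grid$L <= grid$L_max, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    h <- hand_state("right", 150, loading_dust = g$L, max_loading = g$L_max)
    h2 <- dermal_contact_step(h, g$L_surf, g$TF, g$fSA)
    L2 <- hand_loading(h2)
    expect_gte(L2, 0)
    expect_lte(L2, g$L_max + 1e-12)
    expect_gte(L2, min(g$L, g$L_surf) - 1e-12)
    expect_lte(L2, max(g$L, g$L_surf) + 1e-12)
  }
})

test_that("handwash scales loading by one minus the removal efficiency", {
  h <- hand_state("left", 100, loading_dust = 4)
  expect_equal(hand_loading(handwash_event(h, 1.0)), 0)
  expect_equal(hand_loading(handwash_event(h, 0)), 4)
  expect_equal(hand_loading(handwash_event(h, 0.75)), 1)
})

test_that("a mouthing event ingests loading x area x efficiency", {
  ev <- mouthing_event(0.002, 10, 0.5) # 2 ug/cm2 over 10 cm2 at RE 0.5
  expect_equal(ev$ingested_mg, 0.01) # = 10 ug
  expect_equal(ev$residual_loading, 0.002) # object source: undepleted

  # RE = 0 ingests nothing
  ev0 <- mouthing_event(0.002, 10, 0)
  expect_equal(ev0$ingested_mg, 0)

  # hand source depletes: mass balance over the whole hand
  evh <- mouthing_event(0.002, 10, 0.5, source_area = 150)
  expect_equal(evh$ingested_mg, 0.01)
  expect_equal(evh$residual_loading, (0.002 * 150 - 0.01) / 150)
  expect_error(mouthing_event(0.002, 200, 0.5, source_area = 150), "exceeds")
})

test_that("back-to-back hand mouthings ingest strictly less each time", {
  # ledger-arithmetic oracle: without recontact the second event draws on a
  # depleted hand, so the ingested masses decrease geometrically
  loading <- 0.01
  area <- 150
  ingested <- numeric(3)
  for (i in 1:3) {
    ev <- mouthing_event(loading, 20, 0.6, source_area = area)
    ingested[i] <- ev$ingested_mg
    loading <- ev$residual_loading
  }
  expect_true(all(diff(ingested) < 0))
  frac <- 1 - 20 * 0.6 / area # per-event retained fraction of hand mass
  expect_equal(ingested[2] / ingested[1], frac)
  expect_equal(ingested[3] / ingested[2], frac)
})

test_that("dose algorithms reproduce their closed forms", {
  # CF forces the all-ones dose to 1e-6 mg/kg/day
  ones <- dose_inputs(C = 1, SA = 1, AF = 1, ABS = 1, EF = 1, BW = 1, IR = 1)
  expect_equal(dermal_absorbed_dose(ones), 1e-6)
  expect_equal(ingestion_dose(ones), 1e-6)

  # linearity in concentration
  d1 <- dermal_absorbed_dose(dose_inputs(C = 3, SA = 2, AF = 1, ABS = 0.5, EF = 1, BW = 10))
  d2 <- dermal_absorbed_dose(dose_inputs(C = 6, SA = 2, AF = 1, ABS = 0.5, EF = 1, BW = 10))
  expect_equal(d2, 2 * d1)

  # hand-evaluated examples
  dder <- dermal_absorbed_dose(
    dose_inputs(C = 250, SA = 400, AF = 0.2, ABS = 0.1, EF = 1, BW = 15)
  )
  expect_equal(dder, 0.002 / 15, tolerance = 1e-12)
  ding <- ingestion_dose(dose_inputs(C = 100, IR = 60, EF = 1, BW = 12))
  expect_equal(ding, 5e-4, tolerance = 1e-12)

  # EF = 0 zeroes the dose; BW <= 0 is rejected
  expect_equal(ingestion_dose(dose_inputs(C = 100, IR = 60, EF = 0, BW = 12)), 0)
  expect_error(dose_inputs(C = 1, BW = 0), "body weight")
})

test_that("a child simulation with point factors is fully deterministic", {
  sc <- composition_scenario()
  fset <- point_factor_set()
  a <- run_child_simulation(sc$left, sc$right, sc$mouth, fset, seed = 1)
  b <- run_child_simulation(sc$left, sc$right, sc$mouth, fset, seed = 99)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$hand_loading, b$hand_loading)
})

test_that("no mouthing events means zero cumulative ingestion", {
  sc <- composition_scenario()
  quiet_mouth <- one_record_series("mouth", "Bedroom", "Nothing", 20)
  res <- run_child_simulation(
    sc$left, sc$right, quiet_mouth, point_factor_set(),
    seed = 1
  )
  expect_equal(nrow(res$ledger), 0)
  expect_equal(unname(res$ingested_mg["dust"] + res$ingested_mg["soil"]), 0)
})

test_that("single contact then hand mouthing composes in closed form", {
  # ingested = (TF * f_SA * L_surf) * A_mouth * RE with point factors
  sc <- composition_scenario()
  fset <- point_factor_set(
    surface_loading = 0.01, tf = 0.2, f_sa = 0.5,
    a_mouth = 10, re = 0.5, hand_area = 150
  )
  res <- run_child_simulation(
    sc$left, sc$right, sc$mouth, fset,
    config = sim_config(dominant_hand = "right"), seed = 1
  )
  expected <- (0.2 * 0.5 * 0.01) * 10 * 0.5
  expect_equal(sum(res$ledger$mass_mg), expected, tolerance = 1e-12)
  expect_equal(res$ledger$pathway, "hand_to_mouth")
})

test_that("Monte Carlo mean of the composition matches the product of means", {
  # TF, f_SA, RE, A_mouth, L_surf sampled independently per contact, so the
  # expected ingested mass is the product of the factor means
  sc <- composition_scenario()
  ln <- function(name, gm, gsd, units, support = c(0, Inf)) {
    factor_dist(name, "lognormal", list(gm = gm, gsd = gsd), units, support)
  }
  fset <- point_factor_set(hand_area = 300)
  d <- fset$distributions
  d$transfer_fraction <- ln("transfer_fraction", 0.2, 1.2, "unitless", c(0, 1))
  d$fraction_hand_contact <- ln("fraction_hand_contact", 0.2, 1.2, "unitless", c(0, 1))
  d$mouthing_removal_efficiency <- ln("mouthing_removal_efficiency", 0.4, 1.2, "unitless", c(0, 1))
  d$mouthed_area <- ln("mouthed_area", 10, 1.3, "cm2")
  d$surface_dust_loading <- ln("surface_dust_loading", 0.01, 1.5, "mg/cm2")
  fset <- factor_set(d)

  n <- 1e4
  set.seed(123)
  totals <- vapply(seq_len(n), function(i) {
    sum(run_child_simulation(
      sc$left, sc$right, sc$mouth, fset,
      config = sim_config(dominant_hand = "right")
    )$ledger$mass_mg)
  }, numeric(1))
  expected <- prod(vapply(
    d[c(
      "transfer_fraction", "fraction_hand_contact",
      "mouthing_removal_efficiency", "mouthed_area", "surface_dust_loading"
    )],
    factor_mean, numeric(1)
  ))
  se <- sd(totals) / sqrt(n)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("scaling all loadings scales cumulative ingestion linearly", {
  sc <- random_child_series(5, total_s = 300)
  for (alpha in c(2, 10)) {
    base <- run_child_simulation(
      sc$left_hand, sc$right_hand, sc$mouth,
      point_factor_set(surface_loading = 0.01, soil_loading = 0.05, l_max = Inf),
      seed = 1
    )
    scaled <- run_child_simulation(
      sc$left_hand, sc$right_hand, sc$mouth,
      point_factor_set(
        surface_loading = 0.01 * alpha, soil_loading = 0.05 * alpha,
        l_max = Inf
      ),
      seed = 1
    )
    expect_equal(
      sum(scaled$ledger$mass_mg), alpha * sum(base$ledger$mass_mg),
      tolerance = 1e-9
    )
  }
})

test_that("mass is conserved across random seeded child simulations", {
  for (seed in 1:25) {
    series <- random_child_series(seed, total_s = 300)
    fset <- default_factor_set()
    res <- run_child_simulation(
      series$left_hand, series$right_hand, series$mouth, fset,
      seed = seed
    )
    l_max <- res$child$max_hand_loading
    expect_true(all(res$hand_loading$loading >= -1e-12))
    expect_true(all(res$hand_loading$loading <= l_max + 1e-9))
    expect_true(all(diff(res$ledger$cumulative_mg) >= -1e-12))
    hand_ingested <- sum(res$ledger$mass_mg[res$ledger$pathway == "hand_to_mouth"])
    expect_lte(hand_ingested, res$transferred_to_hands_mg + 1e-9)
  }
})

test_that("clock mismatch beyond tolerance is an error", {
  left <- one_record_series("left_hand", "Bedroom", "Nothing", 100)
  right <- one_record_series("right_hand", "Bedroom", "Nothing", 100)
  mouth <- one_record_series("mouth", "Bedroom", "Nothing", 90)
  expect_error(
    run_child_simulation(left, right, mouth, point_factor_set()),
    "clocks disagree"
  )
  mouth99 <- one_record_series("mouth", "Bedroom", "Nothing", 99)
  expect_silent(
    run_child_simulation(left, right, mouth99, point_factor_set(), seed = 1)
  )
})

test_that("medium is assigned by location: outdoor contacts are soil", {
  left <- one_record_series("left_hand", "Yard", "Nothing", 30)
  right <- one_record_series("right_hand", "Yard", "Soil", 30)
  mouth <- series_of("mouth", "Yard", c("Nothing", "Hands"), c(15, 15))
  res <- run_child_simulation(
    left, right, mouth, point_factor_set(),
    config = sim_config(dominant_hand = "right"), seed = 1
  )
  expect_true(all(res$ledger$medium == "soil"))
  expect_gt(sum(res$ledger$mass_mg), 0)
})

test_that("handwash events reset loading mid-simulation", {
  left <- one_record_series("left_hand", "Bedroom", "Nothing", 60)
  right <- series_of("right_hand", "Bedroom", c("Floor", "Nothing"), c(30, 30))
  mouth <- one_record_series("mouth", "Bedroom", "Nothing", 60)
  fset <- point_factor_set(wash_eff = 1)
  washed <- run_child_simulation(
    left, right, mouth, fset,
    config = sim_config(handwash_times_s = 45), seed = 1
  )
  final <- washed$final_hands$right
  expect_equal(hand_loading(final), 0)
})

test_that("daily extrapolation scales by time-activity hours and is additive", {
  ledger <- data.frame(
    time_s = c(1800, 5400), pathway = "object_to_mouth",
    medium = "dust", mass_mg = c(0.2, 0.3),
    cumulative_mg = c(0.2, 0.5), stringsAsFactors = FALSE
  )
  # 0.5 mg over 2 h observed, 10 indoor h/day -> 2.5 mg/day
  rate <- extrapolate_daily_rate(
    ledger,
    profile = list(indoor_h = 10, outdoor_h = 2), observed_s = 7200
  )
  expect_equal(unname(rate["dust"]), 2.5)
  expect_equal(unname(rate["soil"]), 0)

  # zero ledger -> zero rate
  empty <- ledger[0, ]
  expect_equal(
    unname(extrapolate_daily_rate(empty,
      profile = list(indoor_h = 10, outdoor_h = 2),
      observed_s = 7200
    )["total"]),
    0
  )
  expect_error(
    extrapolate_daily_rate(empty, observed_s = 0),
    "zero observation"
  )

  # splitting the window in half and averaging the two rates recombines to
  # the full-window rate
  h1 <- ledger[ledger$time_s <= 3600, ]
  h2 <- ledger[ledger$time_s > 3600, ]
  r1 <- extrapolate_daily_rate(h1, profile = list(indoor_h = 10, outdoor_h = 2), observed_s = 3600)
  r2 <- extrapolate_daily_rate(h2, profile = list(indoor_h = 10, outdoor_h = 2), observed_s = 3600)
  expect_equal((r1 + r2) / 2, rate)
})
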