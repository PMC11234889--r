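# Shared builders for test fixtures: everything is constructed in code.

# The published example MLATS file (right hand observed): six records.
example_mlats_lines <- function() {
  c(
    "Activity type\tLocation\tObject/Surface\tDuration (Seconds)",
    "Constant\tBedroom\tHard_Toy\t15",
    "Constant\tBedroom\tNothing\t5",
    "Constant\tBedroom\tHard_Toy\t30",
    "Repetitive\tKitchen\tClothing\t12",
    "Constant\tKitchen\tNothing\t2",
    "Constant\tKitchen\tSticky_Food\t45"
  )
}

# A factor set where every factor is a point mass, for deterministic runs.
point_factor_set <- function(surface_loading = 0.01,
                             soil_loading = 0.05,
                             tf = 0.2, f_sa = 0.5,
                             hand_area = 150, a_mouth = 10,
                             re = 0.5, l_max = Inf,
                             wash_eff = 0.9, bw = 12,
                             conc = 100) {
  pt <- function(name, value, units, support = c(0, Inf)) {
    factor_dist(name, "point", list(value = value), units, support)
  }
  factor_set(list(
    surface_dust_loading = pt("surface_dust_loading", surface_loading, "mg/cm2"),
    soil_loading_outdoor = pt("soil_loading_outdoor", soil_loading, "mg/cm2"),
    transfer_fraction = pt("transfer_fraction", tf, "unitless", c(0, 1)),
    fraction_hand_contact = pt("fraction_hand_contact", f_sa, "unitless", c(0, 1)),
    hand_area = pt("hand_area", hand_area, "cm2"),
    mouthed_area = pt("mouthed_area", a_mouth, "cm2"),
    mouthing_removal_efficiency = pt("mouthing_removal_efficiency", re, "unitless", c(0, 1)),
    max_hand_loading = pt("max_hand_loading", l_max, "mg/cm2"),
    handwash_removal_efficiency = pt("handwash_removal_efficiency", wash_eff, "unitless", c(0, 1)),
    body_weight = pt("body_weight", bw, "kg"),
    contaminant_concentration = pt("contaminant_concentration", conc, "mg/kg"),
    exposure_factor = pt("exposure_factor", 1, "unitless", c(0, 1)),
    absorption_fraction = pt("absorption_fraction", 0.1, "unitless", c(0, 1)),
    soil_skin_adherence = pt("soil_skin_adherence", 0.2, "mg/cm2"),
    surface_area_contact = pt("surface_area_contact", 10, "cm2")
  ))
}

# Single-record series builder.
one_record_series <- function(body_part, location, object, duration_s,
                              activity = "constant", child_id = "t") {
  mlats_series(
    data.frame(
      activity_type = activity, location = location,
      object_surface = object, duration_s = duration_s,
      stringsAsFactors = FALSE
    ),
    body_part,
    child_id = child_id
  )
}

# Multi-record series from parallel vectors.
series_of <- function(body_part, location, object, duration_s,
                      activity = "constant", child_id = "t") {
  n <- max(length(location), length(object), length(duration_s))
  mlats_series(
    data.frame(
      activity_type = rep_len(activity, n),
      location = rep_len(location, n),
      object_surface = rep_len(object, n),
      duration_s = rep_len(duration_s, n),
      stringsAsFactors = FALSE
    ),
    body_part,
    child_id = child_id
  )
}

# The one-contact-then-mouthing scenario: the right hand touches a surface
# once at t = 0, and the mouth mouths the hands at t = 10.
composition_scenario <- function() {
  list(
    left = one_record_series("left_hand", "Bedroom", "Nothing", 20),
    right = series_of(
      "right_hand", "Bedroom", c("Hard_Toy", "Nothing"), c(10, 10)
    ),
    mouth = series_of(
      "mouth", "Bedroom", c("Nothing", "Hands"), c(10, 10)
    )
  )
}

# Random small series triple for property sweeps.
random_child_series <- function(seed, total_s = 300) {
  cfg <- synth_config(
    states = data.frame(
      location = c("Bedroom", "Kitchen", "Outdoor", "Living_Room"),
      object = c("Hard_Toy", "Floor", "Soil", "Nothing"),
      stringsAsFactors = FALSE
    ),
    dwell_gm_s = 8, dwell_gsd = 2, p_repetitive = 0.2,
    hand_mouth_per_h = 40, object_mouth_per_h = 20,
    total_s = total_s
  )
  generate_mlats(cfg, seed = seed)
}
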