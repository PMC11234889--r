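#' Hand loading state
#'
#' Tracks the dust/soil mass per unit area currently carried by one hand.
#' Loading is split into a dust component and a soil component so that
#' ingested mass can later be attributed to medium; the total loading is
#' their sum and is kept within `[0, max_loading]` at all times.
#'
#' @param hand `"left"` or `"right"`.
#' @param area Palmar hand area, cm2 (> 0).
#' @param loading_dust,loading_soil Initial loadings, mg/cm2 (>= 0).
#' @param max_loading Saturation cap on total loading, mg/cm2 (may be `Inf`).
#' @return An object of class `hand_state`.
#' @export
hand_state <- function(hand = c("right", "left"), area,
                       loading_dust = 0, loading_soil = 0,
                       max_loading = Inf) {
  hand <- match.arg(hand)
  stopifnot(
    area > 0, loading_dust >= 0, loading_soil >= 0, max_loading >= 0,
    loading_dust + loading_soil <= max_loading
  )
  structure(
    list(
      hand = hand, area = area,
      loading_dust = loading_dust, loading_soil = loading_soil,
      max_loading = max_loading
    ),
    class = "hand_state"
  )
}

#' Total loading on a hand, mg/cm2
#' @param state A [hand_state()].
#' @return Numeric scalar.
#' @export
hand_loading <- function(state) {
  stopifnot(inherits(state, "hand_state"))
  state$loading_dust + state$loading_soil
}

#' @export
print.hand_state <- function(x, ...) {
  cat(sprintf(
    "<hand_state> %s hand, %.0f cm2: %.4g mg/cm2 (dust %.4g, soil %.4g), cap %.4g\n",
    x$hand, x$area, hand_loading(x), x$loading_dust, x$loading_soil,
    x$max_loading
  ))
  invisible(x)
}

#' Apply one dermal surface contact to a hand
#'
#' Net first-order transfer toward the surface loading:
#' `L' = clip(L + TF * f_SA * (L_surf - L), 0, L_max)`.
#' When the hand is cleaner than the surface this is one-way adherence; when
#' the hand is dirtier it off-loads back to the surface; at `L = L_surf` the
#' contact is at equilibrium. The contacted surface is treated as an
#' undepleted reservoir — its loading is sampled afresh at the next contact.
#' Mass gained is attributed to `medium`; mass lost is removed from both
#' components proportionally.
#'
#' @param state A [hand_state()].
#' @param surface_loading Surface/object loading, mg/cm2.
#' @param transfer_fraction Fraction of the loading difference moved (TF).
#' @param fraction_contact Fraction of the hand surface contacting (f_SA).
#' @param medium `"dust"` or `"soil"` — which component receives gained mass.
#' @return The updated `hand_state`.
#' @export
#' @examples
#' h <- hand_state("right", area = 150)
#' h <- dermal_contact_step(h, 0.01, 0.2, 0.5)
#' hand_loading(h) # 0.001 mg/cm2
dermal_contact_step <- function(state, surface_loading, transfer_fraction,
                                fraction_contact, medium = c("dust", "soil")) {
  stopifnot(
    inherits(state, "hand_state"),
    surface_loading >= 0,
    transfer_fraction >= 0, transfer_fraction <= 1,
    fraction_contact >= 0, fraction_contact <= 1
  )
  medium <- match.arg(medium)
  total <- hand_loading(state)
  delta <- transfer_fraction * fraction_contact * (surface_loading - total)
  if (delta >= 0) {
    # gain, capped at the saturation loading
    delta <- min(delta, state$max_loading - total)
    comp <- paste0("loading_", medium)
    state[[comp]] <- state[[comp]] + delta
  } else {
    # off-loading back to the surface, proportional across components
    loss <- min(-delta, total)
    if (total > 0) {
      state$loading_dust <- state$loading_dust * (1 - loss / total)
      state$loading_soil <- state$loading_soil * (1 - loss / total)
    }
  }
  state
}

#' Apply a handwash to a hand
#'
#' Both loading components are reduced by the removal efficiency:
#' `L' = L * (1 - efficiency)`.
#'
#' @param state A [hand_state()].
#' @param efficiency Removal efficiency in `[0, 1]`.
#' @return The updated `hand_state`.
#' @export
handwash_event <- function(state, efficiency) {
  stopifnot(
    inherits(state, "hand_state"),
    efficiency >= 0, efficiency <= 1
  )
  state$loading_dust <- state$loading_dust * (1 - efficiency)
  state$loading_soil <- state$loading_soil * (1 - efficiency)
  state
}

#' One instantaneous mouthing event
#'
#' Each mouthing is a discrete event occurring instantaneously on contact:
#' the ingested mass is `source_loading * mouthed_area * removal_efficiency`
#' (mg). For a hand source supply `source_area`; the hand's total mass then
#' decreases by exactly the ingested mass, spread uniformly over the whole
#' hand, so the residual loading is
#' `(source_loading * source_area - ingested) / source_area`. Object sources
#' are undepleted reservoirs: the residual loading equals the source loading.
#'
#' @param source_loading Loading on the mouthed source, mg/cm2.
#' @param mouthed_area Area mouthed, cm2; for a hand source must not exceed
#'   `source_area`.
#' @param removal_efficiency Fraction of loading on the mouthed area
#'   ingested, in `[0, 1]`.
#' @param source_area Total source area (cm2) for a depletable (hand)
#'   source; `NULL` for an undepleted object source.
#' @return List with `ingested_mg` and `residual_loading` (mg/cm2).
#' @export
#' @examples
#' mouthing_event(0.002, 10, 0.5) # 0.01 mg ingested
mouthing_event <- function(source_loading, mouthed_area, removal_efficiency,
                           source_area = NULL) {
  stopifnot(
    source_loading >= 0, mouthed_area >= 0,
    removal_efficiency >= 0, removal_efficiency <= 1
  )
  if (!is.null(source_area)) {
    stopifnot(source_area > 0)
    if (mouthed_area > source_area) {
      stop("mouthed area exceeds the source (hand) area")
    }
  }
  ingested <- source_loading * mouthed_area * removal_efficiency
  residual <- if (is.null(source_area)) {
    source_loading
  } else {
    (source_loading * source_area - ingested) / source_area
  }
  list(ingested_mg = ingested, residual_loading = residual)
}

#' Dose-algorithm inputs
#'
#' Bundles the terms of the dermal and ingestion dose algorithms with their
#' units. The conversion factor CF is the fixed constant `1e-6` kg/mg.
#'
#' @param C Contaminant concentration in the dust/soil, mg/kg.
#' @param SA Surface area available for contact, cm2/event.
#' @param AF Soil-to-skin adherence factor, mg/cm2.
#' @param ABS Absorption factor, unitless, in `[0, 1]`.
#' @param EF Exposure factor, unitless pass-through multiplier, in `[0, 1]`.
#' @param BW Body weight, kg (> 0).
#' @param IR Intake rate, mg/day.
#' @return A list of class `dose_inputs`.
#' @export
dose_inputs <- function(C, SA = NA_real_, AF = NA_real_, ABS = NA_real_,
                        EF = 1, BW, IR = NA_real_) {
  stopifnot(C >= 0, EF >= 0, EF <= 1)
  if (!is.finite(BW) || BW <= 0) stop("body weight must be positive")
  if (!is.na(ABS) && (ABS < 0 || ABS > 1)) stop("ABS must be in [0, 1]")
  structure(
    list(C = C, SA = SA, AF = AF, ABS = ABS, EF = EF, CF = 1e-6, BW = BW, IR = IR),
    class = "dose_inputs"
  )
}

#' Dermal absorbed dose algorithm
#'
#' `Dder = C * SA * AF * ABS * EF * CF / BW` in mg/kg/day, with
#' CF = 1e-6 kg/mg. At the all-ones input the dose is forced to 1e-6 by CF.
#'
#' @param inputs A [dose_inputs()] with `C`, `SA`, `AF`, `ABS`, `EF`, `BW`.
#' @return Dermal absorbed dose, mg/kg/day.
#' @export
#' @examples
#' dermal_absorbed_dose(dose_inputs(
#'   C = 250, SA = 400, AF = 0.2,
#'   ABS = 0.1, EF = 1, BW = 15
#' ))
dermal_absorbed_dose <- function(inputs) {
  stopifnot(inherits(inputs, "dose_inputs"))
  with(inputs, {
    if (anyNA(c(C, SA, AF, ABS, EF, BW))) {
      stop("dermal dose needs C, SA, AF, ABS, EF, BW")
    }
    C * SA * AF * ABS * EF * CF / BW
  })
}

#' Ingestion (exposure) dose algorithm
#'
#' `Ding = C * IR * EF * CF / BW` in mg/kg/day, with CF = 1e-6 kg/mg. The
#' intake rate IR (mg/day) is typically the simulated daily dust/soil
#' ingestion rate.
#'
#' @param inputs A [dose_inputs()] with `C`, `IR`, `EF`, `BW`.
#' @return Exposure dose, mg/kg/day.
#' @export
#' @examples
#' ingestion_dose(dose_inputs(C = 100, IR = 60, EF = 1, BW = 12))
ingestion_dose <- function(inputs) {
  stopifnot(inherits(inputs, "dose_inputs"))
  with(inputs, {
    if (anyNA(c(C, IR, EF, BW))) stop("ingestion dose needs C, IR, EF, BW")
    C * IR * EF * CF / BW
  })
}

#' Simulation configuration
#'
#' @param sub_contact_rate Sub-contacts per second for repetitive records.
#' @param outdoor_locations Location tokens mapped to the soil medium; all
#'   other locations are indoor/dust (unknown tokens warn once).
#' @param dominant_hand `NULL` (mouthed area split half per hand) or
#'   `"left"`/`"right"` (that hand supplies the whole mouthed area).
#' @param clock_tolerance Maximum relative mismatch between the three series'
#'   total durations (they are assumed to start simultaneously; small
#'   mismatches arise from videotape segment trimming).
#' @param direct_ingestion_mg_per_h Optional constant direct (e.g. pica or
#'   food-borne) ingestion term, off by default.
#' @param handwash_times_s Times (s) at which both hands are washed with a
#'   sampled handwash removal efficiency.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sub_contact_rate = 0.5,
                       outdoor_locations = c("Outdoor", "Yard", "Patio", "Porch"),
                       dominant_hand = NULL,
                       clock_tolerance = 0.02,
                       direct_ingestion_mg_per_h = 0,
                       handwash_times_s = numeric(0)) {
  stopifnot(
    sub_contact_rate > 0, clock_tolerance >= 0,
    direct_ingestion_mg_per_h >= 0
  )
  if (!is.null(dominant_hand)) {
    dominant_hand <- match.arg(dominant_hand, c("left", "right"))
  }
  structure(
    list(
      sub_contact_rate = sub_contact_rate,
      outdoor_locations = outdoor_locations,
      dominant_hand = dominant_hand,
      clock_tolerance = clock_tolerance,
      direct_ingestion_mg_per_h = direct_ingestion_mg_per_h,
      handwash_times_s = handwash_times_s
    ),
    class = "sim_config"
  )
}

# Draw one value from a named factor in the set.
draw1 <- function(fset, name) sample_factor(fset$distributions[[name]], 1)

# Surface loading distribution for an object in a location: soil when the
# location token is outdoor, else per-object override or the generic
# indoor distribution.
surface_loading_dist <- function(fset, object, outdoor) {
  if (outdoor) {
    return(fset$distributions$soil_loading_outdoor)
  }
  ov <- fset$surface_loading_by_object[[object]]
  if (!is.null(ov)) ov else fset$distributions$surface_dust_loading
}

#' Run one child's event-driven exposure simulation
#'
#' Merges the timed contact events of the three body-part series (two hands,
#' one mouth; sharing one clock from recording start) and walks them in time
#' order. Hand contacts with surfaces/objects update the hand's loading via
#' [dermal_contact_step()]; mouth contacts with the object `Hands` ingest
#' from the current hand loading (depleting the hands); mouth contacts with
#' other objects ingest `loading * mouthed_area * removal_efficiency` from an
#' undepleted reservoir. Each contact is an independent event: transfer
#' fraction, contact fraction, removal efficiency, mouthed area, and surface
#' loadings are sampled fresh per (sub-)contact, while hand area, body
#' weight, and the maximum hand loading are sampled once per child.
#' Repetitive records expand into sub-contacts at
#' `config$sub_contact_rate`. The medium is soil when the location token is
#' in `config$outdoor_locations`, dust otherwise. `Nothing` and `Not_In_View`
#' records elapse time without events, and hand-series records touching
#' `Mouth` are no-ops (the mouth series governs ingestion, avoiding double
#' counting).
#'
#' @param left_hand,right_hand,mouth [mlats_series()] objects for the three
#'   body parts (durations must agree within `config$clock_tolerance`).
#' @param factors A [factor_set()].
#' @param config A [sim_config()].
#' @param seed Optional integer; when given, seeds R's RNG for a
#'   reproducible run.
#' @return An object of class `child_sim_result`: `hand_loading` (time
#'   series data frame), `ledger` (per-event ingestion data frame with
#'   pathway and medium), `observed_s`, `ingested_mg` (by medium),
#'   `mg_per_h` (by medium), `child` (per-child factor draws), and
#'   `transferred_to_hands_mg` (total mass ever loaded onto the hands).
#' @export
run_child_simulation <- function(left_hand, right_hand, mouth, factors,
                                 config = sim_config(), seed = NULL) {
  stopifnot(
    inherits(left_hand, "mlats_series"), left_hand$body_part == "left_hand",
    inherits(right_hand, "mlats_series"), right_hand$body_part == "right_hand",
    inherits(mouth, "mlats_series"), mouth$body_part == "mouth",
    inherits(factors, "factor_set"), inherits(config, "sim_config")
  )
  if (!is.null(seed)) set.seed(seed)
  durs <- c(
    total_duration(left_hand), total_duration(right_hand),
    total_duration(mouth)
  )
  if (max(durs) > 0) {
    mismatch <- (max(durs) - min(durs)) / max(durs)
    if (mismatch > config$clock_tolerance) {
      stop(sprintf(
        "series clocks disagree: total durations %.1f/%.1f/%.1f s differ by %.1f%% (> %.1f%% tolerance)",
        durs[1], durs[2], durs[3], 100 * mismatch, 100 * config$clock_tolerance
      ))
    }
  }
  observed_s <- max(durs)

  # per-child draws
  child <- list(
    hand_area = draw1(factors, "hand_area"),
    body_weight = draw1(factors, "body_weight"),
    max_hand_loading = draw1(factors, "max_hand_loading")
  )
  hands <- list(
    left = hand_state("left", child$hand_area, max_loading = child$max_hand_loading),
    right = hand_state("right", child$hand_area, max_loading = child$max_hand_loading)
  )

  expand_subcontacts <- function(series, stream) {
    ev <- series_to_events(series, config$sub_contact_rate)
    if (nrow(ev) == 0) {
      return(NULL)
    }
    idx <- rep(seq_len(nrow(ev)), ev$sub_contact_count)
    off <- unlist(lapply(seq_len(nrow(ev)), function(i) {
      n <- ev$sub_contact_count[i]
      ev$start_s[i] + (seq_len(n) - 0.5) / n * ev$duration_s[i] * (n > 1)
    }))
    # constant records fire at record start; repetitive sub-contacts are
    # spread across the record
    t0 <- ifelse(ev$sub_contact_count[idx] > 1, off, ev$start_s[idx])
    data.frame(
      time_s = t0, stream = stream,
      location = ev$location[idx], object = ev$object_surface[idx],
      stringsAsFactors = FALSE
    )
  }

  events <- rbind(
    expand_subcontacts(left_hand, "left"),
    expand_subcontacts(right_hand, "right"),
    expand_subcontacts(mouth, "mouth")
  )
  if (length(config$handwash_times_s) > 0) {
    events <- rbind(events, data.frame(
      time_s = config$handwash_times_s, stream = "wash",
      location = "", object = "", stringsAsFactors = FALSE
    ))
  }
  pal <- default_palette()
  skip_tokens <- c(pal$no_contact_token, pal$not_in_view_token)

  # flat accumulators (per-event data frames are too slow in the hot loop)
  led_t <- numeric(0); led_path <- character(0)
  led_med <- character(0); led_mass <- numeric(0)
  tr_t <- numeric(0); tr_hand <- character(0)
  tr_dust <- numeric(0); tr_soil <- numeric(0)
  transferred <- 0

  add_ledger <- function(t, path, med, mass) {
    led_t[length(led_t) + 1] <<- t
    led_path[length(led_path) + 1] <<- path
    led_med[length(led_med) + 1] <<- med
    led_mass[length(led_mass) + 1] <<- mass
  }
  add_trace <- function(t, hn, h) {
    tr_t[length(tr_t) + 1] <<- t
    tr_hand[length(tr_hand) + 1] <<- hn
    tr_dust[length(tr_dust) + 1] <<- h$loading_dust
    tr_soil[length(tr_soil) + 1] <<- h$loading_soil
  }

  if (!is.null(events) && nrow(events) > 0) {
    ord <- order(events$time_s, match(events$stream, c("wash", "left", "right", "mouth")))
    ev_time <- events$time_s[ord]
    ev_stream <- events$stream[ord]
    ev_loc <- events$location[ord]
    ev_obj <- events$object[ord]
    ev_outdoor <- ev_loc %in% config$outdoor_locations
    for (i in seq_along(ev_time)) {
      stream <- ev_stream[i]
      if (stream == "wash") {
        eff <- draw1(factors, "handwash_removal_efficiency")
        hands$left <- handwash_event(hands$left, eff)
        hands$right <- handwash_event(hands$right, eff)
        add_trace(ev_time[i], "left", hands$left)
        add_trace(ev_time[i], "right", hands$right)
        next
      }
      obj <- ev_obj[i]
      if (obj %in% skip_tokens) next
      outdoor <- ev_outdoor[i]
      medium <- if (outdoor) "soil" else "dust"

      if (stream == "left" || stream == "right") {
        if (obj == "Mouth") next # ingestion is governed by the mouth series
        h <- hands[[stream]]
        before <- h$loading_dust + h$loading_soil
        ldist <- surface_loading_dist(factors, obj, outdoor)
        l_surf <- sample_factor(ldist, 1)
        tf <- draw1(factors, "transfer_fraction")
        fsa <- draw1(factors, "fraction_hand_contact")
        h <- dermal_contact_step(h, l_surf, tf, fsa, medium)
        gain <- h$loading_dust + h$loading_soil - before
        if (gain > 0) transferred <- transferred + gain * h$area
        hands[[stream]] <- h
        add_trace(ev_time[i], stream, h)
      } else { # mouth stream
        a_mouth <- draw1(factors, "mouthed_area")
        re <- draw1(factors, "mouthing_removal_efficiency")
        if (obj == "Hands") {
          shares <- if (is.null(config$dominant_hand)) {
            c(left = 0.5, right = 0.5)
          } else {
            stats::setNames(
              as.numeric(c("left", "right") == config$dominant_hand),
              c("left", "right")
            )
          }
          for (hn in names(shares)) {
            if (shares[[hn]] == 0) next
            h <- hands[[hn]]
            a_eff <- min(a_mouth * shares[[hn]], h$area)
            total <- h$loading_dust + h$loading_soil
            ev <- mouthing_event(total, a_eff, re, source_area = h$area)
            ing <- ev$ingested_mg
            if (total > 0 && ing > 0) {
              frac <- ing / (total * h$area) # fraction of hand mass removed
              ing_dust <- h$loading_dust * h$area * frac
              ing_soil <- h$loading_soil * h$area * frac
              h$loading_dust <- h$loading_dust * (1 - frac)
              h$loading_soil <- h$loading_soil * (1 - frac)
              hands[[hn]] <- h
              if (ing_dust > 0) {
                add_ledger(ev_time[i], "hand_to_mouth", "dust", ing_dust)
              }
              if (ing_soil > 0) {
                add_ledger(ev_time[i], "hand_to_mouth", "soil", ing_soil)
              }
              add_trace(ev_time[i], hn, h)
            }
          }
        } else {
          ldist <- surface_loading_dist(factors, obj, outdoor)
          l_obj <- sample_factor(ldist, 1)
          ev <- mouthing_event(l_obj, a_mouth, re)
          if (ev$ingested_mg > 0) {
            add_ledger(ev_time[i], "object_to_mouth", medium, ev$ingested_mg)
          }
        }
      }
    }
  }

  if (config$direct_ingestion_mg_per_h > 0 && observed_s > 0) {
    add_ledger(
      observed_s, "direct", "dust",
      config$direct_ingestion_mg_per_h * observed_s / 3600
    )
  }

  ledger <- data.frame(
    time_s = led_t, pathway = led_path, medium = led_med, mass_mg = led_mass,
    stringsAsFactors = FALSE
  )
  ledger <- ledger[order(ledger$time_s), ]
  rownames(ledger) <- NULL
  ledger$cumulative_mg <- cumsum(ledger$mass_mg)
  trace <- data.frame(
    time_s = tr_t, hand = tr_hand, loading_dust = tr_dust,
    loading_soil = tr_soil, loading = tr_dust + tr_soil,
    stringsAsFactors = FALSE
  )

  ingested <- c(
    dust = sum(ledger$mass_mg[ledger$medium == "dust"]),
    soil = sum(ledger$mass_mg[ledger$medium == "soil"])
  )
  mg_per_h <- if (observed_s > 0) ingested / (observed_s / 3600) else c(dust = NA_real_, soil = NA_real_)

  structure(
    list(
      hand_loading = trace, ledger = ledger, observed_s = observed_s,
      ingested_mg = ingested, mg_per_h = mg_per_h, child = child,
      transferred_to_hands_mg = transferred,
      final_hands = hands
    ),
    class = "child_sim_result"
  )
}

#' @export
print.child_sim_result <- function(x, ...) {
  cat(sprintf(
    "<child_sim_result> %.0f s observed; ingested %.4g mg dust, %.4g mg soil (%d ledger events)\n",
    x$observed_s, x$ingested_mg[["dust"]], x$ingested_mg[["soil"]],
    nrow(x$ledger)
  ))
  invisible(x)
}

#' Extrapolate observed ingestion to a daily rate
#'
#' Scales the observed hourly ingestion rate of each medium by the child's
#' active hours in that medium's setting from a time-activity profile:
#' `mg/day(dust) = mg/h(dust) * indoor_h` and
#' `mg/day(soil) = mg/h(soil) * outdoor_h`.
#'
#' @param result A [run_child_simulation()] result, or a ledger data frame
#'   (then `observed_s` is required).
#' @param profile List with `indoor_h` and `outdoor_h`, waking hours per day
#'   spent in each setting.
#' @param observed_s Observation duration in seconds when `result` is a bare
#'   ledger.
#' @return Named numeric: `dust`, `soil`, `total` (mg/day).
#' @export
extrapolate_daily_rate <- function(result, profile = list(indoor_h = 10, outdoor_h = 2),
                                   observed_s = NULL) {
  if (inherits(result, "child_sim_result")) {
    ledger <- result$ledger
    observed_s <- result$observed_s
  } else {
    ledger <- result
    if (is.null(observed_s)) stop("observed_s required with a bare ledger")
  }
  stopifnot(
    is.numeric(profile$indoor_h), profile$indoor_h >= 0,
    is.numeric(profile$outdoor_h), profile$outdoor_h >= 0
  )
  if (observed_s <= 0) stop("cannot extrapolate from zero observation time")
  hours <- observed_s / 3600
  dust_rate <- sum(ledger$mass_mg[ledger$medium == "dust"]) / hours
  soil_rate <- sum(ledger$mass_mg[ledger$medium == "soil"]) / hours
  out <- c(
    dust = dust_rate * profile$indoor_h,
    soil = soil_rate * profile$outdoor_h
  )
  c(out, total = sum(out))
}
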