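#' Configuration for the synthetic MLATS generator
#'
#' Defines a semi-Markov model of a child's sequential contact behavior:
#' a state set of (location, object) pairs, a transition matrix between
#' states, and a lognormal dwell-time distribution per state (geometric
#' mean seconds, geometric SD), truncated at 1 s so every record duration is
#' valid. The mouth series is generated by thinning: a background `Nothing`
#' stream into which hand-mouthing and object-mouthing events are inserted
#' at configured rates (events per hour) with their own dwell distribution.
#'
#' @param states Data frame with columns `location`, `object` (one row per
#'   state).
#' @param transition Square matrix, `transition[i, j]` = probability of
#'   moving from state i to state j; rows must sum to 1.
#' @param dwell_gm_s,dwell_gsd Dwell-time geometric means (s) and geometric
#'   SDs, recycled across states.
#' @param p_repetitive Probability a record is `repetitive` rather than
#'   `constant`.
#' @param hand_mouth_per_h,object_mouth_per_h Mouthing event rates, events
#'   per hour.
#' @param mouth_objects Object tokens mouthed during object-mouthing events
#'   (sampled uniformly).
#' @param mouth_dwell_gm_s,mouth_dwell_gsd Mouthing dwell distribution.
#' @param total_s Total observed duration, seconds (> 0).
#' @param child_id Identifier stamped on the generated series.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(states = data.frame(
                           location = c("Bedroom", "Bedroom", "Kitchen", "Living_Room"),
                           object = c("Hard_Toy", "Nothing", "Floor", "Electronics"),
                           stringsAsFactors = FALSE
                         ),
                         transition = NULL,
                         dwell_gm_s = 15, dwell_gsd = 2.5,
                         p_repetitive = 0.15,
                         hand_mouth_per_h = 12, object_mouth_per_h = 8,
                         mouth_objects = c("Hard_Toy", "Pacifier", "Clothing"),
                         mouth_dwell_gm_s = 3, mouth_dwell_gsd = 2,
                         total_s = 3600, child_id = "synthetic") {
  n <- nrow(states)
  stopifnot(
    n >= 1, all(c("location", "object") %in% names(states)),
    total_s > 0, p_repetitive >= 0, p_repetitive <= 1,
    hand_mouth_per_h >= 0, object_mouth_per_h >= 0,
    all(dwell_gm_s > 0), all(dwell_gsd >= 1),
    mouth_dwell_gm_s > 0, mouth_dwell_gsd >= 1
  )
  if (is.null(transition)) {
    transition <- matrix(1 / n, n, n)
  }
  transition <- as.matrix(transition)
  stopifnot(nrow(transition) == n, ncol(transition) == n, all(transition >= 0))
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  structure(
    list(
      states = states, transition = transition,
      dwell_gm_s = rep_len(dwell_gm_s, n), dwell_gsd = rep_len(dwell_gsd, n),
      p_repetitive = p_repetitive,
      hand_mouth_per_h = hand_mouth_per_h,
      object_mouth_per_h = object_mouth_per_h,
      mouth_objects = mouth_objects,
      mouth_dwell_gm_s = mouth_dwell_gm_s, mouth_dwell_gsd = mouth_dwell_gsd,
      total_s = total_s, child_id = child_id
    ),
    class = "synth_config"
  )
}

# Deterministic substream seed derivation (Knuth multiplicative hash),
# kept within the 32-bit signed-integer range R requires of set.seed().
substream_seed <- function(master_seed, stream_index) {
  as.integer((as.numeric(master_seed) * 2654435761 + stream_index * 97003) %% 2147483647)
}

rlnorm_dwell <- function(n, gm, gsd, min_s = 1) {
  if (gsd <= 1) {
    return(pmax(rep(gm, n), min_s))
  }
  pmax(stats::rlnorm(n, meanlog = log(gm), sdlog = log(gsd)), min_s)
}

generate_hand_series <- function(config, body_part) {
  n_states <- nrow(config$states)
  state <- sample.int(n_states, 1)
  t <- 0
  cap <- 64L
  states_seq <- integer(cap)
  dwells <- numeric(cap)
  k <- 0L
  while (t < config$total_s) {
    dwell <- rlnorm_dwell(1, config$dwell_gm_s[state], config$dwell_gsd[state])
    dwell <- min(dwell, config$total_s - t) # clip the last record to the window
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(states_seq) <- cap
      length(dwells) <- cap
    }
    states_seq[k] <- state
    dwells[k] <- dwell
    t <- t + dwell
    state <- sample.int(n_states, 1, prob = config$transition[state, ])
  }
  states_seq <- states_seq[seq_len(k)]
  dwells <- dwells[seq_len(k)]
  records <- data.frame(
    activity_type = ifelse(
      stats::runif(k) < config$p_repetitive, "repetitive", "constant"
    ),
    location = config$states$location[states_seq],
    object_surface = config$states$object[states_seq],
    duration_s = dwells, stringsAsFactors = FALSE
  )
  mlats_series(records, body_part, config$child_id)
}

generate_mouth_series <- function(config) {
  total <- config$total_s
  rate_per_s <- (config$hand_mouth_per_h + config$object_mouth_per_h) / 3600
  events <- list() # (time, object)
  if (rate_per_s > 0) {
    t <- stats::rexp(1, rate_per_s)
    p_hand <- config$hand_mouth_per_h /
      (config$hand_mouth_per_h + config$object_mouth_per_h)
    while (t < total) {
      obj <- if (stats::runif(1) < p_hand) {
        "Hands"
      } else {
        sample(config$mouth_objects, 1)
      }
      events[[length(events) + 1]] <- list(time = t, object = obj)
      t <- t + stats::rexp(1, rate_per_s)
    }
  }
  loc0 <- config$states$location[1]
  rows <- list()
  t <- 0
  for (ev in events) {
    dwell <- rlnorm_dwell(1, config$mouth_dwell_gm_s, config$mouth_dwell_gsd)
    if (ev$time > t) {
      rows[[length(rows) + 1]] <- data.frame(
        activity_type = "constant", location = loc0,
        object_surface = "Nothing", duration_s = ev$time - t,
        stringsAsFactors = FALSE
      )
      t <- ev$time
    }
    dwell <- min(dwell, total - t)
    if (dwell <= 0) break
    rows[[length(rows) + 1]] <- data.frame(
      activity_type = "constant", location = loc0,
      object_surface = ev$object, duration_s = dwell,
      stringsAsFactors = FALSE
    )
    t <- t + dwell
  }
  if (t < total) {
    rows[[length(rows) + 1]] <- data.frame(
      activity_type = "constant", location = loc0,
      object_surface = "Nothing", duration_s = total - t,
      stringsAsFactors = FALSE
    )
  }
  recs <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  mlats_series(recs, "mouth", config$child_id)
}

#' Generate synthetic MLATS series for the three body parts
#'
#' Realizes the semi-Markov activity model of a [synth_config()] for the
#' left hand, right hand, and mouth, sharing one clock (all series start at
#' t = 0 and cover exactly `total_s` seconds). Randomness flows from the one
#' `seed` through documented per-body-part substreams, so regenerating one
#' body part cannot perturb the others and an identical seed yields
#' byte-identical series.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed.
#' @return Named list of [mlats_series()]: `left_hand`, `right_hand`,
#'   `mouth`.
#' @export
#' @examples
#' s <- generate_mlats(synth_config(total_s = 600), seed = 1)
#' total_duration(s$mouth)
generate_mlats <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  out <- list()
  set.seed(substream_seed(seed, 1))
  out$left_hand <- generate_hand_series(config, "left_hand")
  set.seed(substream_seed(seed, 2))
  out$right_hand <- generate_hand_series(config, "right_hand")
  set.seed(substream_seed(seed, 3))
  out$mouth <- generate_mouth_series(config)
  out
}

#' Generate a Coulter-style particle-size-bin fixture for a target mass
#'
#' Constructs a synthetic particle-count table over log-spaced diameter bins
#' (lognormal number-weighted size distribution), scaled so that the
#' volumetric mass computation — total particle volume from bin counts,
#' scaled from the analyzed aliquot to the full rinse, multiplied by the
#' particle density — recovers `target_mass_g` to within `tolerance`
#' (relative). After rounding counts to integers, the count of the bin
#' contributing the most volume is adjusted to restore the target within
#' tolerance. This emulates a laboratory control spike (a fixed dust mass
#' added to a rinse bag) analyzed on a particle counter.
#'
#' @param target_mass_g Spiked dust mass, g (>= 0).
#' @param density_g_cm3 Particle density, g/cm3 (> 0).
#' @param psd_gm_um,psd_gsd Number-weighted lognormal size-distribution
#'   parameters: geometric-mean diameter (micrometres) and geometric SD.
#' @param n_bins Number of diameter bins.
#' @param d_range_um Diameter range covered by the bins, micrometres.
#' @param rinse_mL Total rinse volume, mL.
#' @param aliquot_mL Analyzed aliquot volume, mL (<= `rinse_mL`).
#' @param tolerance Relative mass-recovery tolerance.
#' @param seed Optional integer seed (the construction is deterministic;
#'   the seed only fixes the RNG state for API symmetry).
#' @return A list of class `coulter_fixture` with `bin_edges_um`,
#'   `bin_mid_um` (geometric-mean midpoints), `counts` (integer),
#'   `raw_counts` (pre-rounding), `aliquot_mL`, `rinse_mL`,
#'   `density_g_cm3`, `target_mass_g`.
#' @export
#' @examples
#' fx <- generate_coulter_fixture(0.01, 2.65)
#' volumetric_mass(coulter_total_volume(fx), fx$density_g_cm3)
generate_coulter_fixture <- function(target_mass_g, density_g_cm3,
                                     psd_gm_um = 20, psd_gsd = 2,
                                     n_bins = 30, d_range_um = c(1, 200),
                                     rinse_mL = 150, aliquot_mL = 1,
                                     tolerance = 0.01, seed = NULL) {
  stopifnot(
    target_mass_g >= 0, density_g_cm3 > 0, psd_gm_um > 0, psd_gsd >= 1,
    n_bins >= 1, length(d_range_um) == 2, d_range_um[1] > 0,
    d_range_um[2] > d_range_um[1], rinse_mL >= aliquot_mL, aliquot_mL > 0,
    tolerance > 0
  )
  if (!is.null(seed)) set.seed(seed)
  edges <- exp(seq(log(d_range_um[1]), log(d_range_um[2]), length.out = n_bins + 1))
  mid <- sqrt(edges[-1] * edges[-(n_bins + 1)]) # geometric-mean midpoints
  # relative number of particles per bin from the lognormal number PSD
  lp <- stats::plnorm(edges, meanlog = log(psd_gm_um), sdlog = log(psd_gsd))
  rel <- diff(lp)
  if (all(rel == 0)) rel <- rep(1, n_bins)
  # volume per particle in cm^3 (d in um -> cm: 1e-4)
  vol1 <- (pi / 6) * (mid * 1e-4)^3
  # mass recovered per unit of 'rel': aliquot counts scaled to full rinse
  mass_per_unit <- sum(rel * vol1) * (rinse_mL / aliquot_mL) * density_g_cm3
  if (target_mass_g == 0) {
    raw <- rep(0, n_bins)
  } else {
    if (mass_per_unit <= 0) stop("unattainable target: bins carry no volume")
    raw <- rel * (target_mass_g / mass_per_unit)
  }
  # integer counts: floor never overshoots, then greedy top-up from the
  # largest-particle bins down leaves a residual below the finest bin's
  # per-particle mass
  counts <- floor(raw)
  if (target_mass_g > 0) {
    step_mass <- vol1 * (rinse_mL / aliquot_mL) * density_g_cm3
    residual <- target_mass_g - sum(counts * step_mass)
    for (k in order(step_mass, decreasing = TRUE)) {
      add <- floor(residual / step_mass[k])
      if (add > 0) {
        counts[k] <- counts[k] + add
        residual <- residual - add * step_mass[k]
      }
    }
    err <- abs(target_mass_g - sum(counts * step_mass)) / target_mass_g
    if (err > tolerance) {
      stop(sprintf(
        "fixture cannot hit target within %.2g%% (achieved %.2g%%); use more/finer bins",
        100 * tolerance, 100 * err
      ))
    }
  }
  fx <- structure(
    list(
      bin_edges_um = edges, bin_mid_um = mid, counts = counts,
      raw_counts = raw, aliquot_mL = aliquot_mL, rinse_mL = rinse_mL,
      density_g_cm3 = density_g_cm3, target_mass_g = target_mass_g
    ),
    class = "coulter_fixture"
  )
  fx
}

#' @export
print.coulter_fixture <- function(x, ...) {
  cat(sprintf(
    "<coulter_fixture> %d bins [%.3g, %.3g] um, %d particles in %.3g mL aliquot of %.3g mL rinse; target %.4g g at %.3g g/cm3\n",
    length(x$counts), min(x$bin_edges_um), max(x$bin_edges_um),
    sum(x$counts), x$aliquot_mL, x$rinse_mL, x$target_mass_g, x$density_g_cm3
  ))
  invisible(x)
}

#' Write or read a Coulter bin table as CSV
#'
#' Columns: `bin_lo_um`, `bin_hi_um`, `bin_mid_um`, `count`; metadata
#' (aliquot, rinse, density, target) stored in `#`-prefixed header comments.
#'
#' @param fixture A [generate_coulter_fixture()] result.
#' @param path CSV path.
#' @return `write_coulter_csv()` returns `path` invisibly;
#'   `read_coulter_csv()` returns a `coulter_fixture`.
#' @export
write_coulter_csv <- function(fixture, path) {
  stopifnot(inherits(fixture, "coulter_fixture"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# aliquot_mL=%g rinse_mL=%g density_g_cm3=%g target_mass_g=%g",
    fixture$aliquot_mL, fixture$rinse_mL, fixture$density_g_cm3,
    fixture$target_mass_g
  ), con)
  n <- length(fixture$counts)
  utils::write.csv(data.frame(
    bin_lo_um = fixture$bin_edges_um[-(n + 1)],
    bin_hi_um = fixture$bin_edges_um[-1],
    bin_mid_um = fixture$bin_mid_um,
    count = fixture$counts
  ), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coulter_csv
#' @export
read_coulter_csv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- list(aliquot_mL = 1, rinse_mL = 150, density_g_cm3 = NA, target_mass_g = NA)
  if (startsWith(header, "#")) {
    kv <- regmatches(header, gregexpr("[a-zA-Z0-9_]+=[0-9.eE+-]+", header))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- as.numeric(parts[2])
    }
  }
  tab <- utils::read.csv(path, comment.char = "#")
  structure(
    list(
      bin_edges_um = c(tab$bin_lo_um, tab$bin_hi_um[nrow(tab)]),
      bin_mid_um = tab$bin_mid_um, counts = tab$count,
      raw_counts = tab$count, aliquot_mL = meta$aliquot_mL,
      rinse_mL = meta$rinse_mL, density_g_cm3 = meta$density_g_cm3,
      target_mass_g = meta$target_mass_g
    ),
    class = "coulter_fixture"
  )
}
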