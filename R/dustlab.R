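#' Density of air-free water by temperature
#'
#' Eleven-point handbook table over 10-35 degrees C (2.5-degree steps,
#' g/mL), linearly interpolated. Used for pycnometer calibration and the
#' water-displacement density computation.
#'
#' @param temp_c Temperature, degrees C, within \[10, 35\].
#' @return Water density, g/mL.
#' @export
#' @examples
#' water_density(20) # ~0.99820
water_density <- function(temp_c) {
  tab_t <- seq(10, 35, by = 2.5)
  tab_rho <- c(
    0.9996996, 0.9994388, 0.9990996, 0.9986866, 0.9982041, 0.9976558,
    0.9970449, 0.9963745, 0.9956473, 0.9948656, 0.9940319
  )
  if (any(!is.finite(temp_c)) || any(temp_c < 10) || any(temp_c > 35)) {
    stop("temperature outside the 10-35 degree C water-density table")
  }
  stats::approx(tab_t, tab_rho, xout = temp_c)$y
}

#' Gravimetric dust mass by weighing difference
#'
#' Mass is the post-sampling weight minus the pre-sampling weight of the
#' wipe or vacuum sock. The detection limit defaults to 0.3 mg (three times
#' the 0.1 mg scale sensitivity). Differences below the detection limit are
#' flagged (such samples are routed to the volumetric method); small negative
#' differences within `-detection_limit` are weighing noise and reported as
#' 0 mg with the flag, while more negative differences indicate a weighing
#' blunder and are an error.
#'
#' @param pre_mg,post_mg Pre- and post-sampling masses, mg.
#' @param detection_limit_mg Detection limit, mg.
#' @return List with `mass_mg` and `below_detection` (logical).
#' @export
#' @examples
#' gravimetric_mass(250.0, 253.2)
gravimetric_mass <- function(pre_mg, post_mg, detection_limit_mg = 0.3) {
  stopifnot(pre_mg >= 0, post_mg >= 0, detection_limit_mg >= 0)
  diff <- post_mg - pre_mg
  if (diff < -detection_limit_mg) {
    stop(sprintf(
      "post mass is %.4g mg below pre mass (beyond -%.4g mg): weighing blunder",
      -diff, detection_limit_mg
    ))
  }
  if (diff < detection_limit_mg) {
    list(mass_mg = max(diff, 0), below_detection = TRUE)
  } else {
    list(mass_mg = diff, below_detection = FALSE)
  }
}

#' Stencil areas used for surface wiping
#'
#' The four fixed stencil sizes, chosen per sampling location as the largest
#' that fits: 25 x 25, 25 x 15, 25 x 10, and 25 x 5 cm.
#'
#' @param dims Character like `"25x25"`, or a length-2 numeric (cm).
#' @return Area, cm2.
#' @export
stencil_area <- function(dims) {
  if (is.character(dims)) {
    allowed <- c("25x25" = 625, "25x15" = 375, "25x10" = 250, "25x5" = 125)
    key <- gsub("[[:space:]]", "", tolower(dims))
    if (!key %in% names(allowed)) {
      stop(
        "unknown stencil '", dims, "'; expected one of ",
        paste(names(allowed), collapse = ", ")
      )
    }
    unname(allowed[key])
  } else {
    stopifnot(is.numeric(dims), length(dims) == 2, all(dims > 0))
    prod(dims)
  }
}

#' Surface loading from mass and area
#'
#' All mass measurements are normalized by the sampled surface area
#' (stencil area for wipes, traced palmar area for hand rinses).
#'
#' @param mass_mg Collected mass, mg (>= 0).
#' @param area_cm2 Sampled area, cm2 (> 0).
#' @return Loading, mg/cm2.
#' @export
#' @examples
#' surface_loading(3.2, stencil_area("25x25"))
surface_loading <- function(mass_mg, area_cm2) {
  stopifnot(mass_mg >= 0)
  if (!is.finite(area_cm2) || area_cm2 <= 0) {
    stop("area must be positive")
  }
  mass_mg / area_cm2
}

#' Total particle volume from Coulter-style size-bin counts
#'
#' Particles in each diameter bin are treated as spheres at the bin midpoint
#' diameter: `V = (rinse/aliquot) * sum_i count_i * (pi/6) * d_i^3`, with
#' diameters converted micrometres to cm. The aliquot-to-rinse ratio scales
#' the counts observed in the analyzed aliquot up to the full rinse volume.
#' When bin edges rather than midpoints are supplied, midpoints are the
#' geometric means of adjacent edges (log-scaled sizing convention).
#'
#' @param sample A `coulter_fixture`, or a list with `counts` and either
#'   `bin_mid_um` or `bin_edges_um`, plus `aliquot_mL` and `rinse_mL`.
#' @return Total particle volume in the full rinse, cm3.
#' @export
#' @examples
#' coulter_total_volume(list(
#'   bin_mid_um = 10, counts = 1000,
#'   aliquot_mL = 1, rinse_mL = 1
#' ))
coulter_total_volume <- function(sample) {
  counts <- sample$counts
  stopifnot(all(counts >= 0))
  mid <- sample$bin_mid_um
  if (is.null(mid)) {
    edges <- sample$bin_edges_um
    if (is.null(edges)) stop("sample needs bin_mid_um or bin_edges_um")
    stopifnot(all(diff(edges) > 0), length(edges) == length(counts) + 1)
    mid <- sqrt(edges[-1] * edges[-length(edges)])
  }
  stopifnot(length(mid) == length(counts), all(mid > 0))
  aliquot <- if (is.null(sample$aliquot_mL)) 1 else sample$aliquot_mL
  rinse <- if (is.null(sample$rinse_mL)) aliquot else sample$rinse_mL
  stopifnot(aliquot > 0, rinse >= aliquot)
  (rinse / aliquot) * sum(counts * (pi / 6) * (mid * 1e-4)^3)
}

#' Volumetric mass: M = V x rho
#'
#' Converts a total particle volume to mass using the measured particle
#' density. This is the quantification route for samples below the
#' gravimetric detection limit (hand rinses and faint surface wipes).
#'
#' @param volume_cm3 Total particle volume, cm3 (>= 0).
#' @param density_g_cm3 Particle density, g/cm3; an `NA` density (no
#'   matched vacuum sample for the home) is an error directing the caller
#'   to a configured default.
#' @return Mass, g.
#' @export
#' @examples
#' volumetric_mass(5.236e-7, 2.65)
volumetric_mass <- function(volume_cm3, density_g_cm3) {
  stopifnot(volume_cm3 >= 0)
  if (is.na(density_g_cm3)) {
    stop(
      "no particle density available (no matched vacuum sample); ",
      "supply a configured default density"
    )
  }
  stopifnot(density_g_cm3 >= 0)
  volume_cm3 * density_g_cm3
}

#' Calibrate a pycnometer's volume from water-fill replicates
#'
#' Each calibration run fills the vessel with de-oxygenized water and weighs
#' it; the run's volume is the water mass divided by the water density at
#' the recorded temperature. (Dividing by density is the dimensionally
#' consistent reading of the standard mass-to-volume conversion.) The
#' calibrated volume is the mean over replicates (nominally 10).
#'
#' @param empty_g,filled_g Vessel masses empty and water-filled, g
#'   (vectors, one element per run).
#' @param temp_c Water temperature per run, degrees C, within \[10, 35\].
#' @return Calibrated volume, mL.
#' @export
#' @examples
#' pycnometer_volume(10.0000, 11.0021, 20)
pycnometer_volume <- function(empty_g, filled_g, temp_c) {
  stopifnot(
    length(empty_g) == length(filled_g),
    length(temp_c) %in% c(1, length(empty_g)),
    length(empty_g) >= 1, all(filled_g > empty_g)
  )
  rho <- water_density(temp_c)
  mean((filled_g - empty_g) / rho)
}

#' Particle density by pycnometer water displacement
#'
#' A known dust mass is placed in a calibrated vessel which is then topped
#' up with water. The water volume is the added water mass divided by the
#' water density at temperature; the dust volume is the calibrated vessel
#' volume minus the water volume; density is dust mass over dust volume.
#' Replicate runs (up to three per home, mass permitting) are averaged.
#'
#' @param runs A data frame (or list coercible to one) with one row per run
#'   and columns `empty_g` (empty vessel mass), `dust_g` (dust mass),
#'   `filled_g` (vessel + dust + water mass), `temp_c`, and
#'   `volume_mL` (calibrated vessel volume).
#' @return List with `density_g_cm3` (mean over runs) and `per_run`
#'   densities.
#' @export
#' @examples
#' dust_density(data.frame(
#'   empty_g = 10, dust_g = 0.5, filled_g = 10 + 0.5 + 0.8113,
#'   temp_c = 20, volume_mL = 1
#' ))
dust_density <- function(runs) {
  runs <- as.data.frame(runs)
  needed <- c("empty_g", "dust_g", "filled_g", "temp_c", "volume_mL")
  stopifnot(all(needed %in% names(runs)), nrow(runs) >= 1)
  per_run <- vapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    if (r$dust_g <= 0) stop("run ", i, ": dust mass must be positive")
    water_g <- r$filled_g - r$empty_g - r$dust_g
    if (water_g < 0) stop("run ", i, ": filled mass less than empty + dust")
    water_mL <- water_g / water_density(r$temp_c)
    dust_mL <- r$volume_mL - water_mL
    if (dust_mL <= 0) {
      stop("run ", i, ": computed dust volume is non-positive")
    }
    r$dust_g / dust_mL
  }, numeric(1))
  list(density_g_cm3 = mean(per_run), per_run = per_run)
}

#' Palmar hand area from 1 cm2 grid tracings
#'
#' Children's hands are traced onto 1 cm2 ruled paper; the digitized trace
#' is a binary grid mask per hand, and the palmar area is the number of
#' filled cells (x 1 cm2), summed over the supplied hands.
#'
#' @param ... One binary matrix (0/1 or logical) per traced hand, or a
#'   single list of such matrices.
#' @return Area, cm2.
#' @export
#' @examples
#' hand_area_from_trace(matrix(1, 8, 10), matrix(1, 8, 10))
hand_area_from_trace <- function(...) {
  masks <- list(...)
  if (length(masks) == 1 && is.list(masks[[1]]) && !is.matrix(masks[[1]])) {
    masks <- masks[[1]]
  }
  if (length(masks) == 0) stop("at least one hand mask is required")
  cells <- vapply(masks, function(m) {
    m <- as.matrix(m)
    v <- as.numeric(m)
    if (!all(v %in% c(0, 1))) stop("hand mask must be binary (0/1)")
    sum(v)
  }, numeric(1))
  if (any(cells == 0)) stop("a traced hand mask has no filled cells")
  sum(cells)
}

#' Read a hand-trace mask from a plain-text grid or CSV
#'
#' Accepts a CSV of 0/1 cells or a text grid of `0`/`1` (or `.`/`#`)
#' characters, one row per line.
#'
#' @param path File path.
#' @return Binary matrix.
#' @export
read_hand_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (any(grepl(",", lines, fixed = TRUE))) {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    chars <- strsplit(gsub("[[:space:]]", "", lines), "")
    m <- do.call(rbind, lapply(chars, function(ch) {
      as.numeric(ch %in% c("1", "#"))
    }))
  }
  storage.mode(m) <- "numeric"
  m
}

#' Hand dust loading gained between pre- and post-activity rinses
#'
#' The pre-rinse (after a supervised handwash) establishes the clean-hands
#' baseline; the post-rinse after the observation session measures what
#' accumulated. Both rinses are quantified volumetrically, and the gained
#' loading is `(M_post - M_pre) / area` in mg/cm2. A negative gain
#' (post below pre) is floored at 0 and flagged.
#'
#' @param pre,post `coulter_fixture`-like volumetric samples (see
#'   [coulter_total_volume()]); both use `density_g_cm3` from `pre` unless
#'   each carries its own.
#' @param area_cm2 Traced palmar area of both hands, cm2 (> 0).
#' @param density_g_cm3 Particle density applied to both rinses; defaults
#'   to the density carried by the samples.
#' @return List with `loading_mg_cm2`, `gained_mg`, `negative_gain`
#'   (logical).
#' @export
hand_rinse_loading <- function(pre, post, area_cm2, density_g_cm3 = NULL) {
  if (!is.finite(area_cm2) || area_cm2 <= 0) stop("area must be positive")
  rho_pre <- if (!is.null(density_g_cm3)) density_g_cm3 else pre$density_g_cm3
  rho_post <- if (!is.null(density_g_cm3)) density_g_cm3 else post$density_g_cm3
  m_pre_mg <- volumetric_mass(coulter_total_volume(pre), rho_pre) * 1000
  m_post_mg <- volumetric_mass(coulter_total_volume(post), rho_post) * 1000
  gained <- m_post_mg - m_pre_mg
  negative <- gained < 0
  if (negative) gained <- 0
  list(
    loading_mg_cm2 = gained / area_cm2,
    gained_mg = gained,
    negative_gain = negative
  )
}
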