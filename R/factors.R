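#' Exposure-factor distribution
#'
#' A named parametric distribution for one exposure factor, with units and an
#' explicit support (truncation bounds). Supported kinds:
#'
#' * `point`: `value`
#' * `uniform`: `min`, `max`
#' * `triangular`: `min`, `mode`, `max`
#' * `normal`: `mean`, `sd`
#' * `lognormal`: `gm` (geometric mean), `gsd` (geometric standard
#'   deviation) — the exposure-science convention; `meanlog = log(gm)`,
#'   `sdlog = log(gsd)`
#' * `empirical`: `values` (resampled with replacement, optional `weights`)
#'
#' Truncation to `support` is by rejection sampling (never clipping, which
#' would pile probability mass at the bounds), with a retry cap.
#'
#' @param name Factor name.
#' @param kind Distribution kind (see above).
#' @param parameters Named list of parameters for the kind.
#' @param units Unit string, e.g. `"mg/cm2"`; `"unitless"` allowed.
#' @param support Length-2 numeric, lower/upper truncation bounds
#'   (may be infinite).
#' @return An object of class `factor_dist`.
#' @export
#' @examples
#' tf <- factor_dist("transfer_fraction", "uniform",
#'   list(min = 0.1, max = 0.4),
#'   units = "unitless", support = c(0, 1)
#' )
#' sample_factor(tf, 3)
factor_dist <- function(name, kind = c(
                          "point", "uniform", "triangular",
                          "normal", "lognormal", "empirical"
                        ),
                        parameters, units, support = c(-Inf, Inf)) {
  kind <- match.arg(kind)
  stopifnot(
    is.character(name), nzchar(name),
    is.character(units), nzchar(units),
    is.numeric(support), length(support) == 2, support[1] <= support[2]
  )
  p <- parameters
  ok <- switch(kind,
    point = is.numeric(p$value),
    uniform = is.numeric(p$min) && is.numeric(p$max) && p$min <= p$max,
    triangular = is.numeric(p$min) && is.numeric(p$mode) && is.numeric(p$max) &&
      p$min <= p$mode && p$mode <= p$max,
    normal = is.numeric(p$mean) && is.numeric(p$sd) && p$sd >= 0,
    lognormal = is.numeric(p$gm) && is.numeric(p$gsd) && p$gm > 0 && p$gsd >= 1,
    empirical = is.numeric(p$values) && length(p$values) > 0
  )
  if (!isTRUE(ok)) {
    stop("invalid parameters for ", kind, " distribution '", name, "'")
  }
  structure(
    list(
      name = name, kind = kind, parameters = p, units = units,
      support = as.numeric(support)
    ),
    class = "factor_dist"
  )
}

#' @export
print.factor_dist <- function(x, ...) {
  ps <- paste(names(x$parameters),
    vapply(x$parameters, function(v) paste(format(v), collapse = ","), ""),
    sep = "=", collapse = ", "
  )
  cat(sprintf(
    "<factor_dist> %s ~ %s(%s) [%s], support [%g, %g]\n",
    x$name, x$kind, ps, x$units, x$support[1], x$support[2]
  ))
  invisible(x)
}

draw_raw <- function(dist, n) {
  p <- dist$parameters
  switch(dist$kind,
    point = rep(p$value, n),
    uniform = stats::runif(n, p$min, p$max),
    triangular = {
      # inverse-CDF sampling of the triangular distribution
      u <- stats::runif(n)
      fc <- if (p$max > p$min) (p$mode - p$min) / (p$max - p$min) else 0
      lo <- u < fc
      out <- numeric(n)
      out[lo] <- p$min + sqrt(u[lo] * (p$max - p$min) * (p$mode - p$min))
      out[!lo] <- p$max - sqrt((1 - u[!lo]) * (p$max - p$min) * (p$max - p$mode))
      out
    },
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, meanlog = log(p$gm), sdlog = log(p$gsd)),
    empirical = {
      w <- p$weights
      sample(p$values, n, replace = TRUE, prob = w)
    }
  )
}

#' Sample from an exposure-factor distribution
#'
#' Draws using R's current random-number stream (seed with [set.seed()] for
#' reproducibility). Values outside the support are rejected and redrawn, up
#' to `max_retries` rounds; exceeding the cap (a pathological truncation,
#' e.g. a support that excludes virtually all the mass) is an error.
#'
#' @param dist A [factor_dist()].
#' @param n Number of draws.
#' @param max_retries Rejection-round cap.
#' @return Numeric vector of length `n`, all values within the support.
#' @export
sample_factor <- function(dist, n = 1, max_retries = 1e4) {
  stopifnot(inherits(dist, "factor_dist"), n >= 0)
  if (n == 0) return(numeric(0))
  lo <- dist$support[1]
  hi <- dist$support[2]
  if (dist$kind == "point") {
    v <- dist$parameters$value
    if (v < lo || v > hi) stop("point value outside support for '", dist$name, "'")
    return(rep(v, n))
  }
  out <- draw_raw(dist, n)
  bad <- which(out < lo | out > hi)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > max_retries) {
      stop(
        "rejection sampling for '", dist$name,
        "' exceeded retry cap; support may exclude nearly all mass"
      )
    }
    out[bad] <- draw_raw(dist, length(bad))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Mean of an exposure-factor distribution (before truncation)
#'
#' Closed-form mean of the untruncated distribution; used by tests comparing
#' Monte Carlo output with products of factor means.
#'
#' @param dist A [factor_dist()].
#' @return Numeric scalar.
#' @export
factor_mean <- function(dist) {
  stopifnot(inherits(dist, "factor_dist"))
  p <- dist$parameters
  switch(dist$kind,
    point = p$value,
    uniform = (p$min + p$max) / 2,
    triangular = (p$min + p$mode + p$max) / 3,
    normal = p$mean,
    lognormal = p$gm * exp(log(p$gsd)^2 / 2),
    empirical = {
      w <- p$weights
      if (is.null(w)) mean(p$values) else sum(p$values * w) / sum(w)
    }
  )
}

# Registry of the factors a child simulation requires: expected units and
# the widest admissible support. Fractions must live in [0, 1].
factor_registry <- function() {
  data.frame(
    name = c(
      "surface_dust_loading", "soil_loading_outdoor", "transfer_fraction",
      "fraction_hand_contact", "hand_area", "mouthed_area",
      "mouthing_removal_efficiency", "max_hand_loading",
      "handwash_removal_efficiency", "body_weight",
      "contaminant_concentration", "exposure_factor", "absorption_fraction",
      "soil_skin_adherence", "surface_area_contact"
    ),
    units = c(
      "mg/cm2", "mg/cm2", "unitless", "unitless", "cm2", "cm2",
      "unitless", "mg/cm2", "unitless", "kg", "mg/kg", "unitless",
      "unitless", "mg/cm2", "cm2"
    ),
    fraction = c(
      FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
      FALSE, FALSE, TRUE, TRUE, FALSE, FALSE
    ),
    stringsAsFactors = FALSE
  )
}

#' Assemble a validated set of exposure-factor distributions
#'
#' A `factor_set` names one distribution for every factor the exposure engine
#' needs: surface dust loading (mg/cm2), outdoor soil loading (mg/cm2),
#' transfer fraction, fraction of hand surface contacting, hand area (cm2),
#' mouthed area per event (cm2), mouthing removal efficiency, maximum hand
#' loading (mg/cm2), handwash removal efficiency, body weight (kg),
#' contaminant concentration (mg/kg), exposure factor, absorption fraction,
#' soil-to-skin adherence (mg/cm2), and surface area available per contact
#' event (cm2). Units are checked against an internal registry, and factors
#' that are physical fractions must have support within \[0, 1\].
#'
#' `surface_loading_by_object` optionally overrides the surface-loading
#' distribution per object/surface category (e.g. a dirtier `Floor`, a
#' pacifier with its own loading distribution).
#'
#' @param distributions Named list of [factor_dist()] objects covering every
#'   registry factor.
#' @param surface_loading_by_object Optional named list of [factor_dist()]
#'   keyed by object token.
#' @return An object of class `factor_set`.
#' @export
factor_set <- function(distributions, surface_loading_by_object = list()) {
  reg <- factor_registry()
  missing <- setdiff(reg$name, names(distributions))
  if (length(missing) > 0) {
    stop(
      "factor set missing required factor(s): ",
      paste(missing, collapse = ", ")
    )
  }
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    d <- distributions[[nm]]
    if (!inherits(d, "factor_dist")) stop("'", nm, "' is not a factor_dist")
    if (d$units != reg$units[i]) {
      stop(
        "unit mismatch for '", nm, "': expected ", reg$units[i],
        ", got ", d$units
      )
    }
    if (reg$fraction[i] && (d$support[1] < 0 || d$support[2] > 1)) {
      stop(
        "support violation for '", nm,
        "': a fraction must have support within [0, 1]"
      )
    }
  }
  for (nm in names(surface_loading_by_object)) {
    d <- surface_loading_by_object[[nm]]
    if (!inherits(d, "factor_dist") || d$units != "mg/cm2") {
      stop("per-object loading override '", nm, "' must be a factor_dist in mg/cm2")
    }
  }
  structure(
    list(
      distributions = distributions[reg$name],
      surface_loading_by_object = surface_loading_by_object
    ),
    class = "factor_set"
  )
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf(
    "<factor_set> %d factors, %d per-object loading overrides\n",
    length(x$distributions), length(x$surface_loading_by_object)
  ))
  invisible(x)
}

dist_from_config <- function(nm, cfg) {
  if (is.null(cfg$kind)) stop("factor '", nm, "' has no 'kind'")
  params <- cfg[!names(cfg) %in% c("kind", "units", "support")]
  support <- if (is.null(cfg$support)) c(-Inf, Inf) else as.numeric(cfg$support)
  units <- if (is.null(cfg$units)) stop("factor '", nm, "' has no 'units'") else cfg$units
  factor_dist(nm, cfg$kind, params, units = units, support = support)
}

#' Load a factor set from a YAML configuration file
#'
#' The file maps each factor name to `kind`, `units`, `support`, and the
#' kind's parameters; an optional `surface_loading_by_object` block maps
#' object tokens to loading distributions. A shipped default configuration
#' with placeholder, literature-style values (not authoritative study
#' distributions) is at
#' `system.file("extdata", "factors-default.yaml", package = "mlatsim")`.
#'
#' @param path YAML file path.
#' @return A validated [factor_set()].
#' @export
load_factor_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  overrides <- list()
  if (!is.null(cfg$surface_loading_by_object)) {
    overrides <- lapply(
      stats::setNames(
        names(cfg$surface_loading_by_object),
        names(cfg$surface_loading_by_object)
      ),
      function(nm) dist_from_config(nm, cfg$surface_loading_by_object[[nm]])
    )
    cfg$surface_loading_by_object <- NULL
  }
  dists <- lapply(
    stats::setNames(names(cfg), names(cfg)),
    function(nm) dist_from_config(nm, cfg[[nm]])
  )
  factor_set(dists, overrides)
}

#' Default placeholder factor set
#'
#' Plausible, clearly non-authoritative distributions for demonstration and
#' testing; real applications should load study-derived distributions with
#' [load_factor_set()].
#'
#' @return A [factor_set()].
#' @export
default_factor_set <- function() {
  load_factor_set(
    system.file("extdata", "factors-default.yaml", package = "mlatsim")
  )
}

#' Export a factor set as a summary table
#'
#' @param fset A [factor_set()].
#' @param path Optional CSV path to write.
#' @return Data frame with one row per factor (name, kind, units, support,
#'   parameters, untruncated mean), invisibly written to `path` when given.
#' @export
factor_set_table <- function(fset, path = NULL) {
  stopifnot(inherits(fset, "factor_set"))
  rows <- lapply(fset$distributions, function(d) {
    data.frame(
      name = d$name, kind = d$kind, units = d$units,
      support_lo = d$support[1], support_hi = d$support[2],
      parameters = paste(names(d$parameters),
        vapply(d$parameters, function(v) paste(format(v), collapse = ";"), ""),
        sep = "=", collapse = " "
      ),
      mean = factor_mean(d),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
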