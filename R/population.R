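#' Configuration for a virtual-child population run
#'
#' Each "virtual child" is one Monte Carlo realization: an activity series
#' (bootstrapped with replacement from a pool of MLATS triples, or generated
#' from a [synth_config()]) combined with freshly sampled exposure factors.
#' The default age-group labels are the four EPA childhood groups.
#'
#' @param n_children Number of virtual children (>= 1).
#' @param factors A [factor_set()], or a named list of factor sets keyed by
#'   age group (per-group overrides).
#' @param mlats_pool Optional list of MLATS triples (each a named list with
#'   `left_hand`, `right_hand`, `mouth`, optionally `age_group`) to
#'   bootstrap from.
#' @param synth A [synth_config()] used to generate series when no pool is
#'   given.
#' @param age_groups Age-group labels; children are assigned uniformly when
#'   the pool carries no labels.
#' @param sim A [sim_config()].
#' @param profile Time-activity profile passed to
#'   [extrapolate_daily_rate()].
#' @param master_seed Integer master seed; child i derives a deterministic
#'   substream so that adding children never perturbs earlier ones.
#' @param tolerance,window Convergence tolerance (relative) and window
#'   fraction for [check_convergence()].
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_children, factors, mlats_pool = NULL,
                              synth = synth_config(),
                              age_groups = c(
                                "6-<12 mo", "1-<2 y", "2-<3 y", "3-<6 y"
                              ),
                              sim = sim_config(),
                              profile = list(indoor_h = 10, outdoor_h = 2),
                              master_seed = 1,
                              tolerance = 0.01, window = 0.1) {
  stopifnot(n_children >= 1, tolerance > 0, window > 0, window < 1)
  if (is.null(mlats_pool) && is.null(synth)) {
    stop("population needs an MLATS pool or a synth_config")
  }
  if (!is.null(mlats_pool) && length(mlats_pool) == 0) {
    stop("empty MLATS pool with no synth_config")
  }
  structure(
    list(
      n_children = as.integer(n_children), factors = factors,
      mlats_pool = mlats_pool, synth = synth, age_groups = age_groups,
      sim = sim, profile = profile, master_seed = as.integer(master_seed),
      tolerance = tolerance, window = window
    ),
    class = "population_config"
  )
}

group_factors <- function(config, group) {
  f <- config$factors
  if (inherits(f, "factor_set")) {
    return(f)
  }
  if (!group %in% names(f)) {
    stop("no factor set for age group '", group, "'")
  }
  f[[group]]
}

#' Simulate a population of virtual children
#'
#' Runs [run_child_simulation()] for `n_children` independent virtual
#' children. Child i seeds R's RNG with a deterministic substream of the
#' master seed before any of its draws (series bootstrap or generation,
#' per-child factors, per-event factors), so results are reproducible and
#' substream-isolated. Daily rates come from [extrapolate_daily_rate()]
#' with the configured time-activity profile.
#'
#' @param config A [population_config()].
#' @return An object of class `population_result`: `children` (data frame of
#'   per-child mg/day by medium and age group), `summary` (per-age-group and
#'   overall mean/p50/p90/p95 of total mg/day, nearest-rank percentiles),
#'   `convergence` (result of [check_convergence()] on the running totals),
#'   and `config` echoes.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_children
  rows <- vector("list", n)
  pool <- config$mlats_pool
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$master_seed, 1000 + i))
    if (!is.null(pool)) {
      pick <- pool[[sample.int(length(pool), 1)]]
      series <- pick
      group <- if (!is.null(pick$age_group)) {
        pick$age_group
      } else {
        sample(config$age_groups, 1)
      }
    } else {
      series <- generate_mlats(config$synth, seed = substream_seed(config$master_seed, 2000 + i))
      group <- sample(config$age_groups, 1)
    }
    fset <- group_factors(config, group)
    res <- run_child_simulation(
      series$left_hand, series$right_hand, series$mouth,
      fset,
      config = config$sim
    )
    daily <- extrapolate_daily_rate(res, config$profile)
    rows[[i]] <- data.frame(
      child = i, age_group = group,
      dust_mg_day = daily[["dust"]], soil_mg_day = daily[["soil"]],
      total_mg_day = daily[["total"]], body_weight_kg = res$child$body_weight,
      stringsAsFactors = FALSE
    )
  }
  children <- do.call(rbind, rows)

  summarize_group <- function(x) {
    data.frame(
      n = length(x), mean = mean(x),
      p50 = nearest_rank_quantile(x, 0.50),
      p90 = nearest_rank_quantile(x, 0.90),
      p95 = nearest_rank_quantile(x, 0.95)
    )
  }
  by_group <- do.call(rbind, lapply(
    split(children$total_mg_day, children$age_group), summarize_group
  ))
  by_group <- cbind(age_group = rownames(by_group), by_group)
  rownames(by_group) <- NULL
  overall <- cbind(age_group = "all", summarize_group(children$total_mg_day))
  summary <- rbind(by_group, overall)

  conv <- check_convergence(
    children$total_mg_day,
    tolerance = config$tolerance, window = config$window
  )
  structure(
    list(
      children = children, summary = summary, convergence = conv,
      master_seed = config$master_seed
    ),
    class = "population_result"
  )
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf(
    "<population_result> %d virtual children (seed %d); converged: %s%s\n",
    nrow(x$children), x$master_seed, x$convergence$converged,
    if (x$convergence$converged) sprintf(" at n = %d", x$convergence$n_stable) else ""
  ))
  print(x$summary, ...)
  invisible(x)
}

#' Nearest-rank percentile
#'
#' The deterministic nearest-rank method: the p-th percentile of n sorted
#' values is the `ceiling(p * n)`-th order statistic (equivalently,
#' `quantile(type = 1)`).
#'
#' @param x Numeric vector.
#' @param p Probability in (0, 1\].
#' @return Numeric scalar.
#' @export
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x)[max(1L, ceiling(p * length(x)))]
}

#' Monte Carlo convergence diagnostic on a result stream
#'
#' The simulation count is judged stable where further replicates stop
#' moving the results: at the end of each window (a fixed fraction of the
#' iterations so far), the running mean and running 95th percentile are
#' compared with their values one window earlier, and convergence is
#' declared at the first point where both relative changes fall below
#' `tolerance`. Both a central and an upper-tail summary are monitored
#' because exposure distributions are right-skewed: a stable mean alone can
#' hide an unstable tail.
#'
#' @param x Numeric stream of per-replicate results, in run order.
#' @param tolerance Relative-change threshold.
#' @param window Window as a fraction of the iterations so far (>= 2
#'   iterations enforced).
#' @return List with `converged`, `n_stable` (`NA` when not converged),
#'   and `trace` (data frame of n, running mean, running p95, relative
#'   changes).
#' @export
#' @examples
#' set.seed(1)
#' check_convergence(rlnorm(5000), tolerance = 0.01, window = 0.1)
check_convergence <- function(x, tolerance = 0.01, window = 0.1) {
  stopifnot(is.numeric(x), tolerance > 0, window > 0, window < 1)
  n <- length(x)
  if (n < 4) {
    return(list(
      converged = FALSE, n_stable = NA_integer_,
      trace = data.frame(
        n = integer(0), mean = numeric(0), p95 = numeric(0),
        rel_change = numeric(0)
      )
    ))
  }
  checkpoints <- unique(pmax(2L, as.integer(floor(seq_len(ceiling(1 / window)) * window * n))))
  checkpoints <- checkpoints[checkpoints <= n]
  if (length(checkpoints) < 2 || checkpoints[length(checkpoints)] < n) {
    checkpoints <- unique(c(checkpoints, n))
  }
  cmeans <- cumsum(x) / seq_len(n)
  means <- cmeans[checkpoints]
  p95_at <- function(k) nearest_rank_quantile(x[1:k], 0.95)
  p95s <- vapply(checkpoints, p95_at, numeric(1))
  relchg <- function(cur, prev) {
    if (cur == prev) return(0)
    if (cur == 0) return(Inf)
    abs(cur - prev) / abs(cur)
  }
  # Within each window, probe single-step changes of the running summaries
  # at a spread of points: a stream that merely oscillates through the
  # window endpoints (e.g. alternating values) must not be called stable.
  window_rel <- function(j) {
    lo <- checkpoints[j - 1]
    hi <- checkpoints[j]
    probes <- unique(pmax(lo + 1L, as.integer(round(seq(lo + 1L, hi, length.out = min(16L, hi - lo))))))
    step <- vapply(probes, function(k) {
      max(
        relchg(cmeans[k], cmeans[k - 1L]),
        relchg(p95_at(k), p95_at(k - 1L))
      )
    }, numeric(1))
    max(
      relchg(means[j], means[j - 1]),
      relchg(p95s[j], p95s[j - 1]),
      step
    )
  }
  rel <- c(NA_real_, vapply(seq_along(checkpoints)[-1], window_rel, numeric(1)))
  trace <- data.frame(n = checkpoints, mean = means, p95 = p95s, rel_change = rel)
  hit <- which(!is.na(rel) & rel < tolerance)
  if (length(hit) > 0) {
    list(converged = TRUE, n_stable = checkpoints[hit[1]], trace = trace)
  } else {
    list(converged = FALSE, n_stable = NA_integer_, trace = trace)
  }
}
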