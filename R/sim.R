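#' Hill-type fitness modulation of birth and death rates
#'
#' The birth-rate factor rises from 1 (at fitness 0) towards the maximal
#' fold-change `g_lambda` as fitness grows; the death-rate factor falls
#' from 1 towards `1 / g_delta`:
#' \deqn{f_\lambda(w) = 1 + (g_\lambda - 1) \frac{w^h}{1 + w^h}, \qquad
#'       f_\delta(w) = \frac{1 + w^h}{1 + g_\delta w^h}.}
#'
#' @param w Fitness score(s), non-negative.
#' @param g_lambda,g_delta Maximal fold-changes (>= 1 for selection).
#' @param h Hill exponent (> 0).
#' @return Numeric vector of modulation factors.
#' @export
f_lambda <- function(w, g_lambda = 2, h = 2) {
  stopifnot(all(w >= 0), h > 0)
  wh <- w^h
  1 + (g_lambda - 1) * wh / (1 + wh)
}

#' @rdname f_lambda
#' @export
f_delta <- function(w, g_delta = 2, h = 2) {
  stopifnot(all(w >= 0), h > 0)
  wh <- w^h
  (1 + wh) / (1 + g_delta * wh)
}

#' Simulation configuration
#'
#' All parameters of the birth-death-mutation model. Rates are per day,
#' times in days, the carrying capacity in cells. The scenario selects
#' the selection regime applied after the growth phase `T_g`:
#' `"lung"` (constant antigen access with growth-rate decay from
#' `T_dec`), `"lung_no_decay"`, `"lymph_node"` (dark/light-zone
#' shuttling; only dark-zone cells divide, compensated by `alpha_LN`),
#' or `"no_selection"` (neutral control).
#'
#' @param scenario One of `"lung"`, `"lung_no_decay"`, `"lymph_node"`,
#'   `"no_selection"`.
#' @param lambda0,delta0 Baseline birth and death rates (`lambda0 >
#'   delta0`).
#' @param D Fitness diffusion coefficient: a daughter's fitness is the
#'   parent's plus a normal deviate with standard deviation
#'   `sqrt(2 * D)`, clamped at zero.
#' @param g_lambda,g_delta,h Hill-modulation parameters, see
#'   [f_lambda()].
#' @param C Carrying capacity.
#' @param n_founders Number of founder clones (one cell each).
#' @param T_g End of the competition-free growth phase.
#' @param T_end Simulation end.
#' @param T_dec Onset of growth-rate decay (lung scenario).
#' @param kappa Decay rate magnitude (per day, > 0); the effective birth
#'   rate after `T_dec` is `(lambda0 - delta0) * exp(-kappa * (t -
#'   T_dec)) + delta0`, which never falls below `delta0`.
#' @param k_DZLZ,k_LZDZ Dark-to-light and light-to-dark zone transition
#'   rates (lymph-node scenario).
#' @param alpha_LN Dark-zone growth compensation factor; the default 2
#'   offsets 50% dark-zone occupancy at equal transition rates.
#' @param w0 Founder fitness: `NULL` (default) draws each founder
#'   uniformly on (0, 1); a scalar fixes all founders.
#' @param capacity_lambda0 Which birth rate enters the capacity term
#'   `(lambda0 - delta0) * M / C`: `"auto"` (default; the alpha-boosted
#'   rate in the lymph-node scenario, where the modified rate replaces
#'   `lambda0` throughout the formalism, and the baseline rate
#'   elsewhere), `"baseline"`, or `"effective"`.
#' @param max_cells Hard population cap; exceeding it aborts.
#' @param record_dt Snapshot interval (days).
#' @param seed Integer seed.
#' @param log_events Keep a full event log (births, deaths, zone
#'   transitions with times); intended for small runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("lung", "lung_no_decay", "lymph_node",
                                    "no_selection"),
                       lambda0 = 2, delta0 = 0.5, D = 0.001,
                       g_lambda = 2, g_delta = 2, h = 2, C = 2000,
                       n_founders = 50, T_g = 5, T_end = 12, T_dec = 7,
                       kappa = 0.5, k_DZLZ = 6, k_LZDZ = 6, alpha_LN = 2,
                       w0 = NULL,
                       capacity_lambda0 = c("auto", "baseline", "effective"),
                       max_cells = 200000L, record_dt = 0.25, seed = 1L,
                       log_events = FALSE) {
  scenario <- match.arg(scenario)
  capacity_lambda0 <- match.arg(capacity_lambda0)
  stopifnot(
    lambda0 > delta0, delta0 >= 0, D >= 0, g_lambda >= 0, g_delta >= 0,
    h > 0, C > n_founders, n_founders >= 1, T_g >= 0, T_end > 0,
    kappa >= 0, k_DZLZ >= 0, k_LZDZ >= 0, alpha_LN > 0,
    is.null(w0) || (w0 >= 0)
  )
  structure(
    list(
      scenario = scenario,
      scenario_code = match(scenario, c("no_selection", "lung_no_decay",
                                        "lung", "lymph_node")) - 1L,
      lambda0 = lambda0, delta0 = delta0, D = D, g_lambda = g_lambda,
      g_delta = g_delta, h = h, C = C, n_founders = as.integer(n_founders),
      T_g = T_g, T_end = T_end, T_dec = T_dec, kappa = kappa,
      k_DZLZ = k_DZLZ, k_LZDZ = k_LZDZ, alpha_LN = alpha_LN, w0 = w0,
      capacity_lambda0 = capacity_lambda0,
      cap_mode = match(capacity_lambda0,
                       c("auto", "baseline", "effective")) - 1L,
      max_cells = as.integer(max_cells), record_dt = record_dt,
      seed = as.integer(seed), log_events = log_events
    ),
    class = "sim_config"
  )
}

#' Scenario-effective average birth rate
#'
#' The population-average birth rate the model conserves at time `t`:
#' the baseline rate, its exponential decay towards `delta0` after
#' `T_dec` in the lung scenario, or `alpha_LN * lambda0` in the
#' lymph-node scenario.
#'
#' @param config A [sim_config()].
#' @param t Time (days).
#' @return A single rate (per day).
#' @export
effective_lambda0 <- function(config, t) {
  if (config$scenario == "lung" && t > config$T_dec) {
    (config$lambda0 - config$delta0) *
      exp(-config$kappa * (t - config$T_dec)) + config$delta0
  } else if (config$scenario == "lymph_node" && t >= config$T_g) {
    config$alpha_LN * config$lambda0
  } else {
    config$lambda0
  }
}

#' Per-cell birth and death rates for a population
#'
#' Freshly recomputed rates for every cell of a population under the
#' model's normalisation: \deqn{\lambda_i = \tilde\lambda_0
#' f_\lambda(w_i) / \bar f_\lambda, \qquad \delta_i = \delta_0
#' f_\delta(w_i) / \bar f_\delta + (\lambda_0 - \delta_0) M / C,}
#' where the bars are population means over the live cells. The
#' normalisation conserves the population averages exactly: the mean of
#' `lambda` equals the scenario-effective birth rate and the mean of
#' `delta` minus the capacity term equals `delta0`, for any fitness
#' distribution. During the growth phase (`t < T_g`) and in the
#' no-selection scenario the Hill factors are replaced by 1.
#'
#' @param w Fitness scores of the live cells.
#' @param config A [sim_config()].
#' @param t Time (days).
#' @return A tibble with columns `lambda` and `delta`, one row per cell.
#' @export
cell_rates <- function(w, config, t = config$T_g) {
  stopifnot(length(w) >= 1L, all(w >= 0))
  M <- length(w)
  l0_eff <- effective_lambda0(config, t)
  l0_cap <- switch(
    config$capacity_lambda0,
    baseline = config$lambda0,
    effective = if (t >= config$T_g) l0_eff else config$lambda0,
    auto = if (config$scenario == "lymph_node" && t >= config$T_g) {
      config$alpha_LN * config$lambda0
    } else {
      config$lambda0
    }
  )
  cap <- (l0_cap - config$delta0) * M / config$C
  if (t < config$T_g || config$scenario == "no_selection") {
    return(tibble::tibble(lambda = rep(config$lambda0, M),
                          delta = rep(config$delta0 + cap, M)))
  }
  fl <- f_lambda(w, config$g_lambda, config$h)
  fd <- f_delta(w, config$g_delta, config$h)
  tibble::tibble(
    lambda = l0_eff * fl / mean(fl),
    delta = config$delta0 * fd / mean(fd) + cap
  )
}

#' Fitness mutation at division
#'
#' The daughter fitness is the parent fitness plus a normal deviate with
#' standard deviation `sqrt(2 * D)`, clamped at zero from below.
#'
#' @param w_parent Parent fitness score(s).
#' @param D Diffusion coefficient (>= 0).
#' @return Mutated fitness score(s).
#' @export
mutate_fitness <- function(w_parent, D) {
  stopifnot(D >= 0)
  pmax(0, w_parent + stats::rnorm(length(w_parent), 0, sqrt(2 * D)))
}

#' Run one stochastic simulation
#'
#' Event-driven exact simulation of the birth-death-mutation process
#' under the configured scenario. All cells grow unmodulated during the
#' growth phase; afterwards the scenario's selection rules apply. In the
#' lymph-node scenario cells shuttle between dark and light zones as
#' Poisson processes, only dark-zone cells divide, the death rate is
#' refreshed on dark-to-light transition and the birth rate on re-entry
#' into the dark zone; rates are otherwise frozen.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: list with `timeline` (tibble
#'   of per-snapshot population statistics), `clone_sizes` (snapshots by
#'   founder-clone matrix), `final` (tibble of live cells), `extinct`,
#'   `n_events`, `event_log` (when requested) and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w0 <- config$w0
  w0 <- if (is.null(w0)) {
    stats::runif(config$n_founders)
  } else {
    rep(w0, length.out = config$n_founders)
  }
  raw <- .sim_run_cpp(config, w0)
  timeline <- tibble::tibble(
    time = raw$time, M = raw$M, n_clones = raw$n_clones,
    mean_clone_size = ifelse(raw$n_clones > 0, raw$M / raw$n_clones, NA_real_),
    dominant_fraction = raw$dominant_fraction, mean_w = raw$mean_w
  )
  structure(
    list(
      timeline = timeline,
      clone_sizes = raw$clone_sizes,
      final = tibble::tibble(w = raw$final_w, clone = raw$final_clone + 1L,
                             zone = c("DZ", "LZ", "none")[
                               match(raw$final_zone, c(0L, 1L, -1L))]),
      extinct = raw$extinct,
      n_events = raw$n_events,
      event_log = raw$event_log,
      config = config
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  fin <- x$timeline[nrow(x$timeline), ]
  cat(sprintf(
    "<sim_result> scenario %s, day %.1f: M = %d in %d clone(s)%s (%.0f events)\n",
    x$config$scenario, fin$time, fin$M, fin$n_clones,
    if (x$extinct) " [EXTINCT]" else "", x$n_events
  ))
  invisible(x)
}

#' @rdname tidy-maturr
#' @export
tidy.sim_result <- function(x, ...) x$timeline

#' @rdname tidy-maturr
#' @export
glance.sim_result <- function(x, ...) {
  fin <- x$timeline[nrow(x$timeline), ]
  tibble::tibble(
    scenario = x$config$scenario, M = fin$M, n_clones = fin$n_clones,
    mean_clone_size = fin$mean_clone_size,
    dominant_fraction = fin$dominant_fraction, mean_w = fin$mean_w,
    extinct = x$extinct
  )
}

#' Ensemble of independent simulations
#'
#' Runs `n_runs` replicates with per-run seeds derived deterministically
#' from `config$seed` (seed + run index) and aggregates population
#' statistics over time as mean and standard error.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of replicates.
#' @return An object of class `sim_ensemble`: list with `runs` (one row
#'   per run: final-day statistics), `timeline` (per-timepoint mean and
#'   SEM over runs), `n_runs` and `config`.
#' @export
ensemble <- function(config, n_runs = 100) {
  stopifnot(n_runs >= 1)
  results <- lapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    run_simulation(cfg)
  })
  runs <- dplyr::bind_rows(lapply(results, glance)) |>
    dplyr::mutate(run = dplyr::row_number(), .before = 1)
  per_time <- dplyr::bind_rows(
    lapply(seq_along(results), function(i) {
      dplyr::mutate(results[[i]]$timeline, run = i)
    })
  )
  sem <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  timeline <- per_time |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      dplyr::across(c("M", "n_clones", "mean_clone_size",
                      "dominant_fraction", "mean_w"),
                    list(mean = ~mean(.x, na.rm = TRUE), sem = sem)),
      .groups = "drop"
    )
  structure(
    list(runs = runs, timeline = timeline, n_runs = n_runs,
         config = config),
    class = "sim_ensemble"
  )
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %s, %d run(s); day %.1f mean clone size %.1f, dominant fraction %.2f\n",
              x$config$scenario, x$n_runs, x$config$T_end,
              mean(x$runs$mean_clone_size, na.rm = TRUE),
              mean(x$runs$dominant_fraction, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidy-maturr
#' @export
tidy.sim_ensemble <- function(x, ...) x$timeline

#' @rdname tidy-maturr
#' @export
glance.sim_ensemble <- function(x, ...) {
  sem <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  tibble::tibble(
    scenario = x$config$scenario, n_runs = x$n_runs,
    n_extinct = sum(x$runs$extinct),
    mean_clone_size = mean(x$runs$mean_clone_size, na.rm = TRUE),
    mean_clone_size_sem = sem(x$runs$mean_clone_size),
    dominant_fraction = mean(x$runs$dominant_fraction, na.rm = TRUE),
    dominant_fraction_sem = sem(x$runs$dominant_fraction),
    mean_w = mean(x$runs$mean_w, na.rm = TRUE),
    mean_w_sem = sem(x$runs$mean_w)
  )
}

#' Two-state dark/light-zone shuttling occupancy
#'
#' Simulates a single cell alternating between dark- and light-zone
#' residence with exponential sojourn times and returns the long-run
#' fraction of time spent in the dark zone. With equal transition rates
#' this fraction converges to 50%.
#'
#' @param k_DZLZ,k_LZDZ Transition rates (per day).
#' @param t_end Trajectory length (days).
#' @param seed Integer seed.
#' @return The dark-zone time fraction.
#' @export
simulate_shuttling <- function(k_DZLZ = 6, k_LZDZ = 6, t_end = 1e4,
                               seed = 1L) {
  stopifnot(k_DZLZ > 0, k_LZDZ > 0, t_end > 0)
  set.seed(seed)
  m <- ceiling(1.5 * t_end / (1 / k_DZLZ + 1 / k_LZDZ)) + 100L
  repeat {
    dz <- stats::rexp(m, k_DZLZ)
    lz <- stats::rexp(m, k_LZDZ)
    if (sum(dz) + sum(lz) >= t_end) break
    m <- 2L * m
  }
  sojourn <- as.vector(rbind(dz, lz))  # alternating DZ, LZ, DZ, ...
  ends <- cumsum(sojourn)
  starts <- c(0, ends[-length(ends)])
  in_dz <- rep(c(TRUE, FALSE), m)
  sum(pmax(0, pmin(ends, t_end) - pmin(starts, t_end))[in_dz]) / t_end
}
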