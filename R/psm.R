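#' Partitioned-survival model configuration
#'
#' Structural settings of the three-state (progression-free / progressed /
#' dead) partitioned-survival model: a 21-day cycle, costs and benefits
#' discounted at 5% per year (plausible range 0-8%), and a lifetime horizon
#' operationalized as "run until fewer than 1% of the cohort survives", with
#' a hard cap (default 25 years) guaranteeing termination for heavy-tailed
#' extrapolations. Utilities are 0.804 progression-free and 0.321 after
#' progression; a one-time adverse-event disutility (a negative QALY
#' decrement) may be applied in the first cycle.
#'
#' @param cycle_length_days model cycle in days.
#' @param discount_rate annual discount rate for costs and benefits.
#' @param horizon_years hard cap on the time horizon.
#' @param os_floor survival fraction below which the trace stops.
#' @param days_per_year calendar convention (365.25).
#' @param u_pfs,u_pd health-state utilities, `0 <= u_pd <= u_pfs <= 1`.
#' @param one_time_disutility one-time QALY decrement (<= 0) applied at the
#'   first cycle; arm-specific, so set per run.
#' @param half_cycle evaluate occupancy at cycle midpoints instead of cycle
#'   starts (half-cycle correction switch; default off).
#' @return an object of class `model_config`.
#' @export
model_config <- function(cycle_length_days = 21,
                         discount_rate = 0.05,
                         horizon_years = 25,
                         os_floor = 0.01,
                         days_per_year = 365.25,
                         u_pfs = 0.804,
                         u_pd = 0.321,
                         one_time_disutility = 0,
                         half_cycle = FALSE) {
  if (cycle_length_days <= 0) stop("cycle_length_days must be > 0", call. = FALSE)
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (!(u_pd >= 0 && u_pd <= u_pfs && u_pfs <= 1))
    stop("utilities must satisfy 0 <= u_pd <= u_pfs <= 1", call. = FALSE)
  if (one_time_disutility > 0)
    stop("one_time_disutility is a decrement and must be <= 0", call. = FALSE)
  structure(list(cycle_length_days = cycle_length_days,
                 discount_rate = discount_rate,
                 horizon_years = horizon_years, os_floor = os_floor,
                 days_per_year = days_per_year,
                 u_pfs = u_pfs, u_pd = u_pd,
                 one_time_disutility = one_time_disutility,
                 half_cycle = isTRUE(half_cycle)),
            class = "model_config")
}

cycle_years <- function(config) config$cycle_length_days / config$days_per_year
months_per_year <- 12

#' Per-cycle discount factor
#'
#' `(1 + rate)^(-t)` with `t` in years at the start of the cycle
#' (`cycle_index * cycle_length / days_per_year`); 1 at cycle 0 and
#' identically 1 when the rate is 0.
#'
#' @param cycle_index 0-based cycle index (vectorized).
#' @param config a [model_config()].
#' @export
discount_factor <- function(cycle_index, config) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  t_years <- cycle_index * cycle_years(config)
  (1 + config$discount_rate)^(-t_years)
}

#' Cycle-wise state occupancy from PFS and OS survival functions
#'
#' The partitioned-survival identity: at each cycle's evaluation time `t`
#' (cycle start, or midpoint under half-cycle correction),
#' `p_PFS = min(S_pfs(t), S_os(t))`, `p_PD = S_os(t) - p_PFS`,
#' `p_death = 1 - S_os(t)`. Independently fitted curves can cross during
#' extrapolation; the clamp keeps the three occupancies a partition of 1.
#' The trace runs while `S_os` at the cycle start exceeds the survivor floor
#' and stops at the hard horizon cap; if the cap is hit first, a warning is
#' recorded in the trace's `horizon_warning` attribute.
#'
#' @param s_pfs,s_os survival functions of time in **months** (e.g.
#'   `function(t) survival_at(fit, t)` or a [parametric_fit]).
#' @param config a [model_config()].
#' @return a data.frame of class `state_trace`: cycle (0-based), time_years,
#'   p_pfs, p_pd, p_death, incident_death, discount.
#' @export
state_occupancy <- function(s_pfs, s_os, config = model_config()) {
  as_fn <- function(f) if (inherits(f, "parametric_fit"))
    function(t) survival_at(f, t) else f
  s_pfs <- as_fn(s_pfs); s_os <- as_fn(s_os)
  cyc_y <- cycle_years(config)
  max_cycles <- ceiling(config$horizon_years / cyc_y)
  cyc <- 0:(max_cycles - 1)
  t_start_months <- cyc * cyc_y * months_per_year
  os_start <- s_os(t_start_months)
  # include cycles whose starting survival is above the floor
  keep <- os_start > config$os_floor
  n_keep <- if (all(keep)) max_cycles else (which(!keep)[1] - 1)
  horizon_warning <- FALSE
  if (n_keep == max_cycles && os_start[max_cycles] > config$os_floor) {
    horizon_warning <- TRUE
    warning(sprintf("horizon cap %g years reached with OS survival %.3f >= %g",
                    config$horizon_years, os_start[max_cycles],
                    config$os_floor), call. = FALSE)
  }
  n_keep <- max(n_keep, 1)
  cyc <- cyc[seq_len(n_keep)]
  t_eval_months <- (cyc + if (config$half_cycle) 0.5 else 0) *
    cyc_y * months_per_year
  s_os_v <- s_os(t_eval_months)
  s_pfs_v <- s_pfs(t_eval_months)
  p_pfs <- pmin(s_pfs_v, s_os_v)
  clamped <- any(s_pfs_v > s_os_v + 1e-12)
  p_pd <- s_os_v - p_pfs
  p_death <- 1 - s_os_v
  incident <- c(p_death[1], diff(p_death))
  incident <- pmax(incident, 0)
  tr <- data.frame(cycle = cyc, time_years = cyc * cyc_y,
                   p_pfs = p_pfs, p_pd = p_pd, p_death = p_death,
                   incident_death = incident,
                   discount = discount_factor(cyc, config))
  class(tr) <- c("state_trace", "data.frame")
  attr(tr, "config") <- config
  attr(tr, "horizon_warning") <- horizon_warning
  attr(tr, "clamped") <- clamped
  stopifnot(max(abs(tr$p_pfs + tr$p_pd + tr$p_death - 1)) < 1e-12)
  tr
}

#' Discounted and undiscounted life-years and QALYs over a trace
#'
#' Each cycle contributes `(p_PFS + p_PD) * cycle_years` life-years and
#' `(u_PFS p_PFS + u_PD p_PD) * cycle_years` QALYs, discounted by the
#' cycle's factor. The configured one-time adverse-event disutility (a
#' negative number) is added once, at the first cycle (whose discount factor
#' is 1, so discounted and undiscounted QALYs receive the same decrement).
#'
#' @param trace a [state_occupancy()] trace.
#' @param config a [model_config()]; defaults to the trace's own.
#' @return list with `ly_disc`, `qaly_disc`, `ly_undisc`, `qaly_undisc`.
#' @export
accumulate_effects <- function(trace, config = attr(trace, "config")) {
  stopifnot(inherits(trace, "state_trace"))
  cyc_y <- cycle_years(config)
  alive <- trace$p_pfs + trace$p_pd
  q <- config$u_pfs * trace$p_pfs + config$u_pd * trace$p_pd
  dis <- config$one_time_disutility
  list(ly_disc = sum(alive * cyc_y * trace$discount),
       qaly_disc = sum(q * cyc_y * trace$discount) + dis,
       ly_undisc = sum(alive * cyc_y),
       qaly_undisc = sum(q * cyc_y) + dis)
}

#' Export a state trace as delimited text
#' @param trace a `state_trace`.
#' @param path output CSV.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
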