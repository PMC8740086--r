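# Independent oracles and small builders used across the suite.

# Brute-force product-limit estimator: no survfit, just the definition.
product_limit <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, survival = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at_risk)
    out$survival[i] <- s
  }
  out
}

# Evaluate a digitized curve as a right-continuous step function.
km_step <- function(curve) {
  stats::stepfun(curve$points$time, c(1, curve$points$survival))
}

# Hand-rolled IPD frame.
ipd <- function(time, event, arm = "A", endpoint = "OS") {
  data.frame(time = time, event = as.integer(event),
             arm = rep_len(arm, length(time)),
             endpoint = rep_len(endpoint, length(time)),
             stringsAsFactors = FALSE)
}

# A state trace built by hand (bypassing state_occupancy) for degenerate
# cost-engine cases.
manual_trace <- function(p_pfs, p_pd, config = model_config()) {
  n <- length(p_pfs)
  cyc <- seq_len(n) - 1L
  p_death <- 1 - p_pfs - p_pd
  tr <- data.frame(cycle = cyc,
                   time_years = cyc * config$cycle_length_days / config$days_per_year,
                   p_pfs = p_pfs, p_pd = p_pd, p_death = p_death,
                   incident_death = pmax(c(p_death[1], diff(p_death)), 0),
                   discount = discount_factor(cyc, config))
  class(tr) <- c("state_trace", "data.frame")
  attr(tr, "config") <- config
  tr
}

# Parameter value lookup from an econ_config.
ep_value <- function(cfg, nm) cfg$params$value[match(nm, cfg$params$name)]

# Single-endpoint generating spec (marginal sampling, optional censoring).
single_arm_spec <- function(family, params, n, followup = Inf, seed = 1) {
  trial_spec(n_per_arm = c(A = as.integer(n)),
             os = list(A = list(family = family, params = params)),
             pfs = list(A = list(family = family, params = params)),
             followup_months = followup, accrual_months = 0,
             joint = FALSE, seed = seed)
}
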