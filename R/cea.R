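#' Incremental cost-effectiveness of one arm against a comparator
#'
#' Incremental quantities are `base - comparator`. The ICER is
#' `delta_cost / delta_QALY`, defined only when the QALY difference is
#' nonzero; otherwise the dominance flag carries the interpretation (no
#' division ever crashes). The flag is `dominant` when the base arm is
#' cheaper and more effective, `dominated` when costlier and less effective,
#' `tradeoff` otherwise and `neutral` for identical arms. Incremental net
#' monetary benefit is `WTP x delta_QALY - delta_cost`.
#'
#' @param base,comparator [accumulate_costs()] results computed under the
#'   same model configuration.
#' @param wtp willingness-to-pay threshold, $/QALY.
#' @return an object of class `ce_result`.
#' @export
icer <- function(base, comparator, wtp = 32457) {
  d_cost <- base$total_cost_disc - comparator$total_cost_disc
  d_ly <- base$ly_disc - comparator$ly_disc
  d_qaly <- base$qaly_disc - comparator$qaly_disc
  ratio <- if (abs(d_qaly) > 0) d_cost / d_qaly else NA_real_
  per_ly <- if (abs(d_ly) > 0) d_cost / d_ly else NA_real_
  flag <- if (d_cost == 0 && d_qaly == 0) "neutral"
          else if (d_cost < 0 && d_qaly > 0) "dominant"
          else if (d_cost > 0 && d_qaly < 0) "dominated"
          else "tradeoff"
  structure(list(base = base, comparator = comparator,
                 delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
                 icer = ratio, cost_per_ly = per_ly, dominance = flag,
                 wtp = wtp, nmb = wtp * d_qaly - d_cost),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$base$arm, x$comparator$arm))
  cat(sprintf("  incremental cost  $%10.2f\n", x$delta_cost))
  cat(sprintf("  incremental LY    %10.3f\n", x$delta_ly))
  cat(sprintf("  incremental QALY  %10.3f\n", x$delta_qaly))
  if (is.finite(x$icer))
    cat(sprintf("  ICER              $%10.2f /QALY (%s)\n", x$icer, x$dominance))
  else cat(sprintf("  ICER undefined (%s)\n", x$dominance))
  cat(sprintf("  NMB at WTP $%s:  $%.2f\n",
              format(x$wtp, big.mark = ","), x$nmb))
  invisible(x)
}

# survival functions of the two arms for one endpoint, from a model set
arm_surv_fns <- function(ms, arm) {
  list(pfs = selected_fit(ms, arm, "PFS"), os = selected_fit(ms, arm, "OS"))
}

# rebuild per-arm traces and arm results for a given economic configuration;
# traces are cached on the survival side, so economic-only changes reuse them
run_arms <- function(ms, mc, cfg, arms = c("CC", "C"), traces = NULL) {
  mc$discount_rate <- ep(cfg, "discount_rate")
  if (is.null(traces)) {
    traces <- lapply(setNames(arms, arms), function(a) {
      f <- arm_surv_fns(ms, a)
      suppressWarnings(state_occupancy(f$pfs, f$os, mc))
    })
  } else {
    # occupancy is discount-free; refresh only the discount column
    traces <- lapply(traces, function(tr) {
      tr$discount <- discount_factor(tr$cycle, mc)
      attr(tr, "config") <- mc
      tr
    })
  }
  res <- lapply(setNames(arms, arms), function(a)
    accumulate_costs(traces[[a]], a, cfg, mc))
  list(results = res, traces = traces)
}

#' Base-case cost-effectiveness analysis
#'
#' Builds both arms' state traces from the selected survival fits, runs the
#' cost engine, and returns the incremental comparison of the combination
#' (`CC`) against chemotherapy (`C`).
#'
#' @param ms a [build_model_set()] result with fits for both arms' PFS and OS.
#' @param mc a [model_config()].
#' @param cfg an [econ_config()].
#' @return a `ce_result`; per-arm results in `$base` / `$comparator`, traces
#'   in attribute `traces`.
#' @export
run_base_case <- function(ms, mc = model_config(), cfg = econ_config()) {
  out <- run_arms(ms, mc, cfg)
  ce <- icer(out$results$CC, out$results$C, wtp = cfg$wtp)
  attr(ce, "traces") <- out$traces
  ce
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the model twice per parameter (at its min, at its max, all else at
#' base) and records the resulting ICERs; rows are sorted by the ICER spread.
#' The choice of parametric survival family is itself the model's dominant
#' uncertainty, so for each (arm, endpoint) a categorical scenario row
#' replaces the selected family with each converged alternative and reports
#' the ICER range across families.
#'
#' @param ms,mc,cfg as in [run_base_case()].
#' @param parameters names to vary; default every parameter whose range is
#'   non-degenerate.
#' @param survival_scenarios include the per-(arm, endpoint) family swap rows?
#' @return data.frame of class `dsa_result`: parameter, low/high input,
#'   ICER at each, spread; plus the base-case ICER as an attribute.
#' @export
run_dsa <- function(ms, mc = model_config(), cfg = econ_config(),
                    parameters = NULL, survival_scenarios = TRUE) {
  base <- run_arms(ms, mc, cfg)
  base_ce <- icer(base$results$CC, base$results$C, wtp = cfg$wtp)
  traces <- base$traces
  pr <- cfg$params
  if (is.null(parameters))
    parameters <- pr$name[pr$max > pr$min]
  missing <- setdiff(parameters, pr$name)
  if (length(missing))
    stop("run_dsa: unknown parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(parameters, function(nm) {
    i <- match(nm, pr$name)
    ic <- vapply(c(pr$min[i], pr$max[i]), function(v) {
      out <- run_arms(ms, mc, set_param(cfg, nm, v), traces = traces)
      icer(out$results$CC, out$results$C, wtp = cfg$wtp)$icer
    }, numeric(1))
    data.frame(parameter = nm, low = pr$min[i], high = pr$max[i],
               icer_low = ic[1], icer_high = ic[2],
               spread = abs(ic[2] - ic[1]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (survival_scenarios) {
    for (key in names(ms$selected)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      a <- parts[1]; e <- parts[2]
      alts <- Filter(function(f) isTRUE(f$converged), ms$fits[[key]])
      ics <- vapply(alts, function(f) {
        ms2 <- ms
        ms2$selected[[key]] <- f
        r <- run_arms(ms2, mc, cfg)
        icer(r$results$CC, r$results$C, wtp = cfg$wtp)$icer
      }, numeric(1))
      out <- rbind(out, data.frame(
        parameter = sprintf("survival_model_%s_%s", a, e),
        low = NA_real_, high = NA_real_,
        icer_low = min(ics), icer_high = max(ics),
        spread = max(ics) - min(ics), stringsAsFactors = FALSE))
    }
  }
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dsa_result", "data.frame")
  attr(out, "base_icer") <- base_ce$icer
  out
}

#' Tornado view: top rows of a DSA table
#' @param dsa a [run_dsa()] result.
#' @param top number of rows to keep (default 20, mirroring a tornado plot).
#' @export
tornado_top <- function(dsa, top = 20) {
  utils::head(dsa, top)
}

#' Method-of-moments beta/gamma sampling of an economic parameter
#'
#' The standard deviation is taken from the deterministic range as
#' `(max - min)/3.92` (the width of a 95% normal interval). Beta shapes and
#' gamma shape/scale are matched to that mean and sd. Negative means
#' (disutilities) are sampled on magnitude and negated. Infeasible beta
#' moments (`sd^2 >= mean(1-mean)`) fall back to uniform(min, max) with a
#' warning.
#'
#' @param mean base value (the distribution's mean).
#' @param min,max deterministic range, setting the spread.
#' @param family `"beta"` or `"gamma"`.
#' @param n number of draws.
#' @return numeric vector of `n` draws within the family's support.
#' @export
sample_parameter <- function(mean, min, max, family = c("beta", "gamma"),
                             n = 1) {
  family <- match.arg(family)
  sd <- (max - min) / 3.92
  neg <- mean < 0
  if (neg) {
    m <- -mean
    lo <- -max; hi <- -min
  } else {
    m <- mean; lo <- min; hi <- max
  }
  if (sd == 0) return(rep(mean, n))
  draws <- if (family == "beta") {
    if (m <= 0 || m >= 1 || sd^2 >= m * (1 - m)) {
      warning(sprintf("beta moments infeasible (mean %.3g, sd %.3g); sampling uniform",
                      m, sd), call. = FALSE)
      stats::runif(n, lo, hi)
    } else {
      nu <- m * (1 - m) / sd^2 - 1
      stats::rbeta(n, m * nu, (1 - m) * nu)
    }
  } else {
    if (m <= 0) {
      warning("gamma requires a positive mean; sampling uniform", call. = FALSE)
      stats::runif(n, lo, hi)
    } else {
      stats::rgamma(n, shape = (m / sd)^2, scale = sd^2 / m)
    }
  }
  if (neg) -draws else draws
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Monte-Carlo simulation (default 1000 iterations): each iteration samples
#' every parameter carrying a beta or gamma distribution (in the fixed order
#' of the parameter table, one RNG stream seeded once), rebuilds both arms'
#' costs and effects on the base-case state traces (survival parameters stay
#' at base — only economic inputs carry distributions), and records the
#' incremental cost and QALY pair. The cost-effectiveness acceptability
#' curve gives, at each willingness-to-pay value, the fraction of iterations
#' with positive incremental net monetary benefit.
#'
#' @param ms,mc,cfg as in [run_base_case()].
#' @param n_iterations Monte-Carlo sample size.
#' @param seed integer seed for the single RNG stream.
#' @param wtp_grid CEAC thresholds; default $0-100,000 in $500 steps, always
#'   including $32,457 (3x GDP per capita) and $10,819 (1x).
#' @return an object of class `psa_result`: `draws` (per-iteration
#'   delta_cost, delta_qaly, nmb), `ceac`, `prob_dominant`, seed and size.
#' @export
run_psa <- function(ms, mc = model_config(), cfg = econ_config(),
                    n_iterations = 1000, seed = 1L, wtp_grid = NULL) {
  if (is.null(wtp_grid))
    wtp_grid <- sort(unique(c(seq(0, 100000, by = 500), 32457, 10819)))
  base <- run_arms(ms, mc, cfg)
  traces <- base$traces
  pr <- cfg$params
  stochastic <- which(pr$dist %in% c("beta", "gamma"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))
  d_cost <- d_qaly <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    cfg_i <- cfg
    for (j in stochastic) {
      cfg_i$params$value[j] <- sample_parameter(pr$value[j], pr$min[j],
                                                pr$max[j], pr$dist[j], n = 1)
    }
    out <- run_arms(ms, mc, cfg_i, traces = traces)
    d_cost[it] <- out$results$CC$total_cost_disc - out$results$C$total_cost_disc
    d_qaly[it] <- out$results$CC$qaly_disc - out$results$C$qaly_disc
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(w)
      mean(w * d_qaly - d_cost > 0), numeric(1)))
  structure(list(draws = data.frame(delta_cost = d_cost, delta_qaly = d_qaly,
                                    nmb = cfg$wtp * d_qaly - d_cost),
                 ceac = ceac,
                 prob_dominant = mean(d_cost < 0 & d_qaly > 0),
                 n_iterations = n_iterations, seed = as.integer(seed),
                 wtp = cfg$wtp),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)\n", x$n_iterations, x$seed))
  cat(sprintf("  mean incremental cost $%.2f, mean incremental QALY %.3f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  cat(sprintf("  dominant (cheaper & more effective) in %.1f%% of iterations\n",
              100 * x$prob_dominant))
  i <- which.min(abs(x$ceac$wtp - x$wtp))
  cat(sprintf("  P(cost-effective) at WTP $%s: %.3f\n",
              format(x$wtp, big.mark = ","), x$ceac$prob_cost_effective[i]))
  invisible(x)
}

#' Write base-case, DSA, and PSA outputs as delimited text
#'
#' @param ce a `ce_result`.
#' @param path output CSV.
#' @export
write_base_case <- function(ce, path) {
  df <- data.frame(
    quantity = c("cost_CC", "cost_C", "ly_CC", "ly_C", "qaly_CC", "qaly_C",
                 "delta_cost", "delta_ly", "delta_qaly",
                 "cost_per_ly", "icer", "nmb", "wtp"),
    value = c(ce$base$total_cost_disc, ce$comparator$total_cost_disc,
              ce$base$ly_disc, ce$comparator$ly_disc,
              ce$base$qaly_disc, ce$comparator$qaly_disc,
              ce$delta_cost, ce$delta_ly, ce$delta_qaly,
              ce$cost_per_ly, ce$icer, ce$nmb, ce$wtp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
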