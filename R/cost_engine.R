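#' Default economic parameter table
#'
#' Every economic input of the model as one row per parameter: base value,
#' deterministic range (reported 95% CI where available, otherwise +/-20% of
#' base), and the distribution family used in probabilistic sensitivity
#' analysis (beta for probabilities/utilities, gamma for costs, none for
#' structural values varied only deterministically). Monetary values are USD.
#'
#' Arms are labelled `CC` (camrelizumab + pemetrexed/carboplatin) and `C`
#' (pemetrexed/carboplatin). Adverse events are grade >= 3 neutropenia,
#' anaemia and thrombocytopenia. Subsequent-therapy rows encode the per-cycle
#' cost and uptake proportion of each post-progression option per arm
#' (docetaxel/supportive care after the combination; docetaxel, nivolumab,
#' camrelizumab crossover or supportive care after chemotherapy alone).
#'
#' @return data.frame with columns name, value, min, max, dist.
#' @export
econ_parameters <- function() {
  p <- function(name, value, min, max, dist) {
    data.frame(name = name, value = value, min = min, max = max, dist = dist,
               stringsAsFactors = FALSE)
  }
  rbind(
    p("u_pfs", 0.804, 0.64, 0.96, "beta"),
    p("u_pd", 0.321, 0.26, 0.39, "beta"),
    p("disutility_neutropenia", -0.2, -0.24, -0.16, "beta"),
    p("disutility_anaemia", -0.07, -0.084, -0.056, "beta"),
    p("disutility_thrombocytopenia", -0.2, -0.24, -0.16, "beta"),
    p("risk_neutropenia_CC", 0.38, 0.30, 0.46, "beta"),
    p("risk_anaemia_CC", 0.19, 0.15, 0.23, "beta"),
    p("risk_thrombocytopenia_CC", 0.17, 0.14, 0.20, "beta"),
    p("risk_neutropenia_C", 0.30, 0.24, 0.36, "beta"),
    p("risk_anaemia_C", 0.11, 0.09, 0.13, "beta"),
    p("risk_thrombocytopenia_C", 0.12, 0.10, 0.14, "beta"),
    p("cost_neutropenia", 466, 415, 508, "gamma"),
    p("cost_anaemia", 537, 478, 585, "gamma"),
    p("cost_thrombocytopenia", 6397, 5117, 7676, "gamma"),
    p("cost_cycle_camrelizumab", 452.00, 361.60, 542.40, "gamma"),
    p("cost_cycle_pemetrexed", 740.00, 592.00, 888.00, "gamma"),
    p("cost_cycle_carboplatin", 87.50, 70.00, 105.00, "gamma"),
    p("sub_cost_docetaxel", 405.00, 324.00, 486.00, "gamma"),
    p("sub_cost_nivolumab", 4182.75, 3346.20, 5019.30, "gamma"),
    p("sub_cost_camrelizumab", 452.00, 361.60, 542.40, "gamma"),
    p("sub_cost_supportive", 338, 159, 476, "gamma"),
    p("sub_prop_docetaxel_CC", 0.815, 0.652, 0.978, "beta"),
    p("sub_prop_supportive_CC", 0.185, 0.148, 0.222, "beta"),
    p("sub_prop_docetaxel_C", 0.252, 0.2016, 0.3024, "beta"),
    p("sub_prop_nivolumab_C", 0.071, 0.0568, 0.0852, "beta"),
    p("sub_prop_camrelizumab_C", 0.622, 0.4976, 0.7464, "beta"),
    p("sub_prop_supportive_C", 0.055, 0.044, 0.066, "beta"),
    p("cost_monitoring_cycle", 102.50, 82.00, 123.00, "gamma"),
    p("cost_pdl1_test", 48.50, 38.80, 58.20, "gamma"),
    p("cost_terminal_care", 2464.50, 1971.60, 2957.40, "gamma"),
    p("discount_rate", 0.05, 0, 0.08, "none"))
}

#' Economic model configuration
#'
#' Bundles the parameter table with structural treatment settings: 5
#' induction cycles (combination: camrelizumab + pemetrexed + carboplatin;
#' control: pemetrexed + carboplatin) followed by maintenance (camrelizumab +
#' pemetrexed, or pemetrexed alone), camrelizumab exposure capped at 2 years
#' (34 complete 21-day cycles), and the willingness-to-pay threshold of
#' $32,457 per QALY (3x China 2020 GDP per capita). Per-mg prices and dosing
#' constants (BSA 1.80 m2, weight 65 kg, creatinine clearance 90 ml/min) are
#' carried as metadata; the printed per-cycle costs are authoritative for the
#' base case because the per-mg arithmetic does not reproduce them exactly
#' (500 mg/m2 x 1.80 m2 x 0.86 $/mg = 774, not 740).
#'
#' @param params parameter table as from [econ_parameters()]; any subset of
#'   values may be overridden via `...` as `name = value`.
#' @param induction_cycles number of induction cycles.
#' @param cam_cap_cycles camrelizumab exposure cap, in cycles.
#' @param wtp willingness-to-pay threshold, $/QALY.
#' @param monitoring_pfs_only restrict monitoring cost to the
#'   progression-free state (default: while alive in either state).
#' @param ... scalar overrides of parameter values by name.
#' @return an object of class `econ_config`.
#' @export
econ_config <- function(params = econ_parameters(),
                        induction_cycles = 5L,
                        cam_cap_cycles = 34L,
                        wtp = 32457,
                        monitoring_pfs_only = FALSE, ...) {
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% params$name)
      stop("unknown economic parameter: ", nm, call. = FALSE)
    params$value[params$name == nm] <- over[[nm]]
  }
  cfg <- structure(list(params = params,
                        induction_cycles = as.integer(induction_cycles),
                        cam_cap_cycles = as.integer(cam_cap_cycles),
                        wtp = wtp,
                        monitoring_pfs_only = isTRUE(monitoring_pfs_only),
                        drug_price_mg = c(camrelizumab = 2.26,
                                          pemetrexed = 0.86,
                                          carboplatin = 0.16,
                                          nivolumab = 14.30, docetaxel = 3.00),
                        dosing = c(bsa_m2 = 1.80, weight_kg = 65,
                                   ccr_ml_min = 90),
                        cny_per_usd = 6.47),
                   class = "econ_config")
  validate_econ_config(cfg)
  cfg
}

validate_econ_config <- function(cfg) {
  pr <- cfg$params
  costs <- grepl("^cost_|^sub_cost_", pr$name)
  if (any(pr$value[costs] < 0))
    stop("costs must be non-negative", call. = FALSE)
  props <- grepl("^risk_|^sub_prop_|^u_", pr$name)
  if (any(pr$value[props] < 0 | pr$value[props] > 1))
    stop("probabilities, proportions and utilities must lie in [0,1]",
         call. = FALSE)
  if (ep(cfg, "u_pd") > ep(cfg, "u_pfs"))
    stop("u_pd must not exceed u_pfs", call. = FALSE)
  for (arm in c("CC", "C")) {
    tot <- sum(pr$value[grepl(paste0("^sub_prop_.*_", arm, "$"), pr$name)])
    if (abs(tot - 1) > 0.02)
      message(sprintf("note: %s subsequent-therapy proportions sum to %.3f",
                      arm, tot))
  }
  invisible(cfg)
}

# parameter lookup by name
ep <- function(cfg, name) {
  i <- match(name, cfg$params$name)
  if (is.na(i)) stop("unknown economic parameter: ", name, call. = FALSE)
  cfg$params$value[i]
}

#' Set one economic parameter (returns a modified config)
#' @param cfg an [econ_config()].
#' @param name parameter name (row of `cfg$params`).
#' @param value new value.
#' @export
set_param <- function(cfg, name, value) {
  i <- match(name, cfg$params$name)
  if (is.na(i)) stop("unknown economic parameter: ", name, call. = FALSE)
  cfg$params$value[i] <- value
  cfg
}

ae_events <- c("neutropenia", "anaemia", "thrombocytopenia")

#' One-time adverse-event burden of an arm
#'
#' Expected first-cycle cost and QALY decrement from grade >= 3 adverse
#' events: each event's incidence multiplied by its unit cost and by its
#' disutility, summed over events.
#'
#' @param risks named per-event incidences in \[0,1\].
#' @param unit_costs named per-event costs ($/event).
#' @param disutilities named per-event utility decrements (<= 0).
#' @return list with `cost` ($) and `disutility` (<= 0).
#' @export
ae_burden <- function(risks, unit_costs, disutilities) {
  if (!setequal(names(risks), names(unit_costs)) ||
      !setequal(names(risks), names(disutilities)))
    stop("ae_burden: event lists do not match", call. = FALSE)
  if (any(risks < 0 | risks > 1))
    stop("ae_burden: risks must lie in [0,1]", call. = FALSE)
  nm <- names(risks)
  list(cost = sum(risks * unit_costs[nm]),
       disutility = sum(risks * disutilities[nm]))
}

arm_ae_burden <- function(cfg, arm) {
  ae_burden(
    risks = setNames(vapply(ae_events, function(e)
      ep(cfg, paste0("risk_", e, "_", arm)), numeric(1)), ae_events),
    unit_costs = setNames(vapply(ae_events, function(e)
      ep(cfg, paste0("cost_", e)), numeric(1)), ae_events),
    disutilities = setNames(vapply(ae_events, function(e)
      ep(cfg, paste0("disutility_", e)), numeric(1)), ae_events))
}

#' Expected subsequent-therapy cost per progressed cycle
#'
#' @param mix data.frame with columns `cost` ($/cycle) and `proportion`.
#' @return $ per cycle: `sum(cost * proportion)`.
#' @export
subsequent_cost_per_cycle <- function(mix) {
  if (any(mix$proportion < 0 | mix$proportion > 1))
    stop("proportions must lie in [0,1]", call. = FALSE)
  sum(mix$cost * mix$proportion)
}

subsequent_mix <- function(cfg, arm) {
  opts <- if (arm == "CC") c("docetaxel", "supportive")
          else c("docetaxel", "nivolumab", "camrelizumab", "supportive")
  data.frame(
    therapy = opts,
    cost = vapply(opts, function(o) ep(cfg, paste0("sub_cost_", o)), numeric(1)),
    proportion = vapply(opts, function(o)
      ep(cfg, paste0("sub_prop_", o, "_", arm)), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Active-treatment drug cost of a cycle
#'
#' Combination arm: camrelizumab + pemetrexed + carboplatin during induction,
#' then camrelizumab + pemetrexed maintenance, with the camrelizumab
#' component zeroed once cumulative exposure reaches the 2-year cap (34
#' complete cycles). Control arm: pemetrexed + carboplatin induction, then
#' pemetrexed maintenance.
#'
#' @param arm `"CC"` or `"C"`.
#' @param cycle_index 1-based treatment cycle number (vectorized).
#' @param cfg an [econ_config()].
#' @return $ per cycle.
#' @export
cycle_drug_cost <- function(arm, cycle_index, cfg) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  if (!arm %in% c("CC", "C")) stop("unknown arm: ", arm, call. = FALSE)
  cam <- ep(cfg, "cost_cycle_camrelizumab")
  pem <- ep(cfg, "cost_cycle_pemetrexed")
  carb <- ep(cfg, "cost_cycle_carboplatin")
  induction <- cycle_index <= cfg$induction_cycles
  base <- pem + carb * induction
  if (arm == "CC") base + cam * (cycle_index <= cfg$cam_cap_cycles) else base
}

#' Accumulate discounted lifetime costs (and effects) of one arm
#'
#' Per cycle: active drug cost weighted by progression-free occupancy,
#' subsequent-therapy cost weighted by progressed occupancy, monitoring
#' while alive, and terminal care weighted by the cycle's incident deaths,
#' all discounted; plus one-time PD-L1 test and adverse-event costs in the
#' first cycle. The itemized ledger (initial drugs, maintenance drugs, AE,
#' subsequent therapy, monitoring, PD-L1, terminal care) sums exactly to the
#' total. Effects come from [accumulate_effects()] with the arm's one-time
#' AE disutility.
#'
#' @param trace a [state_occupancy()] trace.
#' @param arm `"CC"` or `"C"`.
#' @param cfg an [econ_config()].
#' @param config the [model_config()] used for the trace (defaults to the
#'   trace's own); its utilities and discount rate are taken as-is except
#'   that the arm's AE disutility replaces `one_time_disutility`.
#' @return an object of class `arm_result`.
#' @export
accumulate_costs <- function(trace, arm, cfg, config = attr(trace, "config")) {
  stopifnot(inherits(trace, "state_trace"), inherits(cfg, "econ_config"))
  ae <- arm_ae_burden(cfg, arm)
  cyc1 <- trace$cycle + 1L       # treatment cycle number, 1-based
  disc <- trace$discount
  drug <- cycle_drug_cost(arm, cyc1, cfg) * trace$p_pfs * disc
  induction <- cyc1 <= cfg$induction_cycles
  sub_rate <- subsequent_cost_per_cycle(subsequent_mix(cfg, arm))
  monitor_occ <- if (cfg$monitoring_pfs_only) trace$p_pfs
                 else trace$p_pfs + trace$p_pd
  items <- c(
    initial_drugs = sum(drug[induction]),
    maintenance_drugs = sum(drug[!induction]),
    ae = ae$cost * disc[1],
    subsequent = sum(sub_rate * trace$p_pd * disc),
    monitoring = sum(ep(cfg, "cost_monitoring_cycle") * monitor_occ * disc),
    pdl1 = ep(cfg, "cost_pdl1_test") * disc[1],
    terminal = sum(ep(cfg, "cost_terminal_care") * trace$incident_death * disc))
  undisc <- c(
    initial_drugs = sum((cycle_drug_cost(arm, cyc1, cfg) * trace$p_pfs)[induction]),
    maintenance_drugs = sum((cycle_drug_cost(arm, cyc1, cfg) * trace$p_pfs)[!induction]),
    ae = ae$cost,
    subsequent = sum(sub_rate * trace$p_pd),
    monitoring = sum(ep(cfg, "cost_monitoring_cycle") * monitor_occ),
    pdl1 = ep(cfg, "cost_pdl1_test"),
    terminal = sum(ep(cfg, "cost_terminal_care") * trace$incident_death))
  mc <- config
  mc$u_pfs <- ep(cfg, "u_pfs"); mc$u_pd <- ep(cfg, "u_pd")
  mc$one_time_disutility <- ae$disutility
  eff <- accumulate_effects(trace, mc)
  structure(list(arm = arm,
                 total_cost_disc = sum(items),
                 total_cost_undisc = sum(undisc),
                 ly_disc = eff$ly_disc, qaly_disc = eff$qaly_disc,
                 ly_undisc = eff$ly_undisc, qaly_undisc = eff$qaly_undisc,
                 items = items, items_undisc = undisc,
                 ae_disutility = ae$disutility),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s: cost $%.2f  LY %.3f  QALY %.3f (discounted)\n",
              x$arm, x$total_cost_disc, x$ly_disc, x$qaly_disc))
  it <- x$items
  for (nm in names(it))
    cat(sprintf("  %-18s $%10.2f\n", nm, it[[nm]]))
  invisible(x)
}

#' Write an itemized arm result as delimited text
#' @param res an `arm_result`.
#' @param path output CSV.
#' @export
write_arm_result <- function(res, path) {
  df <- data.frame(arm = res$arm,
                   item = c(names(res$items), "total", "ly", "qaly"),
                   discounted = c(unname(res$items), res$total_cost_disc,
                                  res$ly_disc, res$qaly_disc),
                   undiscounted = c(unname(res$items_undisc),
                                    res$total_cost_undisc,
                                    res$ly_undisc, res$qaly_undisc))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
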