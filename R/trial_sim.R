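#' Specify a synthetic two-arm trial
#'
#' Defines the generating process for a two-arm trial with PFS and OS
#' endpoints, used to exercise the full reconstruction-fitting-modelling
#' pipeline when the original digitized curves are unavailable. Defaults
#' emulate a first-line trial of camrelizumab plus chemotherapy ("CC") versus
#' chemotherapy ("C") in advanced non-squamous NSCLC: median PFS 11.3 vs 8.3
#' months, median OS 27.9 vs 20.5 months, with the OS of the combination arm
#' log-normal, the OS of the chemotherapy arm log-logistic, and PFS log-normal
#' in both arms.
#'
#' When `joint = TRUE` each subject's OS time is drawn first and PFS is taken
#' as the minimum of OS and a latent progression time drawn from the PFS
#' family, so PFS <= OS holds per subject by construction, as it must for a
#' partitioned-survival model. When `joint = FALSE` each endpoint is drawn
#' independently from its marginal family (useful for parameter-recovery
#' studies on a single endpoint).
#'
#' Censoring is administrative: subjects accrue uniformly over
#' `accrual_months` and are censored `followup_months` after the start of
#' accrual, i.e. at `followup_months - entry`. Set `accrual_months = 0` for a
#' sharp cutoff, or `followup_months = Inf` for no censoring.
#'
#' @param n_per_arm named integer vector of arm sizes; names are arm labels.
#' @param os,pfs named lists (one entry per arm) of `list(family, params)`
#'   generating distributions, times in months. Families and parameter names
#'   follow [survival_at()].
#' @param followup_months administrative follow-up from start of accrual.
#' @param accrual_months width of the uniform accrual window.
#' @param joint draw PFS as `min(OS, latent progression)`?
#' @param seed integer seed; identical specs give identical data.
#' @return an object of class `trial_spec`.
#' @export
trial_spec <- function(n_per_arm = c(CC = 205L, C = 207L),
                       os = list(
                         CC = list(family = "lognormal",
                                   params = c(meanlog = log(27.9), sdlog = 0.8)),
                         C = list(family = "loglogistic",
                                  params = c(shape = 1.6, scale = 20.5))),
                       pfs = list(
                         CC = list(family = "lognormal",
                                   params = c(meanlog = log(11.3), sdlog = 0.8)),
                         C = list(family = "lognormal",
                                  params = c(meanlog = log(8.3), sdlog = 0.8))),
                       followup_months = 30,
                       accrual_months = 12,
                       joint = TRUE,
                       seed = 1L) {
  if (is.null(names(n_per_arm)) || any(!nzchar(names(n_per_arm))))
    stop("n_per_arm must be a named vector of arm sizes", call. = FALSE)
  if (any(n_per_arm < 0))
    stop("n_per_arm must be non-negative", call. = FALSE)
  arms <- names(n_per_arm)
  for (ep in list(os = os, pfs = pfs)) {
    missing_arm <- setdiff(arms, names(ep))
    if (length(missing_arm))
      stop("missing generating distribution for arm(s): ",
           paste(missing_arm, collapse = ", "), call. = FALSE)
  }
  for (nm in arms) {
    check_family_params(os[[nm]]$family, os[[nm]]$params)
    check_family_params(pfs[[nm]]$family, pfs[[nm]]$params)
  }
  if (followup_months <= 0) stop("followup_months must be > 0", call. = FALSE)
  if (accrual_months < 0) stop("accrual_months must be >= 0", call. = FALSE)
  structure(list(n_per_arm = n_per_arm, os = os, pfs = pfs,
                 followup_months = followup_months,
                 accrual_months = accrual_months,
                 joint = isTRUE(joint), seed = as.integer(seed)),
            class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat("Synthetic two-arm trial specification\n")
  for (nm in names(x$n_per_arm)) {
    cat(sprintf("  arm %-3s n=%d  OS: %s(%s)  PFS: %s(%s)\n", nm,
                x$n_per_arm[[nm]],
                x$os[[nm]]$family, fmt_params(x$os[[nm]]$params),
                x$pfs[[nm]]$family, fmt_params(x$pfs[[nm]]$params)))
  }
  cat(sprintf("  follow-up %s months, accrual %s months, %s, seed %d\n",
              format(x$followup_months), format(x$accrual_months),
              if (x$joint) "joint PFS<=OS" else "independent endpoints",
              x$seed))
  invisible(x)
}

fmt_params <- function(p) paste(sprintf("%s=%.3g", names(p), p), collapse = ", ")

# Under joint generation PFS = min(OS, latent progression), so drawing the
# latent time from the marginal PFS family would shift the realized PFS
# median below the stated target. Rescale the latent distribution so that
# S_os(m) * S_latent(m) = 1/2 exactly at the target marginal median m.
calibrate_latent <- function(os, pfs) {
  m <- family_median(pfs$family, pfs$params)
  s_os <- surv_prob(os$family, os$params, m)
  q <- 0.5 / s_os          # survival the latent distribution needs at m
  if (q >= 1)
    stop("joint calibration impossible: OS median below the PFS target",
         call. = FALSE)
  p <- pfs$params
  p2 <- switch(pfs$family,
    exponential = c(rate = unname(-log(q) / m)),
    weibull = c(shape = unname(p[["shape"]]),
                scale = unname(m / (-log(q))^(1 / p[["shape"]]))),
    gompertz = {
      a <- p[["shape"]]
      c(shape = unname(a), rate = unname(-log(q) * a / (exp(a * m) - 1)))
    },
    loglogistic = c(shape = unname(p[["shape"]]),
                    scale = unname(m * (q / (1 - q))^(1 / p[["shape"]]))),
    lognormal = c(meanlog = unname(log(m) - p[["sdlog"]] * stats::qnorm(1 - q)),
                  sdlog = unname(p[["sdlog"]])),
    gengamma = {
      tq <- flexsurv::qgengamma(1 - q, mu = 0, sigma = p[["sigma"]],
                                Q = p[["Q"]])
      c(mu = unname(log(m) - log(tq)), sigma = unname(p[["sigma"]]),
        Q = unname(p[["Q"]]))
    })
  list(family = pfs$family, params = p2)
}

family_median <- function(family, params) {
  p <- params
  switch(family,
    exponential = log(2) / p[["rate"]],
    weibull = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    gompertz = log(1 + p[["shape"]] * log(2) / p[["rate"]]) / p[["shape"]],
    loglogistic = p[["scale"]],
    lognormal = exp(p[["meanlog"]]),
    gengamma = flexsurv::qgengamma(0.5, mu = p[["mu"]], sigma = p[["sigma"]],
                                   Q = p[["Q"]]))
}

# random draws from a named survival family (times in months)
rsurv_family <- function(family, params, n) {
  check_family_params(family, params)
  switch(family,
    exponential = stats::rexp(n, rate = params[["rate"]]),
    weibull = stats::rweibull(n, shape = params[["shape"]],
                              scale = params[["scale"]]),
    gompertz = flexsurv::rgompertz(n, shape = params[["shape"]],
                                   rate = params[["rate"]]),
    loglogistic = flexsurv::rllogis(n, shape = params[["shape"]],
                                    scale = params[["scale"]]),
    lognormal = stats::rlnorm(n, meanlog = params[["meanlog"]],
                              sdlog = params[["sdlog"]]),
    gengamma = flexsurv::rgengamma(n, mu = params[["mu"]],
                                   sigma = params[["sigma"]],
                                   Q = params[["Q"]]))
}

# deterministic per-arm seed stream; endpoints share subjects so PFS<=OS holds
arm_seed <- function(seed, arm_index) {
  as.integer((as.double(seed) * 48271 + arm_index * 7919) %% 2147483629)
}

sim_arm_subjects <- function(spec, arm) {
  idx <- match(arm, names(spec$n_per_arm))
  if (is.na(idx)) stop("unknown arm: ", arm, call. = FALSE)
  n <- spec$n_per_arm[[idx]]
  out <- list()
  if (n == 0L) {
    return(list(os = numeric(0), pfs = numeric(0), censor = numeric(0)))
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(arm_seed(spec$seed, idx))
  os_t <- rsurv_family(spec$os[[arm]]$family, spec$os[[arm]]$params, n)
  lat <- if (spec$joint) calibrate_latent(spec$os[[arm]], spec$pfs[[arm]])
         else spec$pfs[[arm]]
  latent <- rsurv_family(lat$family, lat$params, n)
  pfs_t <- if (spec$joint) pmin(os_t, latent) else latent
  entry <- if (spec$accrual_months > 0) {
    stats::runif(n, 0, spec$accrual_months)
  } else rep(0, n)
  list(os = os_t, pfs = pfs_t, censor = spec$followup_months - entry)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate one arm and endpoint of a synthetic trial
#'
#' Draws individual patient data (IPD) for one arm/endpoint under the
#' generating process in `spec`, applying administrative censoring. The same
#' spec (including its seed) always produces the same records; PFS and OS of
#' an arm share the same subjects, so with `joint = TRUE` every subject's PFS
#' time is at most their OS time.
#'
#' @param spec a [trial_spec()].
#' @param arm arm label present in `spec$n_per_arm`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @return a data.frame with columns `time` (months), `event` (1 event,
#'   0 censored), `arm`, `endpoint`.
#' @export
simulate_arm <- function(spec, arm, endpoint = c("OS", "PFS")) {
  stopifnot(inherits(spec, "trial_spec"))
  endpoint <- match.arg(endpoint)
  subj <- sim_arm_subjects(spec, arm)
  true_t <- if (endpoint == "OS") subj$os else subj$pfs
  if (length(true_t) == 0L) {
    return(data.frame(time = numeric(0), event = integer(0),
                      arm = character(0), endpoint = character(0)))
  }
  obs <- pmin(true_t, subj$censor)
  data.frame(time = obs,
             event = as.integer(true_t <= subj$censor),
             arm = arm, endpoint = endpoint,
             stringsAsFactors = FALSE)
}

#' Simulate the full trial (all arms, both endpoints)
#'
#' @param spec a [trial_spec()].
#' @return one data.frame of IPD records (time, event, arm, endpoint).
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  do.call(rbind, lapply(names(spec$n_per_arm), function(a)
    rbind(simulate_arm(spec, a, "OS"), simulate_arm(spec, a, "PFS"))))
}

#' Kaplan-Meier step coordinates and risk table from IPD
#'
#' Computes the product-limit estimate (via [survival::survfit()]) and
#' renders it as a digitized-curve object: step coordinates `(time,
#' survival)` anchored at (0, 1), plus a numbers-at-risk table at the
#' requested times. This is both the export format of the synthetic trial
#' generator and the round-trip oracle for the pseudo-IPD reconstruction.
#'
#' @param records IPD data.frame with `time` and `event` columns (a single
#'   arm/endpoint).
#' @param risk_times times (months) at which numbers at risk are tabulated.
#' @return a [digitized_curve()].
#' @export
km_from_ipd <- function(records, risk_times = NULL) {
  if (is.null(records) || nrow(records) == 0L)
    stop("km_from_ipd: no records supplied", call. = FALSE)
  if (is.null(risk_times))
    risk_times <- seq(0, max(records$time), by = 3)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  tt <- fit$time
  ss <- fit$surv
  # keep the steps (event times) plus the final observed time so the curve
  # extends over the full observation window
  keep <- fit$n.event > 0
  keep[length(keep)] <- TRUE
  pts <- data.frame(time = c(0, tt[keep]), survival = c(1, ss[keep]))
  pts <- pts[!duplicated(pts$time), , drop = FALSE]
  risk_times <- risk_times[risk_times <= max(records$time)]
  risk <- data.frame(time = risk_times,
                     n_at_risk = vapply(risk_times, function(t)
                       sum(records$time >= t), integer(1)))
  digitized_curve(points = pts, risk_table = risk,
                  arm = if ("arm" %in% names(records)) records$arm[1] else NA,
                  endpoint = if ("endpoint" %in% names(records))
                    records$endpoint[1] else NA,
                  total_events = sum(records$event))
}

#' Write IPD records as 4-column delimited text
#' @param records IPD data.frame (time, event, arm, endpoint).
#' @param path output file.
#' @export
write_ipd <- function(records, path) {
  utils::write.csv(records[, c("time", "event", "arm", "endpoint")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read IPD records written by [write_ipd()]
#' @param path input file.
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "event", "arm", "endpoint")
  if (!all(need %in% names(df)))
    stop("IPD file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
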