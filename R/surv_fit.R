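#' @importFrom stats pnorm dnorm qnorm setNames AIC BIC optim runif
NULL

# the six candidate families, in the documented tie-break order
SURV_FAMILIES <- c("exponential", "weibull", "gompertz", "loglogistic",
                   "lognormal", "gengamma")

FAMILY_NPAR <- c(exponential = 1L, weibull = 2L, gompertz = 2L,
                 loglogistic = 2L, lognormal = 2L, gengamma = 3L)

FAMILY_PARNAMES <- list(
  exponential = "rate",
  weibull = c("shape", "scale"),
  gompertz = c("shape", "rate"),
  loglogistic = c("shape", "scale"),
  lognormal = c("meanlog", "sdlog"),
  gengamma = c("mu", "sigma", "Q"))

# flexsurv's dist codes for the same parameterizations
FAMILY_FLEXSURV <- c(exponential = "exp", weibull = "weibull",
                     gompertz = "gompertz", loglogistic = "llogis",
                     lognormal = "lnorm", gengamma = "gengamma")

check_family_params <- function(family, params) {
  if (!family %in% SURV_FAMILIES)
    stop("unknown survival family: ", family, call. = FALSE)
  need <- FAMILY_PARNAMES[[family]]
  if (!all(need %in% names(params)))
    stop(sprintf("%s requires parameters: %s", family,
                 paste(need, collapse = ", ")), call. = FALSE)
  pos <- switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    gompertz = "rate",            # shape may be negative (decreasing hazard)
    loglogistic = c("shape", "scale"),
    lognormal = "sdlog",
    gengamma = "sigma")           # mu and Q unrestricted
  bad <- pos[params[pos] <= 0]
  if (length(bad))
    stop(sprintf("%s parameter(s) out of domain (must be > 0): %s", family,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# S(t) under the documented parameterizations:
#   exponential  S = exp(-rate t)
#   weibull      S = exp(-(t/scale)^shape)
#   gompertz     S = exp(-(rate/shape)(exp(shape t) - 1))
#   loglogistic  S = 1 / (1 + (t/scale)^shape)
#   lognormal    S = 1 - Phi((ln t - meanlog)/sdlog)
#   gengamma     three-parameter (mu, sigma, Q) form
surv_prob <- function(family, params, t) {
  check_family_params(family, params)
  p <- params
  out <- switch(family,
    exponential = exp(-p[["rate"]] * t),
    weibull = exp(-(t / p[["scale"]])^p[["shape"]]),
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) exp(-b * t) else exp(-(b / a) * (exp(a * t) - 1))
    },
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal = ifelse(t <= 0, 1,
                       1 - pnorm((log(pmax(t, 1e-300)) - p[["meanlog"]]) /
                                   p[["sdlog"]])),
    gengamma = flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                   Q = p[["Q"]], lower.tail = FALSE))
  out[t == 0] <- 1
  pmin(pmax(out, 0), 1)
}

# log f(t); vectorized over t > 0
surv_logdens <- function(family, params, t) {
  p <- params
  switch(family,
    exponential = log(p[["rate"]]) - p[["rate"]] * t,
    weibull = stats::dweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                              log = TRUE),
    gompertz = flexsurv::dgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                   log = TRUE),
    loglogistic = flexsurv::dllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]], log = TRUE),
    lognormal = stats::dlnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                              log = TRUE),
    gengamma = flexsurv::dgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                   Q = p[["Q"]], log = TRUE))
}

#' Right-censored log-likelihood of a parametric survival family
#'
#' Sum of `log f(t)` over events plus `log S(t)` over censored records, under
#' the package's documented parameterizations (see [survival_at()]).
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`, `"gengamma"`.
#' @param params named parameter vector for the family.
#' @param records IPD data.frame with `time` (> 0) and `event` columns.
#' @return the log-likelihood (finite real).
#' @export
log_likelihood <- function(family, params, records) {
  check_family_params(family, params)
  if (is.null(records) || nrow(records) == 0L)
    stop("log_likelihood: no records", call. = FALSE)
  if (any(records$time <= 0))
    stop("log_likelihood: times must be strictly positive", call. = FALSE)
  ev <- records$event == 1
  ll <- 0
  if (any(ev)) ll <- ll + sum(surv_logdens(family, params, records$time[ev]))
  if (any(!ev)) {
    st <- surv_prob(family, params, records$time[!ev])
    ll <- ll + sum(log(pmax(st, 1e-300)))
  }
  ll
}

#' Fit one parametric survival family by maximum likelihood
#'
#' Fits right-censored IPD with [flexsurv::flexsurvreg()] and packages the
#' result with the bookkeeping the selection step needs: natural-scale
#' parameters under the documented parameterizations, log-likelihood, and
#' AIC/BIC with `k` the parameter count and BIC's `n` the number of subjects.
#' Optimizer failure is never silent: the returned fit carries
#' `converged = FALSE` and the captured diagnostic message.
#'
#' @inheritParams log_likelihood
#' @return an object of class `parametric_fit`.
#' @export
fit_distribution <- function(family, records) {
  if (!family %in% SURV_FAMILIES)
    stop("unknown survival family: ", family, call. = FALSE)
  if (is.null(records) || nrow(records) == 0L)
    stop("fit_distribution: no records", call. = FALSE)
  if (any(records$time <= 0))
    stop("fit_distribution: times must be strictly positive", call. = FALSE)
  n <- nrow(records)
  n_events <- sum(records$event == 1)
  k <- FAMILY_NPAR[[family]]
  few_events <- n_events < 5
  fit <- tryCatch(
    suppressWarnings(flexsurv::flexsurvreg(
      survival::Surv(time, event) ~ 1, data = records,
      dist = FAMILY_FLEXSURV[[family]])),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(family = family,
                          params = setNames(rep(NA_real_, k),
                                            FAMILY_PARNAMES[[family]]),
                          log_likelihood = NA_real_, aic = NA_real_,
                          bic = NA_real_, n_subjects = n, n_events = n_events,
                          converged = FALSE, few_events = few_events,
                          message = conditionMessage(fit)),
                     class = "parametric_fit"))
  }
  params <- setNames(fit$res[, "est"], FAMILY_PARNAMES[[family]])
  ll <- fit$loglik
  conv <- is.finite(ll) &&
    (is.null(fit$opt$convergence) || fit$opt$convergence == 0)
  structure(list(family = family, params = params, log_likelihood = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n_subjects = n, n_events = n_events,
                 converged = conv, few_events = few_events, message = NULL),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("Parametric survival fit: %s (%s)\n", x$family,
              if (x$converged) "converged" else "NOT converged"))
  cat("  ", fmt_params(x$params), "\n", sep = "")
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f  (n=%d, events=%d)\n",
              x$log_likelihood, x$aic, x$bic, x$n_subjects, x$n_events))
  invisible(x)
}

#' Evaluate a fitted survival function
#'
#' @param fit a [parametric_fit()] — or any list with `family` and `params`.
#' @param t times (months), `t >= 0`; vectorized.
#' @return survival probabilities in \[0, 1\], with `S(0) = 1`.
#' @export
survival_at <- function(fit, t) {
  if (any(t < 0)) stop("survival_at: t must be >= 0", call. = FALSE)
  surv_prob(fit$family, fit$params, t)
}

#' Fit all six families to one arm/endpoint
#'
#' @param records IPD data.frame for a single arm/endpoint.
#' @param families subset of the six families (default all).
#' @return named list of [parametric_fit] objects.
#' @export
fit_all_families <- function(records, families = SURV_FAMILIES) {
  setNames(lapply(families, fit_distribution, records = records), families)
}

#' Select the best fit by information criterion
#'
#' Returns the converged fit minimizing AIC (or BIC). Ties are broken first
#' by parameter count (fewer wins), then by the fixed family order
#' exponential, weibull, gompertz, loglogistic, lognormal, gengamma. When AIC
#' and BIC disagree on the winner a message is emitted (never silently
#' resolved); the full ranked table stays available via [fit_table()].
#'
#' @param fits list of [parametric_fit] objects.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @return the selected `parametric_fit`.
#' @export
select_best <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv))
    stop("select_best: no converged fits to select from", call. = FALSE)
  pick <- function(crit) {
    vals <- vapply(conv, function(f) f[[crit]], numeric(1))
    npar <- vapply(conv, function(f) FAMILY_NPAR[[f$family]], integer(1))
    fam_rank <- match(vapply(conv, function(f) f$family, character(1)),
                      SURV_FAMILIES)
    conv[[order(vals, npar, fam_rank)[1]]]
  }
  best <- pick(criterion)
  other <- pick(setdiff(c("aic", "bic"), criterion))
  if (!identical(best$family, other$family))
    message(sprintf("select_best: AIC and BIC disagree (%s vs %s); using %s by %s",
                    best$family, other$family, best$family, criterion))
  best
}

#' Tabulate a set of fits (the goodness-of-fit table)
#'
#' @param fits list of [parametric_fit] objects.
#' @return data.frame with family, parameters, logLik, AIC, BIC, converged.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    family = f$family,
    parameters = fmt_params(f$params),
    logLik = f$log_likelihood, AIC = f$aic, BIC = f$bic,
    n = f$n_subjects, events = f$n_events, converged = f$converged,
    stringsAsFactors = FALSE)))
}

#' Fit and select survival models for every arm/endpoint
#'
#' Runs [fit_all_families()] and [select_best()] on each (arm, endpoint)
#' stratum of an IPD table, retaining the full six-fit tables for reporting.
#'
#' @param ipd IPD data.frame with time, event, arm, endpoint columns.
#' @param criterion selection criterion, `"aic"` or `"bic"`.
#' @return an object of class `model_set`: per-stratum `fits` (all six),
#'   `selected`, and the selection criterion.
#' @export
build_model_set <- function(ipd, criterion = "aic") {
  strata <- unique(ipd[, c("arm", "endpoint")])
  key <- function(a, e) paste(a, e, sep = ".")
  fits <- list(); selected <- list()
  for (r in seq_len(nrow(strata))) {
    a <- strata$arm[r]; e <- strata$endpoint[r]
    rec <- ipd[ipd$arm == a & ipd$endpoint == e, , drop = FALSE]
    ff <- fit_all_families(rec)
    fits[[key(a, e)]] <- ff
    selected[[key(a, e)]] <- select_best(ff, criterion)
  }
  structure(list(fits = fits, selected = selected, criterion = criterion),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("Survival model set (criterion:", toupper(x$criterion), ")\n")
  for (nm in names(x$selected)) {
    f <- x$selected[[nm]]
    cat(sprintf("  %-8s -> %-12s AIC %.2f  BIC %.2f\n", nm, f$family,
                f$aic, f$bic))
  }
  invisible(x)
}

#' Selected fit for one arm/endpoint
#' @param ms a `model_set`.
#' @param arm,endpoint stratum labels.
#' @export
selected_fit <- function(ms, arm, endpoint) {
  f <- ms$selected[[paste(arm, endpoint, sep = ".")]]
  if (is.null(f))
    stop(sprintf("no selected fit for (%s, %s)", arm, endpoint), call. = FALSE)
  f
}

#' Overlay data: KM steps plus each fitted survival curve on a grid
#'
#' Emits plot-ready data for visual inspection of fit quality (the analogue
#' of superimposing fitted curves on the trial KM plot).
#'
#' @param curve a [digitized_curve()] (the KM reference).
#' @param fits list of [parametric_fit] objects.
#' @param times evaluation grid (months); default 0 to twice the curve end.
#' @return data.frame with columns time, survival, source (`km` or a family).
#' @export
overlay_data <- function(curve, fits, times = NULL) {
  if (is.null(times))
    times <- seq(0, 2 * max(curve$points$time), length.out = 201)
  km <- data.frame(time = curve$points$time, survival = curve$points$survival,
                   source = "km", stringsAsFactors = FALSE)
  fitted <- do.call(rbind, lapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    data.frame(time = times, survival = survival_at(f, times),
               source = f$family, stringsAsFactors = FALSE)
  }))
  rbind(km, fitted)
}
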