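#' A digitized Kaplan-Meier curve with its numbers-at-risk table
#'
#' Container for one endpoint/arm's digitized survival coordinates and the
#' published numbers-at-risk table, the two ingredients of pseudo-IPD
#' reconstruction.
#'
#' @param points data.frame with columns `time` (months, non-negative,
#'   strictly increasing) and `survival` (in \[0, 1\]).
#' @param risk_table data.frame with columns `time` and `n_at_risk`
#'   (non-increasing counts at strictly increasing times).
#' @param arm,endpoint labels carried through to reconstructed records.
#' @param total_events optional total event count reported alongside the
#'   curve; used to pin down censoring in the final interval.
#' @return an object of class `digitized_curve`.
#' @export
digitized_curve <- function(points, risk_table, arm = NA, endpoint = NA,
                            total_events = NULL) {
  stopifnot(is.data.frame(points), all(c("time", "survival") %in% names(points)),
            is.data.frame(risk_table),
            all(c("time", "n_at_risk") %in% names(risk_table)))
  # raw digitizer output may carry tied times and pixel overshoot; those are
  # repaired by clean_curve, so only outright corruption is rejected here
  if (any(diff(points$time) < 0))
    stop("digitized point times must be non-decreasing", call. = FALSE)
  if (any(points$survival < -0.05 | points$survival > 1.05))
    stop("survival values must lie in [0, 1]", call. = FALSE)
  if (nrow(risk_table) > 1 && any(diff(risk_table$time) <= 0))
    stop("risk-table times must be strictly increasing", call. = FALSE)
  if (nrow(risk_table) > 1 && any(diff(risk_table$n_at_risk) > 0))
    stop("numbers at risk must be non-increasing", call. = FALSE)
  structure(list(points = points, risk_table = risk_table,
                 arm = arm, endpoint = endpoint,
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized KM curve [%s / %s]: %d points over %.1f months, %d risk-table rows\n",
              x$arm, x$endpoint, nrow(x$points), max(x$points$time),
              nrow(x$risk_table)))
  if (!is.null(x$total_events))
    cat(sprintf("  reported events: %d\n", x$total_events))
  invisible(x)
}

#' Repair digitization noise in a KM curve
#'
#' Digitizer output is noisy: survival may wobble upwards by a pixel, exceed
#' 1, or miss the (0, 1) anchor. This clamps the curve to a valid KM shape:
#' tied times are merged keeping the lower survival value, survival is
#' clipped to \[0, 1\] and made monotone non-increasing (each value capped at
#' its predecessor), and a (0, 1) anchor is prepended when absent. Already
#' clean curves pass through unchanged.
#'
#' @param raw a [digitized_curve()].
#' @return a cleaned `digitized_curve`.
#' @export
clean_curve <- function(raw) {
  stopifnot(inherits(raw, "digitized_curve"))
  pts <- raw$points[order(raw$points$time), , drop = FALSE]
  if (nrow(pts) < 2)
    stop("clean_curve: need at least 2 digitized points", call. = FALSE)
  if (all(pts$survival == 0))
    stop("clean_curve: all survival values are 0", call. = FALSE)
  # merge ties at identical times, keeping the lower (later) survival value
  if (anyDuplicated(pts$time)) {
    s <- tapply(pts$survival, pts$time, min)
    pts <- data.frame(time = as.numeric(names(s)), survival = as.numeric(s))
    pts <- pts[order(pts$time), , drop = FALSE]
  }
  pts$survival <- pmin(pmax(pts$survival, 0), 1)
  pts$survival <- cummin(pts$survival)
  if (pts$time[1] > 0) {
    pts <- rbind(data.frame(time = 0, survival = 1), pts)
  } else {
    pts$survival[1] <- 1
  }
  rownames(pts) <- NULL
  digitized_curve(pts, raw$risk_table, arm = raw$arm, endpoint = raw$endpoint,
                  total_events = raw$total_events)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the iterative reconstruction algorithm of Guyot and colleagues:
#' within each interval between consecutive numbers-at-risk times, an initial
#' guess of the number censored is refined until the implied number at risk
#' at the start of the next interval matches the published count; event
#' counts at each digitized step are recovered from the survival drops via
#' the product-limit relation, and censoring times are spread uniformly
#' across the interval. Beyond the last risk-table time no at-risk anchor
#' exists, so events are taken from the remaining survival drops (rescaled to
#' match `total_events` when reported) and all remaining subjects are
#' censored at the last digitized time.
#'
#' @param curve a cleaned [digitized_curve()] whose risk table has at least
#'   two rows (see [clean_curve()]).
#' @param total_events optional; overrides `curve$total_events`.
#' @param max_iter iteration cap per interval.
#' @return IPD data.frame (time, event, arm, endpoint); one row per subject
#'   initially at risk.
#' @export
reconstruct_ipd <- function(curve, total_events = NULL, max_iter = 100L) {
  stopifnot(inherits(curve, "digitized_curve"))
  curve <- clean_curve(curve)
  if (is.null(total_events)) total_events <- curve$total_events
  rt <- curve$risk_table
  if (nrow(rt) < 2)
    stop("reconstruct_ipd: risk table needs at least 2 rows", call. = FALSE)
  t_s <- curve$points$time
  s <- curve$points$survival
  n_t <- length(t_s)
  # drop risk-table rows beyond the digitized support
  rt <- rt[rt$time <= max(t_s) + 1e-9, , drop = FALSE]
  t_risk <- rt$time
  n_risk <- rt$n_at_risk
  n_int <- length(n_risk)
  # digitized index ranges per risk interval
  lower <- vapply(t_risk, function(tr) which(t_s >= tr - 1e-9)[1], integer(1))
  if (any(is.na(lower)))
    stop("reconstruct_ipd: risk-table times outside digitized range",
         call. = FALSE)
  upper <- c(lower[-1] - 1L, n_t)

  n_hat <- rep(NA_real_, n_t + 1)
  n_hat[1] <- n_risk[1]
  d <- rep(0, n_t)        # events per digitized step
  cen <- rep(0, n_t)      # censorings per digitized step (after that step)
  km_hat <- rep(1, n_t)
  n_censor <- rep(0, n_int)
  last_i <- rep(1L, n_int + 1)

  # walk one interval: spread n_censor_i censor times uniformly over it, bin
  # them to digitized steps, then recover events from the product-limit
  # relation; censorings in bin k are removed after the event at t_s[k]
  walk_interval <- function(i, n_censor_i, end_idx) {
    t_end <- t_s[end_idx]
    if (n_censor_i > 0 && t_end > t_s[lower[i]]) {
      ct <- t_s[lower[i]] +
        (1:n_censor_i) * (t_end - t_s[lower[i]]) / (n_censor_i + 1)
    } else ct <- numeric(0)
    cn <- rep(0, n_t)
    if (length(ct)) {
      brk <- t_s[lower[i]:end_idx]
      cn[lower[i]:(end_idx - 1)] <-
        graphics::hist(ct, breaks = brk, plot = FALSE, right = FALSE)$counts
    }
    nh <- n_hat; dd <- d; km <- km_hat
    nh[lower[i]] <- n_risk[i]
    last <- last_i[i]
    resid <- 0   # carried rounding residue, so event totals do not drift
    for (k in lower[i]:upper[i]) {
      if (i == 1 && k == lower[i]) {
        dd[k] <- 0; km[k] <- 1
      } else if (nh[k] <= 0) {
        dd[k] <- 0; cn[k] <- 0; km[k] <- km[last]
      } else {
        d_raw <- nh[k] * (1 - s[k] / km[last])
        if (d_raw < -1.5)
          stop(sprintf("reconstruct_ipd: negative event count in interval %d (t = %.3g)",
                       i, t_s[k]), call. = FALSE)
        if (d_raw < 0) { d_raw <- 0; resid <- 0 }
        dd[k] <- round(d_raw + resid)
        dd[k] <- min(max(dd[k], 0), nh[k])
        resid <- resid + d_raw - dd[k]
        km[k] <- km[last] * (1 - dd[k] / nh[k])
        if (!is.finite(km[k])) km[k] <- 0
      }
      cn[k] <- min(cn[k], nh[k] - dd[k])
      nh[k + 1] <- nh[k] - dd[k] - cn[k]
      if (dd[k] != 0) last <- k
    }
    list(n_hat = nh, d = dd, cen = cn, km = km, last = last)
  }

  accept <- function(i, res) {
    n_hat <<- res$n_hat; d <<- res$d
    cen[lower[i]:upper[i]] <<- res$cen[lower[i]:upper[i]]
    km_hat <<- res$km; last_i[i + 1] <<- res$last
  }

  extra_cen_times <- numeric(0)
  if (n_int > 1) {
    for (i in 1:(n_int - 1)) {
      # no digitized step inside the interval: everyone lost is censored at
      # the interval midpoint (there is no survival drop to explain events)
      if (upper[i] < lower[i]) {
        m <- max(n_risk[i] - n_risk[i + 1], 0)
        extra_cen_times <- c(extra_cen_times,
                             rep((t_risk[i] + t_risk[i + 1]) / 2, m))
        n_hat[lower[i + 1]] <- n_risk[i + 1]
        last_i[i + 1] <- last_i[i]
        next
      }
      s_lo <- max(s[lower[i]], 1e-12)
      n_censor[i] <- round(n_risk[i] * s[lower[i + 1]] / s_lo - n_risk[i + 1])
      iter <- 0L
      repeat {
        if (n_censor[i] < 0) n_censor[i] <- 0
        res <- walk_interval(i, n_censor[i], lower[i + 1])
        gap <- res$n_hat[lower[i + 1]] - n_risk[i + 1]
        iter <- iter + 1L
        if (gap == 0 || (gap < 0 && n_censor[i] == 0) || iter >= max_iter) {
          accept(i, res)
          break
        }
        n_censor[i] <- n_censor[i] + gap
      }
      # keep the chain exactly consistent even when the published count is
      # unreachable (the discrepancy is at most a couple of subjects)
      n_risk[i + 1] <- n_hat[lower[i + 1]]
    }
  }

  # final interval: no further at-risk anchor, so events come from the
  # remaining survival drops; when a reported event total is available,
  # censoring is added until the totals agree (or no further progress)
  i <- n_int
  if (upper[i] >= lower[i]) {
    n_cen_last <- 0L
    res <- walk_interval(i, n_cen_last, n_t)
    if (!is.null(total_events) && sum(res$d) > total_events) {
      # search the censor count whose events best match the reported total,
      # but never at the price of KM fidelity: allocations that distort the
      # reconstructed curve are rejected
      km_err <- function(r) max(abs(r$km[lower[i]:upper[i]] -
                                      s[lower[i]:upper[i]]))
      best_gap <- sum(res$d) - total_events
      for (m in seq_len(min(n_risk[i], max_iter))) {
        cand <- walk_interval(i, m, n_t)
        if (km_err(cand) > 0.015) next
        gap <- abs(sum(cand$d) - total_events)
        if (gap < best_gap) {
          best_gap <- gap; n_cen_last <- m; res <- cand
        }
        if (sum(cand$d) <= total_events) break
      }
    }
    accept(i, res)
  }

  # assemble records: events at their step times, bin-k censorings spread
  # uniformly over (t_s[k], t_s[k+1]), survivors censored at the curve end
  ev_times <- rep(t_s, times = pmax(round(d), 0))
  cn_times <- unlist(lapply(which(cen > 0), function(k) {
    m <- round(cen[k])
    hi <- if (k < n_t) t_s[k + 1] else t_s[n_t]
    # keep censor times inside their risk-table interval, so at-risk counts
    # recomputed from the records match the published table
    nxt <- t_risk[t_risk > t_s[k] + 1e-9]
    if (length(nxt)) hi <- min(hi, nxt[1])
    if (hi > t_s[k]) t_s[k] + (1:m) * (hi - t_s[k]) / (m + 1)
    else rep(t_s[k], m)
  }), use.names = FALSE)
  n_left <- n_hat[n_t + 1]
  if (!is.finite(n_left) || n_left < 0) n_left <- 0
  tail_times <- rep(t_s[n_t], round(n_left))
  cn_times <- c(cn_times, extra_cen_times)
  out <- data.frame(
    time = c(ev_times, cn_times, tail_times),
    event = c(rep(1L, length(ev_times)),
              rep(0L, length(cn_times) + length(tail_times))))
  out$arm <- curve$arm
  out$endpoint <- curve$endpoint
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  # reconstruction can only return whole subjects; the count must match the
  # initial risk set
  stopifnot(nrow(out) == rt$n_at_risk[1])
  out
}

#' Write a digitized curve to delimited text
#'
#' Two CSV files: the step coordinates (`time, survival`) and the risk table
#' (`time, n_at_risk`), both with a header row; lines starting `#` are
#' treated as comments on read.
#'
#' @param curve a [digitized_curve()].
#' @param points_path,risk_path output files.
#' @export
write_curve <- function(curve, points_path, risk_path) {
  stopifnot(inherits(curve, "digitized_curve"))
  utils::write.csv(curve$points, points_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(curve$risk_table, risk_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(points_path, risk_path))
}

#' Read a digitized curve from delimited text
#'
#' @param points_path CSV of `time, survival` (header required, `#` comments
#'   ignored).
#' @param risk_path CSV of `time, n_at_risk`.
#' @param arm,endpoint,total_events metadata attached to the curve.
#' @export
read_curve <- function(points_path, risk_path, arm = NA, endpoint = NA,
                       total_events = NULL) {
  pts <- utils::read.csv(points_path, comment.char = "#")
  rt <- utils::read.csv(risk_path, comment.char = "#")
  if (!all(c("time", "survival") %in% names(pts)))
    stop("points file must have header columns: time, survival", call. = FALSE)
  if (!all(c("time", "n_at_risk") %in% names(rt)))
    stop("risk file must have header columns: time, n_at_risk", call. = FALSE)
  digitized_curve(pts, rt, arm = arm, endpoint = endpoint,
                  total_events = total_events)
}
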