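make_curve <- function(points, risk, ...) {
  digitized_curve(points = points, risk_table = risk, ...)
}

test_that("clean_curve clamps digitization noise and anchors at (0,1)", {
  rt <- data.frame(time = c(0, 6), n_at_risk = c(10L, 5L))
  raw <- make_curve(data.frame(time = c(0, 3, 6), survival = c(1, 0.92, 0.94)), rt)
  expect_equal(clean_curve(raw)$points$survival, c(1, 0.92, 0.92))
  # already monotone: unchanged
  ok <- make_curve(data.frame(time = c(0, 3, 6), survival = c(1, 0.9, 0.8)), rt)
  expect_equal(clean_curve(ok)$points, ok$points)
  # idempotent
  expect_equal(clean_curve(clean_curve(raw))$points, clean_curve(raw)$points)
  # missing anchor prepended
  noanchor <- make_curve(data.frame(time = c(3, 6), survival = c(0.9, 0.8)), rt)
  expect_equal(clean_curve(noanchor)$points[1, ],
               data.frame(time = 0, survival = 1))
  # tied times merged keeping the lower survival
  tied <- make_curve(data.frame(time = c(0, 3, 3, 6), survival = c(1, 0.9, 0.88, 0.8)),
                     rt)
  expect_equal(clean_curve(tied)$points$survival, c(1, 0.88, 0.8))
  expect_error(clean_curve(make_curve(data.frame(time = 0, survival = 1), rt)),
               "at least 2")
  expect_error(clean_curve(make_curve(data.frame(time = c(0, 3), survival = c(0, 0)),
                                      rt)), "all survival")
})

test_that("curve containers reject invalid shapes", {
  expect_error(digitized_curve(data.frame(time = c(1, 0), survival = c(1, 1)),
                               data.frame(time = 0, n_at_risk = 5)),
               "non-decreasing")
  expect_error(digitized_curve(data.frame(time = c(0, 1), survival = c(1, 1.2)),
                               data.frame(time = 0, n_at_risk = 5)),
               "survival")
  expect_error(digitized_curve(data.frame(time = c(0, 1), survival = c(1, 0.5)),
                               data.frame(time = c(0, 3), n_at_risk = c(5, 9))),
               "non-increasing")
})

test_that("no-event curve reconstructs to all-censored records", {
  cv <- make_curve(data.frame(time = c(0, 12), survival = c(1, 1)),
                   data.frame(time = c(0, 12), n_at_risk = c(100L, 100L)))
  rec <- reconstruct_ipd(cv)
  expect_equal(nrow(rec), 100L)
  expect_equal(sum(rec$event), 0L)
  expect_true(all(rec$time == 12))
})

test_that("single-interval hand case recovers the unique consistent split", {
  # n0 = 4 at t=0, survival halves at a drop inside the interval, 2 at risk
  # at t=10: with the drop before any censoring, the only (events before 10,
  # censored before 10) pair satisfying S = 1 - d/4 = 1/2 and
  # 4 - d - c = 2 is (2, 0) -- verified by enumeration
  enumerate <- function(n0, s_target, n_next) {
    hits <- list()
    for (d in 0:n0) for (c in 0:(n0 - d)) {
      if (n0 - d - c == n_next && abs((1 - d / n0) - s_target) < 1e-9)
        hits[[length(hits) + 1]] <- c(events = d, censored = c)
    }
    hits
  }
  hits <- enumerate(4, 0.5, 2)
  expect_equal(length(hits), 1L)
  expect_equal(hits[[1]], c(events = 2, censored = 0))

  cv <- make_curve(data.frame(time = c(0, 9, 10), survival = c(1, 0.5, 0.5)),
                   data.frame(time = c(0, 10), n_at_risk = c(4L, 2L)))
  rec <- reconstruct_ipd(cv)
  expect_equal(nrow(rec), 4L)
  expect_equal(sum(rec$event), 2L)
  expect_equal(sum(rec$event == 0 & rec$time < 10), 0L)
  expect_true(all(rec$time[rec$event == 1] == 9))
})

test_that("record count equals the initial risk set and rescaling time keeps events", {
  spec <- trial_spec(seed = 4)
  rec <- simulate_arm(spec, "C", "OS")
  cv <- km_from_ipd(rec, seq(0, 30, 3))
  out <- reconstruct_ipd(cv)
  expect_equal(nrow(out), cv$risk_table$n_at_risk[1])
  # uniform time rescaling: same event count
  cv2 <- cv
  cv2$points$time <- cv$points$time * 12
  cv2$risk_table$time <- cv$risk_table$time * 12
  out2 <- reconstruct_ipd(cv2)
  expect_equal(sum(out2$event), sum(out$event))
  expect_error(reconstruct_ipd(
    make_curve(data.frame(time = c(0, 5), survival = c(1, 0.5)),
               data.frame(time = 0, n_at_risk = 10))), "at least 2 rows")
})

test_that("round-trip KM error stays within 0.02 across seeds and strata", {
  for (sd in 1:10) {
    spec <- trial_spec(seed = sd)
    sim <- simulate_trial(spec)
    for (a in c("CC", "C")) for (e in c("OS", "PFS")) {
      rec <- sim[sim$arm == a & sim$endpoint == e, ]
      cv <- km_from_ipd(rec, seq(0, 30, 3))
      out <- reconstruct_ipd(cv)
      f2 <- km_step(km_from_ipd(out, seq(0, 30, 3)))
      err <- max(abs(cv$points$survival - f2(cv$points$time)))
      expect_lt(err, 0.02)
      # recomputed numbers at risk stay within 2 of the published table
      recomputed <- vapply(cv$risk_table$time, function(t)
        sum(out$time >= t), numeric(1))
      expect_lte(max(abs(recomputed - cv$risk_table$n_at_risk)), 2)
    }
  }
})

test_that("curve text round trip preserves points and risk table", {
  spec <- trial_spec(seed = 9)
  cv <- km_from_ipd(simulate_arm(spec, "CC", "OS"), seq(0, 30, 6))
  pf <- withr::local_tempfile(fileext = ".csv")
  rf <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, pf, rf)
  cv2 <- read_curve(pf, rf, arm = "CC", endpoint = "OS")
  expect_equal(cv2$points$survival, cv$points$survival, tolerance = 1e-9)
  expect_equal(cv2$risk_table$n_at_risk, cv$risk_table$n_at_risk)
})
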