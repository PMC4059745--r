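# Compiled integrator: agreement with the pure R stepper, bookkeeping,
# non-negativity, nested no-memory variant, observers and continuations.

p <- default_params

test_that("compiled trajectory matches the pure R stepper", {
  init <- std_init()
  sch <- const_schedule(20, 2)
  tr <- simulate(p, sch, init, dt = 5, stride = 1440 / 5)
  ref <- metmemo:::simulate_r(p, sch, init, dt = 5,
                              q_prehist = attr(init, "q0"))
  day_rows <- tr$states[tr$states$time_min %in% c(0, 1440, 2880), ]
  for (v in c("F", "FFM", "H", "L", "G", "Ghr", "lam"))
    expect_equal(day_rows[[v]], unname(ref$states[, v]), tolerance = 1e-8)
  expect_equal(tr$daily$consumed_kJ, ref$daily_consumed, tolerance = 1e-8)
})

test_that("starvation gives monotone weight loss and empty availability", {
  init <- std_init()
  sch <- const_schedule(0, 10)
  tr <- simulate(p, sch, init)
  expect_true(all(diff(tr$states$BW_g) < 0))
  expect_true(all(tr$states$Favail[-1] == 0))
  expect_true(all(tr$daily$consumed_kJ == 0))
})

test_that("food bookkeeping is exact: delivered = consumed + removed + left", {
  init <- std_init()
  tr <- simulate(p, with_lead_in(build_H4(14), 2), init)
  balance <- sum(tr$daily$delivered_kJ) - sum(tr$daily$consumed_kJ) -
    sum(tr$daily$removed_kJ) - tr$final_state[["Favail"]]
  expect_equal(balance, 0, tolerance = 1e-9 * sum(tr$daily$delivered_kJ))
  # per-day consumption never exceeds what was in the trough
  expect_true(all(tr$daily$consumed_kJ <= tr$daily$delivered_kJ + 1e-9))
})

test_that("state variables stay non-negative along restriction trajectories", {
  init <- std_init()
  for (sch in list(const_schedule(0, 8), with_lead_in(build_H4(28), 2))) {
    tr <- simulate(p, sch, init, stride = 60)
    expect_true(all(as.matrix(tr$states[, -1]) >= 0))
  }
})

test_that("zero adaptation gain reproduces the no-memory variant exactly", {
  init <- std_init()
  sch <- with_lead_in(build_H4(14), 2)
  p0 <- params_with(c(mem_gain = 0))
  tr_k0 <- simulate(p0, sch, init, memory_on = TRUE)
  tr_off <- simulate(p0, sch, init, memory_on = FALSE)
  expect_identical(tr_k0$states, tr_off$states)
  tr_on <- simulate(p, sch, init, memory_on = TRUE)
  expect_false(identical(tr_on$states$lam, tr_off$states$lam))
})

test_that("weekly weight observer samples body weight on the weigh days", {
  init <- std_init()
  tr <- simulate(p, with_lead_in(build_H0(56), 5), init)
  ww <- observe_weekly_weights(tr)
  expect_equal(nrow(ww), 8)
  t_expect <- (5 + (1:8 - 1) * 7 + 7) * 1440
  expect_equal(ww$BW_g,
               tr$states$BW_g[match(t_expect, tr$states$time_min)])
  ww3 <- observe_weekly_weights(tr, weigh_day_offset = 3)
  expect_equal(nrow(ww3), 8)
  expect_false(isTRUE(all.equal(ww3$BW_g, ww$BW_g)))
})

test_that("daily intake bookkeeping: cumulative consumed below delivered", {
  init <- std_init()
  tr <- simulate(p, with_lead_in(build_H0(28), 5), init)
  di <- observe_daily_intake(tr)
  expect_true(all(diff(cumsum(di$consumed_g)) >= 0))
  expect_true(all(cumsum(tr$daily$consumed_kJ) <=
                    cumsum(tr$daily$delivered_kJ) + 1e-9))
  expect_equal(sum(di$consumed_g), sum(tr$daily$consumed_kJ) / 12.6)
  # the constant hypocaloric group eats everything it is given
  expect_lt(sum(di$leftover_g[-(1:5)]), 1e-6 * sum(di$allocated_g[-(1:5)]))
  # ad-libitum animals feed to demand and leave food
  trAL <- simulate(p, build_AL(14), init)
  diAL <- observe_daily_intake(trAL)
  expect_true(all(diAL$consumed_g < 25))
})

test_that("restricted feeding produces a within-day consume-then-fast sawtooth", {
  init <- std_init()
  tr <- simulate(p, const_schedule(20, 3), init, stride = 30)
  day3 <- tr$states[tr$states$time_min > 2 * 1440 &
                      tr$states$time_min <= 3 * 1440, ]
  # weight rises after the deposition then falls once the trough is empty
  expect_gt(max(day3$BW_g), day3$BW_g[nrow(day3)])
  expect_gt(max(day3$Favail), 0)
  expect_lt(min(day3$Favail), 1e-6)
})

test_that("constant feeding drives the expenditure rate to a fixed point", {
  init <- std_init()
  tr <- simulate(p, const_schedule(20, 140), init, stride = 1440)
  lam <- tr$states$lam
  n <- length(lam)
  late_rel_per_week <- abs(lam[n] - lam[n - 7]) / lam[n]
  expect_lt(late_rel_per_week, 1e-3)
  bw <- tr$states$BW_g
  expect_lt(abs(bw[n] - bw[n - 7]) / bw[n], 1e-3)
})

test_that("scenario continuation equals one uninterrupted simulation", {
  init <- std_init()
  whole <- simulate(p, const_schedule(20, 28), init)
  split <- extend_scenario(simulate(p, const_schedule(20, 14), init),
                           const_schedule(20, 14))
  expect_equal(split$final_state, whole$final_state, tolerance = 1e-9)
  expect_equal(nrow(split$daily), 28)
  expect_equal(split$daily$consumed_kJ, whole$daily$consumed_kJ,
               tolerance = 1e-9)
  expect_identical(extend_scenario(whole), whole)
})

test_that("trajectory CSV export carries the full tidy state table", {
  init <- std_init()
  tr <- simulate(p, const_schedule(20, 3), init)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), nrow(tr$states))
  expect_true(all(c("time_min", "BW_g", "lambda_permin", "consumed_kJ")
                  %in% names(df)))
  expect_true(all(diff(df$consumed_kJ) >= 0))
  expect_equal(max(df$consumed_kJ), sum(tr$daily$consumed_kJ))
})
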