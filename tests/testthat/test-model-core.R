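# Right-hand-side evaluators: signs, closed-form steady states, and the
# energy-partition identity.

p <- default_params

test_that("food intake rate follows the min rule", {
  expect_equal(food_intake_rate(0, 100, p), 0)
  expect_equal(food_intake_rate(100, 0, p), 0)
  # depends on min(H, Favail) only
  expect_equal(food_intake_rate(50, 200, p), food_intake_rate(50, 50, p))
  expect_equal(food_intake_rate(50, 50, p), 50 / p[["theta_intake"]])
  # non-decreasing in both arguments
  grid <- expand.grid(H = c(0, 1, 10, 50), Fav = c(0, 1, 10, 50))
  q <- food_intake_rate(grid$H, grid$Fav, p)
  for (i in seq_len(nrow(grid)))
    for (j in seq_len(nrow(grid)))
      if (grid$H[j] >= grid$H[i] && grid$Fav[j] >= grid$Fav[i])
        expect_gte(q[j], q[i])
  expect_error(food_intake_rate(-1, 5, p), "non-negative")
  expect_error(food_intake_rate(5, -1, p), "non-negative")
})

test_that("energy expenditure is the rate times the body caloric content", {
  expect_equal(energy_expenditure(0, 0, 1e-4, p), 0)
  expect_equal(energy_expenditure(50, 350, 1e-5, p),
               1e-5 * (39.3 * 50 + 7.5 * 350))
  expect_equal(energy_expenditure(50, 350, 2e-5, p),
               2 * energy_expenditure(50, 350, 1e-5, p))
  # strictly increasing in each argument
  expect_gt(energy_expenditure(51, 350, 1e-5, p),
            energy_expenditure(50, 350, 1e-5, p))
  expect_gt(energy_expenditure(50, 351, 1e-5, p),
            energy_expenditure(50, 350, 1e-5, p))
  expect_error(energy_expenditure(-1, 350, 1e-5, p), "non-negative")
})

test_that("energy balance is intake minus expenditure", {
  expect_equal(energy_balance(1, 1), 0)
  expect_equal(energy_balance(0.5, 0.2), 0.3)
  expect_equal(energy_balance(0.2, 0.5), -energy_balance(0.5, 0.2))
})

test_that("body-composition split satisfies the energy-partition identity", {
  set.seed(1)
  for (i in 1:50) {
    st <- c(F = runif(1, 1, 250), FFM = runif(1, 50, 500))
    E <- runif(1, -0.5, 0.5)
    d <- rhs_body_composition(st, E, p)
    stored <- p[["rho_F"]] * d[["dF"]] + p[["rho_FFM"]] * d[["dFFM"]]
    expect_equal(stored, E, tolerance = 1e-9)
  }
  d0 <- rhs_body_composition(c(F = 80, FFM = 300), 0, p)
  expect_equal(p[["rho_F"]] * d0[["dF"]] + p[["rho_FFM"]] * d0[["dFFM"]], 0)
  expect_error(rhs_body_composition(c(F = 80, FFM = 300), Inf, p), "finite")
})

test_that("partition coefficient is positive and monotone in fat mass", {
  Fs <- seq(0, 300, 5)
  a <- alpha_partition(Fs, p)
  expect_true(all(a > 0))
  expect_true(all(diff(a) < 0)) # heavier animals partition more into fat
  # the fat-free share of a positive balance falls with F accordingly
  share <- sapply(Fs, function(f) {
    d <- rhs_body_composition(c(F = f, FFM = 300), 0.2, p)
    p[["rho_FFM"]] * d[["dFFM"]] / 0.2
  })
  expect_true(all(diff(share) < 0))
})

test_that("leptin, glucose and ghrelin relax to their closed-form steady states", {
  # leptin at fixed F = 100 g
  Lstar <- p[["leptin_prod"]] * 100 / p[["leptin_clear"]]
  expect_equal(Lstar, 0.126 * 100 / 0.074, tolerance = 1e-12)
  expect_lt(rhs_leptin(Lstar * 1.01, 100, p), 0)
  expect_gt(rhs_leptin(Lstar * 0.99, 100, p), 0)
  expect_equal(rhs_leptin(0, 0, p), 0)

  # numeric integration over 10 clearance half-lives reaches 0.1%
  integrate_to <- function(rhs, clear, x0) {
    t_end <- 10 * log(2) / clear
    dt <- 0.5
    x <- x0
    for (i in seq_len(ceiling(t_end / dt))) {
      k1 <- rhs(x); k2 <- rhs(x + dt / 2 * k1)
      k3 <- rhs(x + dt / 2 * k2); k4 <- rhs(x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x
  }
  L10 <- integrate_to(function(L) rhs_leptin(L, 100, p), p[["leptin_clear"]], 0)
  expect_equal(L10, Lstar, tolerance = 1e-3)

  q <- 0.2
  Gstar <- p[["glucose_yield"]] * q / p[["glucose_clear"]]
  G10 <- integrate_to(function(G) rhs_glucose(G, q, p), p[["glucose_clear"]], 0)
  expect_equal(G10, Gstar, tolerance = 1e-3)
  expect_lt(rhs_glucose(Gstar * 1.01, q, p), 0)
  expect_equal(rhs_glucose(0, 0, p), 0)

  # fasted ghrelin: production is maximal, steady state prod/clear
  expect_equal(rhs_ghrelin(0, 0, p), p[["ghrelin_prod"]])
  Ghrstar <- p[["ghrelin_prod"]] / p[["ghrelin_clear"]]
  Ghr10 <- integrate_to(function(G) rhs_ghrelin(G, 0, p),
                        p[["ghrelin_clear"]], 0)
  expect_equal(Ghr10, Ghrstar, tolerance = 1e-3)
  # monotone inhibition by the consumed-food flux
  qs <- c(0, 0.1, 0.5, 2, 10)
  prod <- sapply(qs, function(qq) rhs_ghrelin(0, qq, p))
  expect_true(all(diff(prod) < 0))
  expect_lt(rhs_ghrelin(0, 1e6, p), 0.01 * p[["ghrelin_prod"]])
})

test_that("hunger derivative has the prescribed hormone signs", {
  st <- list(H = 1, L = 150, G = 1, Ghr = 40)
  eps <- 1e-6
  base <- rhs_hunger(st$H, st$L, st$G, st$Ghr, p)
  dGhr <- (rhs_hunger(st$H, st$L, st$G, st$Ghr + eps, p) - base) / eps
  dL <- (rhs_hunger(st$H, st$L + eps, st$G, st$Ghr, p) - base) / eps
  dG <- (rhs_hunger(st$H, st$L, st$G + eps, st$Ghr, p) - base) / eps
  expect_gt(dGhr, 0) # ghrelin raises hunger
  expect_lt(dL, 0)   # leptin lowers hunger
  expect_lt(dG, 0)   # glucose lowers hunger
  # no ghrelin drive plus strong leptin/glucose: hunger cannot grow
  expect_lte(rhs_hunger(1, 1e4, 10, 0, p), 0)
  # production is non-negative at H = 0, so hunger stays non-negative
  expect_gte(rhs_hunger(0, 1e4, 10, 50, p), 0)
  # finite and continuous over a wide hormone range
  for (s in 10^seq(-2, 1.1, 0.5)) {
    v <- rhs_hunger(st$H, st$L * s, st$G * s, st$Ghr * s, p)
    expect_true(is.finite(v))
  }
})

test_that("moving average of intake matches brute-force window sums", {
  hist <- list(dt = 60, buffer = rep(315 / 24, 24 * 10)) # 315 kJ/day, 10 days
  expect_equal(moving_average_intake(hist, 8), 315)
  expect_equal(moving_average_intake(hist, 1), 315)
  hist0 <- list(dt = 60, buffer = rep(0, 240))
  expect_equal(moving_average_intake(hist0, 8), 0)
  # square wave: alternate days of 0 and 480 kJ
  sq <- list(dt = 60, buffer = rep(c(rep(0, 24), rep(20, 24)), 5))
  expect_equal(moving_average_intake(sq, 2),
               sum(utils::tail(sq$buffer, 48)) / 2)
  expect_equal(moving_average_intake(sq, 3),
               sum(utils::tail(sq$buffer, 72)) / 3)
  expect_error(moving_average_intake(sq, 11), "too short")
})

test_that("expenditure-rate adaptation has the memory fixed point and signs", {
  expect_equal(rhs_lambda(2.5e-5, 300, 300, p), 0)
  expect_lt(rhs_lambda(2.5e-5, 250, 300, p), 0)  # restriction lowers the rate
  expect_gt(rhs_lambda(2.5e-5, 350, 300, p), 0)  # overfeeding raises it
  # magnitude scales with the adaptation gain
  p2 <- params_with(c(mem_gain = 2 * p[["mem_gain"]]))
  expect_equal(rhs_lambda(2.5e-5, 250, 300, p2),
               2 * rhs_lambda(2.5e-5, 250, 300, p))
  p0 <- params_with(c(mem_gain = 0))
  expect_equal(rhs_lambda(2.5e-5, 250, 300, p0), 0) # nested no-memory limit
  expect_error(rhs_lambda(0, 250, 300, p), "positive")
})

test_that("parameter sets validate their invariants and round-trip to disk", {
  expect_error(model_parameters(tau1 = 9), "tau1")
  expect_error(model_parameters(rho_F = 5), "rho_F")
  expect_error(model_parameters(lambda0 = -1), "positive")
  expect_error(model_parameters(nonsense = 1), "unknown parameter")
  f <- tempfile(fileext = ".txt")
  write_parameters(p, f)
  p2 <- read_parameters(f)
  expect_equal(as.numeric(p2), as.numeric(p))
  expect_equal(names(p2), names(p))
})
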