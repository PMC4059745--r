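# Reference R implementation of one integration step and of a short
# trajectory, composed directly from the exported rhs_* evaluators. It exists
# to cross-check the compiled integrator (same scheme: RK4 with the window
# means frozen over the step, daily deposition, non-negativity clamps); it is
# far too slow for production runs.

rhs_vec_r <- function(s, p, m1, m2, memory_on) {
  sc <- pmax(s, 0)
  q <- food_intake_rate(sc[["H"]], sc[["Favail"]], p)
  ee <- energy_expenditure(sc[["F"]], sc[["FFM"]], s[["lam"]], p)
  E <- energy_balance(q, ee)
  bc <- rhs_body_composition(c(F = sc[["F"]], FFM = sc[["FFM"]]), E, p)
  dF <- bc[["dF"]]; dFFM <- bc[["dFFM"]]
  if (s[["F"]] <= 0 && dF < 0) {
    dFFM <- dFFM + dF * p[["rho_F"]] / p[["rho_FFM"]]
    dF <- 0
  }
  if (s[["FFM"]] <= 0 && dFFM < 0) dFFM <- 0
  c(F = dF, FFM = dFFM,
    Favail = rhs_food(sc[["Favail"]], 0, q),
    H = rhs_hunger(sc[["H"]], sc[["L"]], sc[["G"]], sc[["Ghr"]], p),
    L = rhs_leptin(sc[["L"]], sc[["F"]], p),
    G = rhs_glucose(sc[["G"]], q, p),
    Ghr = rhs_ghrelin(sc[["Ghr"]], q, p),
    lam = if (memory_on) rhs_lambda(s[["lam"]], m1, m2, p) else 0)
}

# one RK4 step + history push; mirrors the compiled step exactly
step_r <- function(state, hist, p, dt, memory_on = TRUE) {
  n1 <- round(p[["tau1"]] * MINUTES_PER_DAY / dt)
  n2 <- round(p[["tau2"]] * MINUTES_PER_DAY / dt)
  m1 <- sum(hist$buffer[(n2 - n1 + 1):n2]) * MINUTES_PER_DAY / (n1 * dt)
  m2 <- sum(hist$buffer) * MINUTES_PER_DAY / (n2 * dt)
  fav0 <- state[["Favail"]]
  k1 <- rhs_vec_r(state, p, m1, m2, memory_on)
  k2 <- rhs_vec_r(state + 0.5 * dt * k1, p, m1, m2, memory_on)
  k3 <- rhs_vec_r(state + 0.5 * dt * k2, p, m1, m2, memory_on)
  k4 <- rhs_vec_r(state + dt * k3, p, m1, m2, memory_on)
  s2 <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  s2[s2 < 0] <- 0
  consumed <- fav0 - s2[["Favail"]]
  hist$buffer <- c(hist$buffer[-1], consumed)
  list(state = s2, hist = hist, consumed = consumed)
}

# pure-R trajectory over a schedule; daily snapshots only
simulate_r <- function(p, s, init, dt = 1, memory_on = TRUE,
                       q_prehist = attr(init, "q0"), unlimited_kj = 1e6) {
  n2 <- round(p[["tau2"]] * MINUTES_PER_DAY / dt)
  hist <- list(dt = dt, buffer = rep(q_prehist * dt, n2))
  state <- setNames(as.numeric(init)[seq_along(STATE_NAMES)], STATE_NAMES)
  steps_per_day <- MINUTES_PER_DAY / dt
  n_days <- length(s$daily_grams)
  out <- matrix(NA_real_, n_days + 1, length(STATE_NAMES),
                dimnames = list(NULL, STATE_NAMES))
  out[1, ] <- state
  daily_consumed <- numeric(n_days)
  for (d in seq_len(n_days)) {
    state[["Favail"]] <- if (s$unlimited[d]) unlimited_kj
      else s$daily_grams[d] * s$energy_density
    ctot <- 0
    for (k in seq_len(steps_per_day)) {
      st <- step_r(state, hist, p, dt, memory_on)
      state <- st$state; hist <- st$hist; ctot <- ctot + st$consumed
    }
    daily_consumed[d] <- ctot
    out[d + 1, ] <- state
  }
  list(states = out, daily_consumed = daily_consumed, hist = hist)
}
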