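# Right-hand-side evaluators for the eight state variables. All rates are per
# minute. These pure R evaluators define the model; the compiled integrator in
# src/sim.cpp implements the same formulas and is cross-checked against them
# in the test suite.

#' Food intake rate
#'
#' Consumption per minute equals the minimum of hunger and available food,
#' converted to a flux by the intake coefficient `theta_intake` (minutes
#' needed to clear one kJ of standing intake backlog):
#' `q = min(H, Favail) / theta_intake`.
#'
#' @param H hunger, kJ.
#' @param Favail available food energy, kJ.
#' @param p a [model_parameters()] set.
#' @return intake flux, kJ per minute.
#' @export
food_intake_rate <- function(H, Favail, p) {
  if (any(H < 0) || any(Favail < 0)) stop("H and Favail must be non-negative")
  pmin(H, Favail) / p[["theta_intake"]]
}

#' Energy expenditure
#'
#' Joules lost per minute: the caloric content of the body multiplied by the
#' rate of energy expenditure, `EE = lam * (rho_F * F + rho_FFM * FFM)`.
#'
#' @param F fat mass, g.
#' @param FFM fat-free mass, g.
#' @param lam rate of energy expenditure, min^-1.
#' @param p a [model_parameters()] set.
#' @return energy expenditure, kJ per minute.
#' @export
energy_expenditure <- function(F, FFM, lam, p) {
  if (any(F < 0) || any(FFM < 0) || any(lam < 0))
    stop("F, FFM and lam must be non-negative")
  lam * (p[["rho_F"]] * F + p[["rho_FFM"]] * FFM)
}

#' Energy balance
#'
#' Instantaneous difference between intake and expenditure (kJ per minute).
#'
#' @param q intake flux, kJ per minute.
#' @param ee energy expenditure, kJ per minute.
#' @return `q - ee`.
#' @export
energy_balance <- function(q, ee) q - ee

#' Body-composition partition coefficient
#'
#' `alpha(F) = dFFM/dF`, the grams of fat-free mass accompanying each gram of
#' fat mass along a trajectory. A two-term Forbes-type law,
#' `alpha(F) = A / (1 + c F) + B K / (K + rho_F F)`,
#' positive and strictly decreasing in F: lean animals partition the energy
#' balance mostly into fat-free mass, fat animals mostly into fat.
#'
#' @param F fat mass, g.
#' @param p a [model_parameters()] set.
#' @return dimensionless partition coefficient.
#' @export
alpha_partition <- function(F, p) {
  p[["part_A"]] / (1 + p[["part_c"]] * F) +
    p[["part_B"]] * p[["part_K"]] / (p[["part_K"]] + p[["rho_F"]] * F)
}

#' Fat / fat-free mass derivatives
#'
#' Splits the energy balance `E` between the two compartments so that the
#' stored-energy identity `rho_F dF/dt + rho_FFM dFFM/dt = E` holds exactly:
#' `dF/dt = E / (rho_F + rho_FFM alpha(F))`, `dFFM/dt = alpha(F) dF/dt`.
#'
#' @param state named numeric with at least `F` and `FFM` (see
#'   [model_state()]).
#' @param E energy balance, kJ per minute.
#' @param p a [model_parameters()] set.
#' @return named numeric `c(dF, dFFM)`, g per minute.
#' @export
rhs_body_composition <- function(state, E, p) {
  if (!is.finite(E)) stop("energy balance must be finite")
  a <- alpha_partition(state[["F"]], p)
  dF <- E / (p[["rho_F"]] + p[["rho_FFM"]] * a)
  c(dF = dF, dFFM = a * dF)
}

#' Available-food derivative
#'
#' Between daily deposition events, available food changes by delivery minus
#' consumption: `dFavail/dt = u - q`.
#'
#' @param Favail available food energy, kJ (unused, kept for signature
#'   symmetry).
#' @param u delivery flux, kJ per minute.
#' @param q intake flux, kJ per minute.
#' @return kJ per minute.
#' @export
rhs_food <- function(Favail, u, q) u - q

#' Leptin derivative
#'
#' Production proportional to fat mass, first-order clearance:
#' `dL/dt = leptin_prod * F - leptin_clear * L`.
#'
#' @param L total plasma leptin, ng.
#' @param F fat mass, g.
#' @param p a [model_parameters()] set.
#' @return ng per minute.
#' @export
rhs_leptin <- function(L, F, p) {
  p[["leptin_prod"]] * F - p[["leptin_clear"]] * L
}

#' Glucose derivative
#'
#' Rises with food intake, first-order clearance:
#' `dG/dt = glucose_yield * q - glucose_clear * G`.
#'
#' @param G total plasma glucose, g.
#' @param q intake flux, kJ per minute.
#' @param p a [model_parameters()] set.
#' @return g per minute.
#' @export
rhs_glucose <- function(G, q, p) {
  p[["glucose_yield"]] * q - p[["glucose_clear"]] * G
}

#' Ghrelin derivative
#'
#' Production is maximal when fasting and inhibited by food passing through
#' the stomach (the consumed-food flux `q` is the stomach-content proxy):
#' `dGhr/dt = ghrelin_prod / (1 + theta_intake * q) - ghrelin_clear * Ghr`.
#' `theta_intake * q` is dimensionless, so no extra constant is needed.
#'
#' @param Ghr plasma ghrelin, pg.mL^-1.
#' @param q consumed-food flux, kJ per minute.
#' @param p a [model_parameters()] set.
#' @return pg.mL^-1 per minute.
#' @export
rhs_ghrelin <- function(Ghr, q, p) {
  p[["ghrelin_prod"]] / (1 + p[["theta_intake"]] * q) -
    p[["ghrelin_clear"]] * Ghr
}

#' Hunger derivative
#'
#' Hunger (the food energy the organism would consume absent availability
#' constraints) is produced by ghrelin, inhibited by leptin and glucose, and
#' relaxed by glucose:
#' `dH/dt = a Ghr exp(-G / c_g) / (1 + b L) - d G H`
#' with `a = hunger_ghrelin`, `b = hunger_leptin`, `c_g = hunger_glucose`,
#' `d = hunger_relax`. The derivative is non-negative at `H = 0`, so hunger
#' never becomes negative.
#'
#' @param H hunger, kJ.
#' @param L total plasma leptin, ng.
#' @param G total plasma glucose, g.
#' @param Ghr plasma ghrelin, pg.mL^-1.
#' @param p a [model_parameters()] set.
#' @return kJ per minute.
#' @export
rhs_hunger <- function(H, L, G, Ghr, p) {
  p[["hunger_ghrelin"]] * Ghr * exp(-G / p[["hunger_glucose"]]) /
    (1 + p[["hunger_leptin"]] * L) -
    p[["hunger_relax"]] * G * H
}

#' Trailing moving average of consumed energy
#'
#' Mean intake over the trailing `window` days, from a per-step intake
#' history. With constant intake `c` kJ/day the average is `c` for any
#' window.
#'
#' @param hist an intake history: list with `dt` (step, min) and `buffer`
#'   (consumed kJ per step, oldest first, ending at the current time).
#' @param window window length, days.
#' @return mean intake over the window, kJ per day.
#' @export
moving_average_intake <- function(hist, window) {
  nsteps <- round(window * MINUTES_PER_DAY / hist$dt)
  if (nsteps < 1) stop("window shorter than one step")
  if (length(hist$buffer) < nsteps)
    stop("intake history too short for a ", window, "-day window")
  tail_sum <- sum(hist$buffer[(length(hist$buffer) - nsteps + 1):length(hist$buffer)])
  tail_sum / window
}

#' Rate-of-expenditure derivative (metabolic memory)
#'
#' The rate of energy expenditure is progressively modified to reduce the
#' difference between the short- and long-window mean food intakes:
#' `dlam/dt = (mem_gain / 1440) * lam * (m_short - m_long)`
#' with the window means in kJ/day (the 1440 converts the per-day adaptation
#' to the per-minute time base). Sustained overfeeding raises expenditure,
#' restriction lowers it; when the two means agree `lam` is constant, and
#' `mem_gain = 0` freezes `lam` (the no-memory model variant).
#'
#' @param lam rate of energy expenditure, min^-1 (must be > 0).
#' @param m_short mean intake over the last `tau1` days, kJ/day.
#' @param m_long mean intake over the last `tau2` days, kJ/day.
#' @param p a [model_parameters()] set.
#' @return min^-2.
#' @export
rhs_lambda <- function(lam, m_short, m_long, p) {
  if (any(lam <= 0)) stop("lam must be strictly positive")
  (p[["mem_gain"]] / MINUTES_PER_DAY) * lam * (m_short - m_long)
}
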