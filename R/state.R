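# Model state and ad-libitum equilibrium initialisation.

STATE_NAMES <- c("F", "FFM", "Favail", "H", "L", "G", "Ghr", "lam")

#' Construct a model state
#'
#' The eight dynamical variables: fat mass `F` (g), fat-free mass `FFM` (g),
#' available food `Favail` (kJ), hunger `H` (kJ), total plasma leptin `L`
#' (ng), total plasma glucose `G` (g), plasma ghrelin `Ghr` (pg/mL) and the
#' rate of energy expenditure `lam` (min^-1). Body weight is `F + FFM`.
#'
#' @param F,FFM,Favail,H,L,G,Ghr,lam state components (see above).
#' @return named numeric of class `"model_state"`.
#' @export
model_state <- function(F, FFM, Favail = 0, H = 0, L = 0, G = 0, Ghr = 0,
                        lam) {
  s <- c(F = F, FFM = FFM, Favail = Favail, H = H, L = L, G = G, Ghr = Ghr,
         lam = lam)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all state variables must be finite and non-negative")
  if (F + FFM <= 0) stop("body weight must be positive")
  structure(s, class = "model_state")
}

#' Ad-libitum equilibrium intake
#'
#' Solves the hunger fixed point under unlimited food at a given fat mass:
#' the intake flux `q` such that hunger production balances its relaxation
#' when glucose, ghrelin and leptin sit at their own steady states and
#' consumption equals hunger (`H = theta_intake * q`). This is the demand an
#' ad-libitum rat settles into.
#'
#' @param F fat mass, g.
#' @param p a [model_parameters()] set.
#' @return equilibrium intake flux, kJ per minute.
#' @export
al_equilibrium_intake <- function(F, p) {
  L <- p[["leptin_prod"]] * F / p[["leptin_clear"]]
  balance <- function(q) {
    G <- p[["glucose_yield"]] * q / p[["glucose_clear"]]
    Ghr <- (p[["ghrelin_prod"]] / (1 + p[["theta_intake"]] * q)) /
      p[["ghrelin_clear"]]
    H <- p[["theta_intake"]] * q
    rhs_hunger(H, L, G, Ghr, p)
  }
  uniroot(balance, c(1e-8, 10), tol = 1e-12)$root
}

#' Initial state at the ad-libitum equilibrium
#'
#' Builds the starting state used by the simulator: fat and fat-free mass
#' from the initial biometrics, hormones and hunger at their closed-form
#' steady states under the ad-libitum equilibrium intake, and
#' `lam = lambda0`. All groups start from the ad-libitum regime (the
#' experiment's lead-in).
#'
#' @param BW0 initial body weight, g.
#' @param F0 initial fat mass, g (must be `< BW0`).
#' @param p a [model_parameters()] set.
#' @return a [model_state()] plus attribute `q0` (equilibrium intake,
#'   kJ/min).
#' @export
initial_state <- function(BW0, F0, p) {
  if (F0 <= 0 || F0 >= BW0) stop("F0 must lie strictly between 0 and BW0")
  q0 <- al_equilibrium_intake(F0, p)
  s <- model_state(
    F = F0, FFM = BW0 - F0,
    Favail = 0,
    H = p[["theta_intake"]] * q0,
    L = p[["leptin_prod"]] * F0 / p[["leptin_clear"]],
    G = p[["glucose_yield"]] * q0 / p[["glucose_clear"]],
    Ghr = (p[["ghrelin_prod"]] / (1 + p[["theta_intake"]] * q0)) /
      p[["ghrelin_clear"]],
    lam = p[["lambda0"]]
  )
  attr(s, "q0") <- q0
  s
}
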