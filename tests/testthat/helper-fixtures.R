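# Baseline parameter set; the two documented soft warnings are expected.
table_params <- function(...) suppressWarnings(addiction_params(...))

full_names <- c("S", "P", "ES", "IS", "PS", "EA", "IA", "PA", "CSA", "PSA", "T")

random_full_state <- function(lo = 1, hi = 100) {
  stats::setNames(stats::runif(11, lo, hi), full_names)
}

# Independent transcription of the controlled system, written directly from
# the eleven printed equations (scalar, no shared kernel with the package).
# Serves as the arithmetic oracle for controlled_rhs().
oracle_controlled_rhs <- function(x, w, p) {
  S <- x[["S"]]; P <- x[["P"]]; ES <- x[["ES"]]; IS <- x[["IS"]]
  PS <- x[["PS"]]; EA <- x[["EA"]]; IA <- x[["IA"]]; PA <- x[["PA"]]
  CSA <- x[["CSA"]]; PSA <- x[["PSA"]]; TT <- x[["T"]]
  N <- S + P + ES + IS + PS + EA + IA + PA + CSA + PSA + TT
  lamA <- p$beta1 / N * (IA + PA + p$theta1 * (CSA + PSA))
  lamS <- p$beta2 / N * (IS + PS + p$theta2 * (CSA + PSA))
  c(S = (1 - p$pi) * p$K - (1 - w[1]) * lamS * S - (1 - w[2]) * lamA * S -
      w[3] * p$delta * S - p$mu * S,
    P = p$pi * p$K + w[3] * p$delta * S - (1 - w[2]) * p$rho1 * lamA * P -
      (1 - w[1]) * p$delta1 * lamS * P - p$mu * P,
    ES = (1 - w[1]) * lamS * S + (1 - w[1]) * p$delta1 * lamS * P -
      (p$mu + p$gamma1) * ES,
    IS = p$gamma1 * ES - w[4] * p$eps2 * IS - p$gamma2 * IS -
      (1 - w[4]) * p$rho3 * lamA * IS - (p$mu + p$dS) * IS,
    PS = p$gamma2 * IS - (1 - w[4]) * p$rho2 * lamA * PS -
      (p$mu + p$dPS) * PS,
    EA = (1 - w[2]) * lamA * S + (1 - w[2]) * p$rho1 * lamA * P -
      (p$mu + p$alpha1) * EA,
    IA = p$alpha1 * EA - p$alpha2 * IA - w[5] * p$eps1 * IA -
      (1 - w[1]) * p$delta2 * lamS * IA - (p$mu + p$dA) * IA,
    PA = p$alpha2 * IA - (1 - w[1]) * p$delta3 * lamS * PA -
      (p$mu + p$dPA) * PA,
    CSA = (1 - w[1]) * p$delta2 * lamS * IA + (1 - w[1]) * p$delta3 * lamS * PA +
      (1 - w[2]) * p$rho3 * lamA * IS + (1 - w[2]) * p$rho2 * lamA * PS -
      (p$alpha + w[6] * p$eps3 + p$mu + p$dC) * CSA,
    PSA = p$alpha * CSA - (p$mu + p$dSA) * PSA,
    T = w[6] * p$eps3 * CSA + w[5] * p$eps1 * IA + w[4] * p$eps2 * IS -
      p$mu * TT)
}

# forward simulation of the controlled system under a fixed constant control
sim_constant_control <- function(params, w, init = addiction_state(),
                                 t_final = 5, n_steps = 150) {
  times <- seq(0, t_final, length.out = n_steps + 1)
  states <- coaddiction:::rk4_integrate(
    function(t, y) controlled_rhs(t, y, w, params), init[full_names], times)
  traj <- data.frame(t = times, states)
  W <- matrix(w, n_steps + 1, 6, byrow = TRUE)
  list(trajectory = traj, controls = W, times = times)
}

constant_control_objective <- function(params, w, weights,
                                       init = addiction_state(),
                                       t_final = 5, n_steps = 150) {
  s <- sim_constant_control(params, w, init, t_final, n_steps)
  objective_functional(s$trajectory, s$controls, weights)
}
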