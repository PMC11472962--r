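#' Objective weights for the optimal-control problem
#'
#' The running cost is
#' \eqn{D_1 I_S + D_2 P_S + D_3 I_A + D_4 P_A + D_5 C_{SA} + D_6 P_{SA}
#'   + \tfrac12 \sum_i \psi_i w_i^2}: linear addiction-burden weights `D` on
#' the six addicted classes plus quadratic effort weights `psi` on the six
#' controls. Defaults `psi = 10`, `D = 7` for every component.
#'
#' @param psi length-6 positive vector of control-effort weights.
#' @param D length-6 positive vector of addiction-burden weights.
#' @return Named list with elements `psi` and `D`.
#' @export
control_weights <- function(psi = rep(10, 6), D = rep(7, 6)) {
  psi <- rep_len(as.numeric(psi), 6)
  D <- rep_len(as.numeric(D), 6)
  if (any(psi <= 0) || any(D <= 0)) stop("weights must be strictly positive")
  list(psi = psi, D = D)
}

#' Catalogue of intervention strategies
#'
#' Nine strategies combining the six controls: `w1`-`w3` are protection
#' (education) against smoking, alcohol and dual addiction; `w4`-`w6` are
#' treatment (rehabilitation) of the smoking-, alcohol- and dually-addicted
#' classes.
#'
#' * A: protection only (`w1, w2, w3`)
#' * B: treatment only (`w4, w5, w6`)
#' * C, D, E: protection plus one treatment (`w4` / `w5` / `w6`)
#' * F, G, H: protection plus two treatments (`w4,w5` / `w4,w6` / `w5,w6`)
#' * I: all six controls
#'
#' @return Named list mapping strategy id to the integer indices of its active
#'   controls.
#' @examples
#' strategy_catalog()$D
#' @export
strategy_catalog <- function() {
  list(A = c(1L, 2L, 3L), B = c(4L, 5L, 6L),
       C = c(1L, 2L, 3L, 4L), D = c(1L, 2L, 3L, 5L), E = c(1L, 2L, 3L, 6L),
       F = c(1L, 2L, 3L, 4L, 5L), G = c(1L, 2L, 3L, 4L, 6L),
       H = c(1L, 2L, 3L, 5L, 6L), I = 1:6)
}

# strategy id or index vector -> logical mask over the six controls
strategy_mask <- function(strategy) {
  if (is.character(strategy)) {
    cat <- strategy_catalog()
    if (!strategy %in% names(cat)) stop("unknown strategy id: ", strategy)
    strategy <- cat[[strategy]]
  }
  if (is.logical(strategy)) return(rep_len(strategy, 6))
  m <- rep(FALSE, 6)
  m[as.integer(strategy)] <- TRUE
  m
}

# Controlled RHS kernel on an unnamed length-11 state (order
# S,P,ES,IS,PS,EA,IA,PA,CSA,PSA,T). Transcribes the controlled system exactly,
# including its two documented idiosyncrasies: the protection flow delta*S is
# multiplied by w3 (so w = 0 switches protection off rather than recovering
# the uncontrolled model), and the dual-addiction inflow carries (1-w2) where
# the matching single-addiction outflow carries (1-w4).
crhs_kernel <- function(x, w, p) {
  N <- sum(x)
  lamA <- p$beta1 * (x[7] + x[8] + p$theta1 * (x[9] + x[10])) / N
  lamS <- p$beta2 * (x[4] + x[5] + p$theta2 * (x[9] + x[10])) / N
  c((1 - p$pi) * p$K - (1 - w[1]) * lamS * x[1] - (1 - w[2]) * lamA * x[1] -
      w[3] * p$delta * x[1] - p$mu * x[1],
    p$pi * p$K + w[3] * p$delta * x[1] - (1 - w[2]) * p$rho1 * lamA * x[2] -
      (1 - w[1]) * p$delta1 * lamS * x[2] - p$mu * x[2],
    (1 - w[1]) * lamS * x[1] + (1 - w[1]) * p$delta1 * lamS * x[2] -
      (p$mu + p$gamma1) * x[3],
    p$gamma1 * x[3] - w[4] * p$eps2 * x[4] - p$gamma2 * x[4] -
      (1 - w[4]) * p$rho3 * lamA * x[4] - (p$mu + p$dS) * x[4],
    p$gamma2 * x[4] - (1 - w[4]) * p$rho2 * lamA * x[5] -
      (p$mu + p$dPS) * x[5],
    (1 - w[2]) * lamA * x[1] + (1 - w[2]) * p$rho1 * lamA * x[2] -
      (p$mu + p$alpha1) * x[6],
    p$alpha1 * x[6] - p$alpha2 * x[7] - w[5] * p$eps1 * x[7] -
      (1 - w[1]) * p$delta2 * lamS * x[7] - (p$mu + p$dA) * x[7],
    p$alpha2 * x[7] - (1 - w[1]) * p$delta3 * lamS * x[8] -
      (p$mu + p$dPA) * x[8],
    (1 - w[1]) * p$delta2 * lamS * x[7] + (1 - w[1]) * p$delta3 * lamS * x[8] +
      (1 - w[2]) * p$rho3 * lamA * x[4] + (1 - w[2]) * p$rho2 * lamA * x[5] -
      (p$alpha + w[6] * p$eps3 + p$mu + p$dC) * x[9],
    p$alpha * x[9] - (p$mu + p$dSA) * x[10],
    w[6] * p$eps3 * x[9] + w[5] * p$eps1 * x[7] + w[4] * p$eps2 * x[4] -
      p$mu * x[11])
}

#' Controlled model right-hand side
#'
#' Time derivative of the eleven compartments under the six time-dependent
#' controls `w1..w6` (protection and treatment efforts, each in \[0, 1\]).
#'
#' @param t time (unused).
#' @param state named full-model state vector.
#' @param w numeric length-6 control vector in \[0, 1\].
#' @param params an [addiction_params()] object.
#' @return Named derivative vector.
#' @export
controlled_rhs <- function(t, state, w, params) {
  if (length(w) != 6 || any(w < 0 | w > 1))
    stop("w must be six values in [0, 1]")
  nm <- state_names("full")
  stats::setNames(crhs_kernel(as.numeric(state[nm]), w, params), nm)
}

# Analytic Jacobian of the controlled RHS with respect to the state.
controlled_jacobian <- function(x, w, p) {
  N <- sum(x)
  aA <- x[7] + x[8] + p$theta1 * (x[9] + x[10])
  aS <- x[4] + x[5] + p$theta2 * (x[9] + x[10])
  lamA <- p$beta1 * aA / N
  lamS <- p$beta2 * aS / N
  eA <- c(0, 0, 0, 0, 0, 0, 1, 1, p$theta1, p$theta1, 0)
  eS <- c(0, 0, 0, 1, 1, 0, 0, 0, p$theta2, p$theta2, 0)
  gA <- p$beta1 * eA / N - lamA / N   # gradient of lamA
  gS <- p$beta2 * eS / N - lamS / N
  J <- matrix(0, 11, 11)
  J[1, ] <- -(1 - w[1]) * x[1] * gS - (1 - w[2]) * x[1] * gA
  J[1, 1] <- J[1, 1] - (1 - w[1]) * lamS - (1 - w[2]) * lamA -
    w[3] * p$delta - p$mu
  J[2, ] <- -(1 - w[2]) * p$rho1 * x[2] * gA -
    (1 - w[1]) * p$delta1 * x[2] * gS
  J[2, 1] <- J[2, 1] + w[3] * p$delta
  J[2, 2] <- J[2, 2] - (1 - w[2]) * p$rho1 * lamA -
    (1 - w[1]) * p$delta1 * lamS - p$mu
  J[3, ] <- (1 - w[1]) * (x[1] + p$delta1 * x[2]) * gS
  J[3, 1] <- J[3, 1] + (1 - w[1]) * lamS
  J[3, 2] <- J[3, 2] + (1 - w[1]) * p$delta1 * lamS
  J[3, 3] <- J[3, 3] - (p$mu + p$gamma1)
  J[4, ] <- -(1 - w[4]) * p$rho3 * x[4] * gA
  J[4, 3] <- J[4, 3] + p$gamma1
  J[4, 4] <- J[4, 4] - (1 - w[4]) * p$rho3 * lamA -
    (w[4] * p$eps2 + p$gamma2 + p$mu + p$dS)
  J[5, ] <- -(1 - w[4]) * p$rho2 * x[5] * gA
  J[5, 4] <- J[5, 4] + p$gamma2
  J[5, 5] <- J[5, 5] - (1 - w[4]) * p$rho2 * lamA - (p$mu + p$dPS)
  J[6, ] <- (1 - w[2]) * (x[1] + p$rho1 * x[2]) * gA
  J[6, 1] <- J[6, 1] + (1 - w[2]) * lamA
  J[6, 2] <- J[6, 2] + (1 - w[2]) * p$rho1 * lamA
  J[6, 6] <- J[6, 6] - (p$mu + p$alpha1)
  J[7, ] <- -(1 - w[1]) * p$delta2 * x[7] * gS
  J[7, 6] <- J[7, 6] + p$alpha1
  J[7, 7] <- J[7, 7] - (1 - w[1]) * p$delta2 * lamS -
    (p$alpha2 + w[5] * p$eps1 + p$mu + p$dA)
  J[8, ] <- -(1 - w[1]) * p$delta3 * x[8] * gS
  J[8, 7] <- J[8, 7] + p$alpha2
  J[8, 8] <- J[8, 8] - (1 - w[1]) * p$delta3 * lamS - (p$mu + p$dPA)
  J[9, ] <- (1 - w[1]) * p$delta2 * x[7] * gS +
    (1 - w[1]) * p$delta3 * x[8] * gS +
    (1 - w[2]) * p$rho3 * x[4] * gA + (1 - w[2]) * p$rho2 * x[5] * gA
  J[9, 4] <- J[9, 4] + (1 - w[2]) * p$rho3 * lamA
  J[9, 5] <- J[9, 5] + (1 - w[2]) * p$rho2 * lamA
  J[9, 7] <- J[9, 7] + (1 - w[1]) * p$delta2 * lamS
  J[9, 8] <- J[9, 8] + (1 - w[1]) * p$delta3 * lamS
  J[9, 9] <- J[9, 9] - (p$alpha + w[6] * p$eps3 + p$mu + p$dC)
  J[10, 9] <- p$alpha
  J[10, 10] <- -(p$mu + p$dSA)
  J[11, 4] <- w[4] * p$eps2
  J[11, 7] <- w[5] * p$eps1
  J[11, 9] <- w[6] * p$eps3
  J[11, 11] <- -p$mu
  J
}

# burden-weight gradient of the running cost w.r.t. the state
running_cost_grad <- function(D) {
  g <- numeric(11)
  g[c(4, 5, 7, 8, 9, 10)] <- D
  g
}

#' Hamiltonian of the optimal-control problem
#'
#' Running cost plus the adjoint-weighted controlled right-hand side,
#' \eqn{H = L(x, w) + f \cdot \chi(x, w)}. The Hamiltonian is the single
#' source of truth for the optimality system: the adjoint equations are its
#' negative state gradient and the control characterization minimizes it
#' pointwise.
#'
#' @param state named full-model state vector.
#' @param w length-6 control vector.
#' @param adjoint length-11 costate vector.
#' @param weights a [control_weights()] object.
#' @param params an [addiction_params()] object.
#' @return Scalar.
#' @export
hamiltonian <- function(state, w, adjoint, weights, params) {
  x <- as.numeric(state[state_names("full")])
  L <- sum(weights$D * x[c(4, 5, 7, 8, 9, 10)]) + 0.5 * sum(weights$psi * w^2)
  L + sum(as.numeric(adjoint) * crhs_kernel(x, w, params))
}

#' Adjoint (costate) system right-hand side
#'
#' \eqn{df/dt = -\partial H/\partial x}, computed analytically from the
#' Jacobian of the implemented controlled right-hand side:
#' \eqn{-\nabla_x L - J(x, w)^\top f}. A finite-difference gradient of
#' [hamiltonian()] is the test oracle.
#'
#' @param t time (unused).
#' @param state named full-model state at time `t`.
#' @param w length-6 control vector at time `t`.
#' @param adjoint length-11 costate vector.
#' @param weights a [control_weights()] object.
#' @param params an [addiction_params()] object.
#' @return Length-11 costate derivative.
#' @export
adjoint_rhs <- function(t, state, w, adjoint, weights, params) {
  x <- as.numeric(state[state_names("full")])
  J <- controlled_jacobian(x, w, params)
  -(running_cost_grad(weights$D) + drop(crossprod(J, as.numeric(adjoint))))
}

# Direct transcription of the published costate equations. Several of its
# components contain typographical errors relative to -dH/dx (swapped
# treatment rates between the smoking and alcohol branches, N* where S*
# belongs, a rho2 P* where gamma2-free decay belongs, a missing natural-decay
# term); the agreement and the divergences are pinned down in the test suite
# and discussed in the methods vignette. Kept for reference only.
adjoint_rhs_printed <- function(t, state, w, adjoint, weights, params) {
  p <- params
  x <- as.numeric(state[state_names("full")])
  f <- as.numeric(adjoint)
  D <- weights$D
  N <- sum(x)
  lamA <- p$beta1 * (x[7] + x[8] + p$theta1 * (x[9] + x[10])) / N
  lamS <- p$beta2 * (x[4] + x[5] + p$theta2 * (x[9] + x[10])) / N
  c((1 - w[1]) * lamS * (f[1] - f[3]) + (1 - w[2]) * lamA * (f[1] - f[6]) +
      w[3] * p$delta * (f[1] - f[2]) + p$mu * f[1],
    (1 - w[2]) * p$rho1 * lamA * (f[2] - f[6]) +
      (1 - w[1]) * p$delta1 * lamS * (f[2] - f[3]) + p$mu * f[2],
    p$mu * f[3] + p$gamma1 * (f[3] - f[4]),
    -D[1] + (1 - w[1]) * (p$beta2 / N) *
      (x[1] * (f[1] - f[3]) + p$delta1 * x[2] * (f[2] - f[3]) +
         x[7] * p$delta2 * (f[7] - f[9]) + x[8] * p$delta3 * (f[8] - f[9])) +
      p$gamma2 * (f[4] - f[5]) + (1 - w[2]) * (f[4] - f[9]) * p$rho3 * lamA +
      (w[5] * p$eps2 + p$mu) * f[4],
    -D[2] + (1 - w[1]) * (p$beta2 / N) *
      (N * (f[1] - f[3]) + p$delta1 * x[2] * (f[2] - f[3]) +
         p$delta2 * x[7] * (f[7] - f[9]) + p$rho2 * x[8] * (f[8] - f[9])) +
      (1 - w[2]) * p$rho2 * lamA * (f[5] - f[9]),
    p$mu * f[6] + p$alpha1 * (f[6] - f[7]),
    -D[3] + (1 - w[2]) * (p$beta1 / N) *
      (x[1] * (f[1] - f[6]) + p$rho1 * x[2] * (f[2] - f[6]) +
         p$rho3 * x[4] * (f[4] - f[9]) + p$rho2 * x[2] * (f[5] - f[9])) +
      (1 - w[1]) * p$delta2 * lamS * (f[7] - f[9]) +
      p$alpha2 * (f[7] - f[8]) + w[4] * p$eps1 * (f[7] - f[11]) + p$mu * f[7],
    -D[4] + (1 - w[2]) * (p$beta1 / N) *
      (x[1] * (f[1] - f[6]) + p$rho1 * x[2] * (f[2] - f[6]) +
         p$rho3 * x[4] * (f[4] - f[9])) +
      (1 - w[1]) * p$delta3 * lamS * (f[8] - f[9]) + p$mu * f[8],
    -D[5] + (1 - w[1]) * p$beta2 * p$theta1 / N *
      (x[1] * (f[1] - f[3]) + p$delta1 * x[2] * (f[2] - f[3]) +
         p$delta2 * x[7] * (f[7] - f[9]) + p$rho3 * x[8] * (f[8] - f[9])) +
      (1 - w[2]) * p$beta1 * p$alpha1 / N *
      (x[1] * (f[1] - f[6]) + p$rho3 * x[4] * (f[4] - f[9]) +
         p$rho1 * x[2] * (f[2] - f[6]) + p$rho2 * x[8] * (f[5] - f[9])) +
      p$mu * f[9] + p$alpha * (f[9] - f[10]) + w[6] * p$eps3 * (f[9] - f[11]),
    -D[6] + (1 - w[1]) * p$beta2 * p$theta1 / N *
      (x[1] * (f[1] - f[3]) + p$delta1 * x[2] * (f[2] - f[3]) +
         p$delta2 * x[7] * (f[7] - f[9]) + p$delta3 * x[8] * (f[8] - f[9])) +
      (1 - w[2]) * p$beta1 * p$alpha1 / N *
      (x[1] * (f[1] - f[6]) + p$rho3 * x[4] * (f[4] - f[9]) +
         p$rho1 * x[2] * (f[2] - f[6]) + p$rho2 * x[8] * (f[5] - f[9])) +
      p$mu * f[10],
    p$mu * f[11])
}

#' Pointwise optimal control update
#'
#' The Hamiltonian is an explicit quadratic in each control with no
#' cross-control terms, so the pointwise minimizer of control `i` is the
#' unconstrained stationary point \eqn{-L_i/\psi_i} clipped to \[0, 1\],
#' where the linear coefficient \eqn{L_i} is extracted from two evaluations
#' of the implemented Hamiltonian (so transcription typos cannot leak into
#' the characterization). Inactive controls return 0.
#'
#' @param state named full-model state.
#' @param adjoint length-11 costate vector.
#' @param weights a [control_weights()] object.
#' @param params an [addiction_params()] object.
#' @param mask logical length-6 mask of active controls (default: all).
#' @return Length-6 control vector in \[0, 1\].
#' @export
control_update <- function(state, adjoint, weights, params,
                           mask = rep(TRUE, 6)) {
  mask <- strategy_mask(mask)
  x <- as.numeric(state[state_names("full")])
  f <- as.numeric(adjoint)
  H0 <- hamiltonian_kernel(x, numeric(6), f, weights, params)
  w <- numeric(6)
  for (i in which(mask)) {
    ei <- numeric(6); ei[i] <- 1
    Li <- hamiltonian_kernel(x, ei, f, weights, params) - H0 -
      weights$psi[i] / 2
    w[i] <- min(1, max(0, -Li / weights$psi[i]))
  }
  w
}

hamiltonian_kernel <- function(x, w, f, weights, params) {
  sum(weights$D * x[c(4, 5, 7, 8, 9, 10)]) + 0.5 * sum(weights$psi * w^2) +
    sum(f * crhs_kernel(x, w, params))
}

#' Objective functional
#'
#' Trapezoid-rule quadrature of the running cost over the shared time grid of
#' a trajectory and a control schedule.
#'
#' @param traj an `addiction_trajectory` (full model) or data frame with
#'   column `t` and the eleven compartments.
#' @param controls matrix or data frame of control values, `length(t)` rows
#'   and 6 columns (a `t` column, if present, must match the trajectory grid).
#' @param weights a [control_weights()] object.
#' @return Scalar cost `J`.
#' @export
objective_functional <- function(traj, controls, weights) {
  tgrid <- traj$t
  W <- control_matrix(controls, tgrid)
  burden <- as.matrix(traj[c("IS", "PS", "IA", "PA", "CSA", "PSA")]) %*%
    weights$D
  effort <- 0.5 * (W^2 %*% weights$psi)
  pracma::trapz(tgrid, as.numeric(burden + effort))
}

control_matrix <- function(controls, tgrid) {
  if (is.data.frame(controls)) {
    if ("t" %in% names(controls)) {
      if (nrow(controls) != length(tgrid) ||
          max(abs(controls$t - tgrid)) > 1e-9 * max(1, max(abs(tgrid))))
        stop("control schedule and trajectory grids do not match")
      controls <- controls[setdiff(names(controls), "t")]
    }
    controls <- as.matrix(controls)
  }
  if (is.null(dim(controls)))
    controls <- matrix(controls, length(tgrid), 6, byrow = TRUE)
  if (nrow(controls) != length(tgrid) || ncol(controls) != 6)
    stop("control schedule and trajectory grids do not match")
  controls
}

#' Forward-backward sweep solver
#'
#' Solves the Pontryagin optimality system by the classical iterative scheme:
#' forward RK4 integration of the controlled state system, backward RK4
#' integration of the adjoint system from the zero terminal (transversality)
#' condition, pointwise control update from the Hamiltonian, and convex
#' relaxation `w <- (1 - relaxation) * w_old + relaxation * w_new`, iterated
#' until the maximum control change (relative to the control scale, with an
#' absolute floor of 1) drops below `tol`. State values at RK4 half-steps of
#' the backward pass are linearly interpolated between grid nodes so the
#' forward and backward passes share one fixed uniform grid.
#'
#' @param params an [addiction_params()] object.
#' @param weights a [control_weights()] object.
#' @param strategy strategy id `"A"`..`"I"` (see [strategy_catalog()]) or a
#'   custom mask of active controls.
#' @param init initial state (default [addiction_state()]).
#' @param t_final horizon (years).
#' @param n_steps RK4 steps.
#' @param tol convergence tolerance on the control change.
#' @param max_iter maximum sweep iterations; non-convergence is flagged in
#'   the result, not raised.
#' @param relaxation convex relaxation factor in (0, 1].
#' @return Object of class `"addiction_ocp"`: list with `trajectory`,
#'   `controls` (data frame `t, w1..w6`), `adjoint`, objective `objective`,
#'   per-iteration `objective_history`, `iterations`, `converged`, `strategy`,
#'   `mask`, and the uncontrolled reference objective `objective_uncontrolled`.
#' @examples
#' \donttest{
#' sol <- forward_backward_sweep(addiction_params(), strategy = "A",
#'                               t_final = 5, n_steps = 250)
#' sol$objective
#' }
#' @export
forward_backward_sweep <- function(params, weights = control_weights(),
                                   strategy = "I", init = addiction_state(),
                                   t_final = 5, n_steps = 1000, tol = 1e-3,
                                   max_iter = 100, relaxation = 0.5) {
  if (tol <= 0) stop("tol must be positive")
  mask <- strategy_mask(strategy)
  nm <- state_names("full")
  x0 <- as.numeric(init[nm])
  n <- n_steps + 1L
  times <- seq(0, t_final, length.out = n)
  h <- times[2L] - times[1L]
  W <- matrix(0, n, 6)
  forward <- function(W) {
    X <- matrix(NA_real_, n, 11)
    X[1L, ] <- x0
    x <- x0
    for (i in seq_len(n - 1L)) {
      wh <- (W[i, ] + W[i + 1L, ]) / 2
      k1 <- crhs_kernel(x, W[i, ], params)
      k2 <- crhs_kernel(x + h / 2 * k1, wh, params)
      k3 <- crhs_kernel(x + h / 2 * k2, wh, params)
      k4 <- crhs_kernel(x + h * k3, W[i + 1L, ], params)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(x)))
        stop("non-finite state in forward sweep at step ", i)
      X[i + 1L, ] <- x
    }
    X
  }
  gL <- running_cost_grad(weights$D)
  backward <- function(X, W) {
    Fm <- matrix(NA_real_, n, 11)
    f <- numeric(11)          # transversality: f(T_F) = 0
    Fm[n, ] <- f
    arhs <- function(x, w, f)
      -(gL + drop(crossprod(controlled_jacobian(x, w, params), f)))
    for (i in seq(n - 1L, 1L)) {
      xh <- (X[i, ] + X[i + 1L, ]) / 2
      wh <- (W[i, ] + W[i + 1L, ]) / 2
      k1 <- arhs(X[i + 1L, ], W[i + 1L, ], f)
      k2 <- arhs(xh, wh, f - h / 2 * k1)
      k3 <- arhs(xh, wh, f - h / 2 * k2)
      k4 <- arhs(X[i, ], W[i, ], f - h * k3)
      f <- f - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(f)))
        stop("non-finite costate in backward sweep at step ", i)
      Fm[i, ] <- f
    }
    Fm
  }
  objective <- function(X, W) {
    burden <- X[, c(4, 5, 7, 8, 9, 10)] %*% weights$D
    pracma::trapz(times, as.numeric(burden + 0.5 * (W^2 %*% weights$psi)))
  }
  X <- forward(W)
  J_unc <- objective(X, W)
  J_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  Fm <- matrix(0, n, 11)
  while (iter < max_iter) {
    iter <- iter + 1L
    Fm <- backward(X, W)
    Wnew <- W
    for (i in seq_len(n)) {
      Wnew[i, ] <- control_update_kernel(X[i, ], Fm[i, ], weights, params,
                                         mask)
    }
    Wrel <- (1 - relaxation) * W + relaxation * Wnew
    delta <- max(abs(Wrel - W)) / max(1, max(abs(Wrel)))
    W <- Wrel
    X <- forward(W)
    J_hist <- c(J_hist, objective(X, W))
    if (delta < tol) { converged <- TRUE; break }
  }
  J <- objective(X, W)
  traj <- data.frame(t = times, X, N = rowSums(X))
  names(traj) <- c("t", nm, "N")
  attr(traj, "submodel") <- "full"
  attr(traj, "params") <- params
  class(traj) <- c("addiction_trajectory", "data.frame")
  controls <- data.frame(t = times, W)
  names(controls) <- c("t", paste0("w", 1:6))
  adjoint <- data.frame(t = times, Fm)
  names(adjoint) <- c("t", paste0("f", 1:11))
  structure(list(trajectory = traj, controls = controls, adjoint = adjoint,
                 objective = J, objective_history = J_hist,
                 objective_uncontrolled = J_unc, iterations = iter,
                 converged = converged,
                 strategy = if (is.character(strategy)) strategy else "custom",
                 mask = mask, weights = weights, t_final = t_final),
            class = "addiction_ocp")
}

# unnamed-vector variant of control_update used in the sweep inner loop
control_update_kernel <- function(x, f, weights, params, mask) {
  H0 <- hamiltonian_kernel(x, numeric(6), f, weights, params)
  w <- numeric(6)
  for (i in which(mask)) {
    ei <- numeric(6); ei[i] <- 1
    Li <- hamiltonian_kernel(x, ei, f, weights, params) - H0 -
      weights$psi[i] / 2
    w[i] <- min(1, max(0, -Li / weights$psi[i]))
  }
  w
}

#' @export
print.addiction_ocp <- function(x, ...) {
  cat("Optimal control sweep, strategy ", x$strategy,
      " (active controls: ", paste(which(x$mask), collapse = ","), ")\n",
      "  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      "  objective J = ", signif(x$objective, 6),
      "  [uncontrolled J = ", signif(x$objective_uncontrolled, 6), "]\n",
      sep = "")
  invisible(x)
}

#' @export
summary.addiction_ocp <- function(object, ...) {
  w <- as.matrix(object$controls[paste0("w", 1:6)])
  cat("Strategy", object$strategy, "-",
      if (object$converged) "converged" else "not converged",
      "in", object$iterations, "iterations\n")
  cat("J =", signif(object$objective, 6), "; reduction vs no control:",
      sprintf("%.1f%%", 100 * (1 - object$objective /
                                 object$objective_uncontrolled)), "\n")
  cat("mean control levels:",
      paste(sprintf("w%d=%.3f", 1:6, colMeans(w)), collapse = " "), "\n")
  invisible(object)
}

#' @export
plot.addiction_ocp <- function(x, what = c("controls", "burden"), ...) {
  what <- match.arg(what)
  if (what == "controls") {
    W <- as.matrix(x$controls[paste0("w", 1:6)])
    graphics::matplot(x$controls$t, W, type = "l", lty = 1, ylim = c(0, 1),
                      xlab = "time (years)", ylab = "control level", ...)
    graphics::legend("topright", paste0("w", 1:6), lty = 1, col = 1:6,
                     cex = 0.8)
  } else {
    tr <- x$trajectory
    burden <- rowSums(tr[c("IS", "PS", "IA", "PA", "CSA", "PSA")])
    graphics::plot(tr$t, burden, type = "l", xlab = "time (years)",
                   ylab = "addicted burden", ...)
  }
  invisible(x)
}
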