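#' Force of addiction
#'
#' Standard-incidence per-capita rate at which at-risk individuals acquire an
#' addiction. In the full model the alcohol force is
#' \eqn{\lambda_A = \beta_1 (I_A + P_A + \theta_1 (C_{SA} + P_{SA})) / N} and
#' the smoking force is
#' \eqn{\lambda_S = \beta_2 (I_S + P_S + \theta_2 (C_{SA} + P_{SA})) / N}.
#' The single-addiction sub-models drop the dual-addicted terms and use the
#' six-compartment sub-population.
#'
#' @param state named state vector (see [addiction_state()]).
#' @param params an [addiction_params()] object.
#' @param addiction `"alcohol"` or `"smoking"`.
#' @param submodel `"full"`, `"alcohol"` or `"smoking"`.
#' @return Nonnegative scalar rate (1/year).
#' @examples
#' p <- addiction_params()
#' force_of_addiction(addiction_state(), p, "alcohol")
#' @export
force_of_addiction <- function(state, params,
                               addiction = c("alcohol", "smoking"),
                               submodel = "full") {
  addiction <- match.arg(addiction)
  submodel <- match.arg(submodel, c("full", "alcohol", "smoking"))
  if (submodel != "full" && addiction != submodel)
    stop("the ", submodel, " sub-model has no ", addiction, " pathway")
  N <- sum(state)
  if (N <= 0) stop("total population is zero: force of addiction undefined")
  if (addiction == "alcohol") {
    w <- state[["IA"]] + state[["PA"]]
    if (submodel == "full")
      w <- w + params$theta1 * (state[["CSA"]] + state[["PSA"]])
    params$beta1 * w / N
  } else {
    w <- state[["IS"]] + state[["PS"]]
    if (submodel == "full")
      w <- w + params$theta2 * (state[["CSA"]] + state[["PSA"]])
    params$beta2 * w / N
  }
}

#' Right-hand side of the addiction model ODE systems
#'
#' Time derivative of every compartment for the full dual-addiction model or
#' one of the two single-addiction sub-models. The componentwise sum always
#' equals \eqn{K - \mu N - \sum (\text{addiction death terms})}.
#'
#' @param t time (unused; the systems are autonomous).
#' @param state named nonnegative state vector matching `submodel`.
#' @param params an [addiction_params()] object.
#' @param submodel `"full"`, `"alcohol"` or `"smoking"`.
#' @param .check if `FALSE`, skip the nonnegativity guard (used by numerical
#'   differentiation, whose centred perturbations straddle zero).
#' @return Named derivative vector in compartment order.
#' @export
addiction_rhs <- function(t, state, params, submodel = "full", .check = TRUE) {
  submodel <- match.arg(submodel, c("full", "alcohol", "smoking"))
  nm <- state_names(submodel)
  if (!all(nm %in% names(state))) stop("state does not match submodel layout")
  state <- state[nm]
  if (.check && any(state < 0))
    stop("negative state component(s): ",
         paste(nm[state < 0], collapse = ", "))
  p <- params
  switch(submodel,
    full = {
      S <- state[["S"]]; P <- state[["P"]]
      ES <- state[["ES"]]; IS <- state[["IS"]]; PS <- state[["PS"]]
      EA <- state[["EA"]]; IA <- state[["IA"]]; PA <- state[["PA"]]
      CSA <- state[["CSA"]]; PSA <- state[["PSA"]]; TT <- state[["T"]]
      N <- sum(state)
      lamA <- p$beta1 * (IA + PA + p$theta1 * (CSA + PSA)) / N
      lamS <- p$beta2 * (IS + PS + p$theta2 * (CSA + PSA)) / N
      c(S   = (1 - p$pi) * p$K - (lamS + lamA + p$delta + p$mu) * S,
        P   = p$pi * p$K + p$delta * S - (p$rho1 * lamA + p$delta1 * lamS + p$mu) * P,
        ES  = lamS * S + p$delta1 * lamS * P - (p$mu + p$gamma1) * ES,
        IS  = p$gamma1 * ES - (p$eps2 + p$gamma2 + p$rho3 * lamA + p$mu + p$dS) * IS,
        PS  = p$gamma2 * IS - (p$rho2 * lamA + p$mu + p$dPS) * PS,
        EA  = lamA * S + p$rho1 * lamA * P - (p$mu + p$alpha1) * EA,
        IA  = p$alpha1 * EA - (p$alpha2 + p$eps1 + p$delta2 * lamS + p$mu + p$dA) * IA,
        PA  = p$alpha2 * IA - (p$delta3 * lamS + p$mu + p$dPA) * PA,
        CSA = p$delta2 * lamS * IA + p$delta3 * lamS * PA +
              p$rho3 * lamA * IS + p$rho2 * lamA * PS -
              (p$alpha + p$eps3 + p$mu + p$dC) * CSA,
        PSA = p$alpha * CSA - (p$mu + p$dSA) * PSA,
        T   = p$eps3 * CSA + p$eps1 * IA + p$eps2 * IS - p$mu * TT)
    },
    alcohol = {
      S <- state[["S"]]; P <- state[["P"]]
      EA <- state[["EA"]]; IA <- state[["IA"]]; PA <- state[["PA"]]
      TT <- state[["T"]]
      N1 <- sum(state)
      lamA <- p$beta1 * (IA + PA) / N1
      c(S  = (1 - p$pi) * p$K - (lamA + p$delta + p$mu) * S,
        P  = p$pi * p$K + p$delta * S - (p$rho1 * lamA + p$mu) * P,
        EA = lamA * S + p$rho1 * lamA * P - (p$mu + p$alpha1) * EA,
        IA = p$alpha1 * EA - (p$alpha2 + p$eps1 + p$mu + p$dA) * IA,
        PA = p$alpha2 * IA - (p$mu + p$dPA) * PA,
        T  = p$eps1 * IA - p$mu * TT)
    },
    smoking = {
      S <- state[["S"]]; P <- state[["P"]]
      ES <- state[["ES"]]; IS <- state[["IS"]]; PS <- state[["PS"]]
      TT <- state[["T"]]
      N2 <- sum(state)
      lamS <- p$beta2 * (IS + PS) / N2
      c(S  = (1 - p$pi) * p$K - (lamS + p$delta + p$mu) * S,
        P  = p$pi * p$K + p$delta * S - (p$delta1 * lamS + p$mu) * P,
        ES = lamS * S + p$delta1 * lamS * P - (p$mu + p$gamma1) * ES,
        IS = p$gamma1 * ES - (p$eps2 + p$gamma2 + p$mu + p$dS) * IS,
        PS = p$gamma2 * IS - (p$mu + p$dPS) * PS,
        T  = p$eps2 * IS - p$mu * TT)
    })
}

# Classical fixed-step RK4 on a uniform grid. Returns the (n_steps+1) x d
# matrix of states. `f(t, y)` must return the derivative vector. A fixed
# shared grid is used so that the optimal-control forward and backward
# integrations coincide node-for-node.
rk4_integrate <- function(f, y0, times) {
  n <- length(times)
  h <- times[2L] - times[1L]
  out <- matrix(NA_real_, n, length(y0),
                dimnames = list(NULL, names(y0)))
  y <- y0
  out[1L, ] <- y
  for (i in seq_len(n - 1L)) {
    t0 <- times[i]
    k1 <- f(t0, y)
    k2 <- f(t0 + h / 2, y + h / 2 * k1)
    k3 <- f(t0 + h / 2, y + h / 2 * k2)
    k4 <- f(t0 + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("non-finite state at integration step ", i,
           " (t = ", signif(times[i + 1L], 6), ")")
    out[i + 1L, ] <- y
  }
  out
}

#' Simulate an addiction model
#'
#' Integrates the selected system with the classical fourth-order Runge-Kutta
#' scheme on a uniform grid. Small negative overshoot is not clipped; the
#' positivity and boundedness invariants are instead checked by the test suite
#' up to integrator tolerance.
#'
#' @param params an [addiction_params()] object.
#' @param init named initial state (default [addiction_state()] layout for
#'   `submodel`); `S` must be positive and all others nonnegative.
#' @param t_final time horizon (years).
#' @param n_steps number of RK4 steps (grid has `n_steps + 1` points).
#' @param submodel `"full"`, `"alcohol"` or `"smoking"`.
#' @return An object of class `"addiction_trajectory"`: a data frame with the
#'   time column `t`, one column per compartment, and the total `N`, plus
#'   attributes `submodel` and `params`.
#' @examples
#' tr <- simulate_addiction(addiction_params(), t_final = 5, n_steps = 200)
#' head(tr)
#' @export
simulate_addiction <- function(params, init = NULL, t_final = 5,
                               n_steps = 1000, submodel = "full") {
  submodel <- match.arg(submodel, c("full", "alcohol", "smoking"))
  if (is.null(init)) {
    init <- addiction_state(submodel = submodel)
  } else init <- init[state_names(submodel)]
  if (init[["S"]] <= 0 || any(init < 0))
    stop("initial data must have S > 0 and all compartments nonnegative")
  if (t_final <= 0 || n_steps < 1) stop("need t_final > 0 and n_steps >= 1")
  times <- seq(0, t_final, length.out = n_steps + 1L)
  states <- rk4_integrate(function(t, y) addiction_rhs(t, y, params, submodel),
                          init, times)
  out <- data.frame(t = times, states, N = rowSums(states))
  attr(out, "submodel") <- submodel
  attr(out, "params") <- params
  class(out) <- c("addiction_trajectory", "data.frame")
  out
}

#' @export
print.addiction_trajectory <- function(x, ...) {
  cat("Addiction model trajectory (", attr(x, "submodel"), " model): ",
      nrow(x), " time points on [0, ", signif(max(x$t), 4), "]\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  cat("...\n")
  invisible(x)
}

#' @export
plot.addiction_trajectory <- function(x, compartments = NULL, ...) {
  comp <- compartments %||% setdiff(names(x), c("t", "N"))
  graphics::matplot(x$t, as.matrix(x[comp]), type = "l", lty = 1,
                    xlab = "time (years)", ylab = "individuals", ...)
  graphics::legend("topright", legend = comp, lty = 1,
                   col = seq_along(comp), cex = 0.8)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' Column layout: `t,S,P,ES,IS,PS,EA,IA,PA,CSA,PSA,T,N` (sub-models omit the
#' compartments they lack).
#'
#' @param traj an `addiction_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
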