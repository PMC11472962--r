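#' Addiction-free equilibrium
#'
#' Closed-form steady state with every addicted compartment zero:
#' \eqn{S_0 = (1-\pi)K/(\delta+\mu)}, \eqn{P_0 = K(\delta+\pi\mu)/(\mu(\delta+\mu))},
#' so that \eqn{S_0 + P_0 = K/\mu}.
#'
#' @param params an [addiction_params()] object.
#' @param submodel `"full"`, `"alcohol"` or `"smoking"`.
#' @return Named state vector at which the RHS vanishes.
#' @examples
#' addiction_free_equilibrium(addiction_params())
#' @export
addiction_free_equilibrium <- function(params, submodel = "full") {
  submodel <- match.arg(submodel, c("full", "alcohol", "smoking"))
  S0 <- (1 - params$pi) * params$K / (params$delta + params$mu)
  P0 <- params$K * (params$delta + params$pi * params$mu) /
        (params$mu * (params$delta + params$mu))
  x <- stats::setNames(numeric(length(state_names(submodel))),
                       state_names(submodel))
  x["S"] <- S0
  x["P"] <- P0
  x
}

#' Effective reproduction numbers (closed form)
#'
#' The alcohol sub-model value is
#' \deqn{R_{0A} = \frac{\beta_1 \alpha_1 (\alpha_2+\mu+d_{PA})
#'   [\mu(1-\pi)+\rho_1(\delta+\pi\mu)]}
#'   {(\mu+\alpha_1)(\alpha_2+\varepsilon_1+\mu+d_A)(\mu+d_{PA})(\delta+\mu)},}
#' the smoking value is symmetric under
#' \eqn{(\beta_1,\alpha_1,\alpha_2,\rho_1,\varepsilon_1,d_A,d_{PA}) \to
#' (\beta_2,\gamma_1,\gamma_2,\delta_1,\varepsilon_2,d_S,d_{PS})}, and the dual
#' model's value is the maximum of the two. The form is derived from the
#' next-generation construction at the addiction-free equilibrium and is
#' certified against [ngm_r0()] in the test suite.
#'
#' @param params an [addiction_params()] object.
#' @param submodel `"alcohol"`, `"smoking"` or `"dual"`.
#' @return Nonnegative scalar.
#' @examples
#' r0(addiction_params(), "alcohol")
#' @export
r0 <- function(params, submodel = c("alcohol", "smoking", "dual")) {
  submodel <- match.arg(submodel)
  p <- params
  mix <- function(mod) (p$mu * (1 - p$pi) + mod * (p$delta + p$pi * p$mu)) /
    (p$delta + p$mu)
  switch(submodel,
    alcohol = p$beta1 * p$alpha1 * (p$alpha2 + p$mu + p$dPA) * mix(p$rho1) /
      ((p$mu + p$alpha1) * (p$alpha2 + p$eps1 + p$mu + p$dA) * (p$mu + p$dPA)),
    smoking = p$beta2 * p$gamma1 * (p$gamma2 + p$mu + p$dPS) * mix(p$delta1) /
      ((p$mu + p$gamma1) * (p$eps2 + p$gamma2 + p$mu + p$dS) * (p$mu + p$dPS)),
    dual = max(r0(params, "alcohol"), r0(params, "smoking")))
}

#' All reproduction numbers at once
#'
#' @param params an [addiction_params()] object.
#' @return Named vector `c(R0A, R0S, R0AS)` with `R0AS = max(R0A, R0S)`.
#' @export
reproduction_numbers <- function(params) {
  ra <- r0(params, "alcohol")
  rs <- r0(params, "smoking")
  c(R0A = ra, R0S = rs, R0AS = max(ra, rs))
}

#' Next-generation-matrix reproduction number (numeric oracle)
#'
#' Builds the new-addiction matrix `F` and transition matrix `V` by
#' numerically linearizing the implemented right-hand side at the
#' addiction-free equilibrium over the addicted compartments (alcohol:
#' `EA, IA, PA`; smoking: `ES, IS, PS`; dual: all eight addicted classes) and
#' returns the spectral radius of \eqn{F V^{-1}}. Independent of the closed
#' form in [r0()], for which it serves as the oracle.
#'
#' @inheritParams r0
#' @return Nonnegative scalar.
#' @export
ngm_r0 <- function(params, submodel = c("alcohol", "smoking", "dual")) {
  submodel <- match.arg(submodel)
  sys <- if (submodel == "dual") "full" else submodel
  x0 <- addiction_free_equilibrium(params, sys)
  nm <- state_names(sys)
  inf <- switch(submodel,
                alcohol = c("EA", "IA", "PA"),
                smoking = c("ES", "IS", "PS"),
                dual    = c("ES", "IS", "PS", "EA", "IA", "PA", "CSA", "PSA"))
  idx <- match(inf, nm)
  # rate of appearance of new addictions, per compartment
  newinf <- function(x) {
    x <- stats::setNames(x, nm)
    N <- sum(x)
    out <- stats::setNames(numeric(length(nm)), nm)
    if (submodel != "smoking") {
      lamA <- force_of_addiction(x, params, "alcohol", sys)
      out["EA"] <- lamA * (x[["S"]] + params$rho1 * x[["P"]])
    }
    if (submodel != "alcohol") {
      lamS <- force_of_addiction(x, params, "smoking", sys)
      out["ES"] <- lamS * (x[["S"]] + params$delta1 * x[["P"]])
    }
    if (submodel == "dual") {
      lamA <- force_of_addiction(x, params, "alcohol", sys)
      lamS <- force_of_addiction(x, params, "smoking", sys)
      out["CSA"] <- params$delta2 * lamS * x[["IA"]] +
        params$delta3 * lamS * x[["PA"]] +
        params$rho3 * lamA * x[["IS"]] + params$rho2 * lamA * x[["PS"]]
    }
    out[idx]
  }
  rhs_inf <- function(x) addiction_rhs(0, stats::setNames(x, nm), params, sys,
                                       .check = FALSE)[idx]
  Fm <- pracma::jacobian(newinf, x0)[, idx, drop = FALSE]
  Jm <- pracma::jacobian(rhs_inf, x0)[, idx, drop = FALSE]
  Vm <- Fm - Jm
  if (abs(det(Vm)) < .Machine$double.eps * 10)
    stop("transition matrix V is singular")
  max(Mod(eigen(Fm %*% solve(Vm), only.values = TRUE)$values))
}

# Equilibrium compartments of a single-addiction sub-model as a function of
# the candidate equilibrium force lam (>= 0); closed-form cascade from setting
# the sub-model RHS to zero.
equilibrium_from_force <- function(params, submodel, lam) {
  p <- params
  S <- (1 - p$pi) * p$K / (lam + p$delta + p$mu)
  if (submodel == "alcohol") {
    P  <- (p$pi * p$K + p$delta * S) / (p$rho1 * lam + p$mu)
    EA <- lam * (S + p$rho1 * P) / (p$mu + p$alpha1)
    IA <- p$alpha1 * EA / (p$alpha2 + p$eps1 + p$mu + p$dA)
    PA <- p$alpha2 * IA / (p$mu + p$dPA)
    TT <- p$eps1 * IA / p$mu
    c(S = S, P = P, EA = EA, IA = IA, PA = PA, T = TT)
  } else {
    P  <- (p$pi * p$K + p$delta * S) / (p$delta1 * lam + p$mu)
    ES <- lam * (S + p$delta1 * P) / (p$mu + p$gamma1)
    IS <- p$gamma1 * ES / (p$eps2 + p$gamma2 + p$mu + p$dS)
    PS <- p$gamma2 * IS / (p$mu + p$dPS)
    TT <- p$eps2 * IS / p$mu
    c(S = S, P = P, ES = ES, IS = IS, PS = PS, T = TT)
  }
}

#' Endemic fixed-point residual
#'
#' Evaluates the sub-model equilibrium compartments at a candidate equilibrium
#' force of addiction `lam` and returns the self-consistency residual
#' \eqn{g(\lambda) = \lambda - \beta\,(\text{weighted addicted})/N^*}. Roots
#' with `lam > 0` are endemic equilibria; `lam = 0` always solves it (the
#' addiction-free state).
#'
#' @param params an [addiction_params()] object.
#' @param submodel `"alcohol"` or `"smoking"`.
#' @param lam candidate equilibrium force (nonnegative scalar or vector).
#' @return Residual(s), same length as `lam`.
#' @export
endemic_fixed_point_map <- function(params, submodel = c("alcohol", "smoking"),
                                    lam) {
  submodel <- match.arg(submodel)
  if (any(lam < 0)) stop("lam must be nonnegative")
  vapply(lam, function(l) {
    eq <- equilibrium_from_force(params, submodel, l)
    addicted <- if (submodel == "alcohol") eq[["IA"]] + eq[["PA"]]
                else eq[["IS"]] + eq[["PS"]]
    beta <- if (submodel == "alcohol") params$beta1 else params$beta2
    l - beta * addicted / sum(eq)
  }, numeric(1))
}

#' Endemic equilibria of a single-addiction sub-model
#'
#' Positive roots of the fixed-point residual are located by a dense sign scan
#' on \eqn{(0, \beta]} followed by bisection (the force of addiction cannot
#' exceed the dissemination rate because the weighted prevalence fraction is
#' below one). The quadratic structure of the cleared-denominator fixed-point
#' polynomial caps the number of positive roots at two; the coefficients
#' `c(c2, c1, c0)` of that quadratic are recovered numerically and satisfy
#' `c2 > 0` and `sign(c0) = sign(1 - R0)`, which drives the case
#' classification (forward branch for `R0 > 1`; two coexisting endemic states
#' possible for `R0 < 1` with `c1 < 0`).
#'
#' @param params an [addiction_params()] object.
#' @param submodel `"alcohol"` or `"smoking"`.
#' @param n_scan sign-scan resolution.
#' @return List with `roots` (positive equilibrium forces), `coefficients`
#'   (`c2`, `c1`, `c0`), `r0`, and `reports` — one per endemic root, each
#'   holding the equilibrium state, Jacobian eigenvalues and a stability
#'   verdict.
#' @export
endemic_equilibria <- function(params, submodel = c("alcohol", "smoking"),
                               n_scan = 10000) {
  submodel <- match.arg(submodel)
  beta <- if (submodel == "alcohol") params$beta1 else params$beta2
  g <- function(l) endemic_fixed_point_map(params, submodel, l)
  lams <- seq(beta / n_scan, beta, length.out = n_scan)
  gv <- vapply(lams, g, numeric(1))
  roots <- numeric(0)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- stats::uniroot(g, c(lams[i], lams[i + 1]), tol = 1e-13)$root
    roots <- c(roots, r)
  }
  roots <- c(roots, lams[gv == 0])
  roots <- sort(unique(roots))
  if (length(roots) > 2)
    stop("internal inconsistency: more than two positive endemic roots found")
  co <- quadratic_coefficients(params, submodel)
  reports <- lapply(roots, function(l) {
    eq <- equilibrium_from_force(params, submodel, l)
    ev <- jacobian_eigenvalues(params, eq, submodel)
    list(lambda = l, state = eq, eigenvalues = ev$values,
         type = "endemic",
         stability = if (ev$stable) "locally stable" else "unstable")
  })
  list(roots = roots, coefficients = co, r0 = r0(params, submodel),
       reports = reports)
}

# Coefficients of the cleared-denominator quadratic in the equilibrium force:
# W(lam) = g(lam) * N*(lam) * (lam+delta+mu) * (m*lam+mu) / lam is a degree-2
# polynomial (m = rho1 or delta1). Recovered by evaluation at three nodes.
quadratic_coefficients <- function(params, submodel) {
  p <- params
  beta <- if (submodel == "alcohol") p$beta1 else p$beta2
  m <- if (submodel == "alcohol") p$rho1 else p$delta1
  W <- function(l) {
    eq <- equilibrium_from_force(p, submodel, l)
    addicted <- if (submodel == "alcohol") eq[["IA"]] + eq[["PA"]]
                else eq[["IS"]] + eq[["PS"]]
    (l * sum(eq) - beta * addicted) *
      (l + p$delta + p$mu) * (m * l + p$mu) / l
  }
  xs <- beta * c(0.25, 0.5, 0.75)
  ys <- vapply(xs, W, numeric(1))
  co <- solve(cbind(xs^2, xs, 1), ys)
  stats::setNames(as.numeric(co), c("c2", "c1", "c0"))
}

#' Jacobian eigenvalues at an equilibrium
#'
#' Central-difference Jacobian of the selected system at a supplied
#' equilibrium state, with eigenvalues and a local-stability verdict (all real
#' parts negative). Errors if the state is not an equilibrium.
#'
#' @param params an [addiction_params()] object.
#' @param state equilibrium state vector for `submodel`.
#' @param submodel `"full"`, `"alcohol"` or `"smoking"`.
#' @param tol relative residual tolerance for accepting `state` as an
#'   equilibrium.
#' @return List with `values` (complex eigenvalues), `max_real`, and `stable`.
#' @export
jacobian_eigenvalues <- function(params, state, submodel = "full",
                                 tol = 1e-8) {
  submodel <- match.arg(submodel, c("full", "alcohol", "smoking"))
  nm <- state_names(submodel)
  state <- state[nm]
  res <- addiction_rhs(0, state, params, submodel)
  scale <- max(abs(state), params$K)
  if (max(abs(res)) > tol * scale)
    stop("state is not an equilibrium (relative residual ",
         signif(max(abs(res)) / scale, 3), ")")
  f <- function(x) addiction_rhs(0, stats::setNames(x, nm), params, submodel,
                                 .check = FALSE)
  J <- pracma::jacobian(f, state)
  ev <- eigen(J, only.values = TRUE)$values
  list(values = ev, max_real = max(Re(ev)), stable = max(Re(ev)) < 0)
}

#' Routh-Hurwitz test for a monic cubic
#'
#' For \eqn{\lambda^3 + a\lambda^2 + b\lambda + c = 0} all roots have negative
#' real parts iff `a > 0`, `c > 0` and `a b > c`.
#'
#' @param a,b,c real coefficients.
#' @return `TRUE` (stable) or `FALSE`.
#' @examples
#' routh_hurwitz_cubic(6, 11, 6)   # roots -1, -2, -3
#' @export
routh_hurwitz_cubic <- function(a, b, c) {
  a > 0 && c > 0 && a * b > c
}

#' Bifurcation curve of a single-addiction sub-model
#'
#' For each dissemination rate in `beta_grid`, records the reproduction
#' number, every equilibrium force (the zero branch plus endemic roots) and
#' its local stability. Suitable for plotting the classical forward /
#' backward bifurcation diagrams (equilibrium force against R0).
#'
#' @param params an [addiction_params()] object.
#' @param submodel `"alcohol"` or `"smoking"`.
#' @param beta_grid increasing positive vector of dissemination rates.
#' @param n_scan root-scan resolution per beta value.
#' @return Data frame with columns `beta`, `R0`, `lambda_star`, `branch`
#'   (`"addiction-free"`/`"endemic"`), `stable`.
#' @export
bifurcation_curve <- function(params, submodel = c("alcohol", "smoking"),
                              beta_grid, n_scan = 2000) {
  submodel <- match.arg(submodel)
  if (any(beta_grid <= 0) || is.unsorted(beta_grid))
    stop("beta_grid must be positive and increasing")
  bkey <- if (submodel == "alcohol") "beta1" else "beta2"
  rows <- lapply(beta_grid, function(b) {
    p <- params
    p[[bkey]] <- b
    rr <- r0(p, submodel)
    dfe <- addiction_free_equilibrium(p, submodel)
    dfe_st <- jacobian_eigenvalues(p, dfe, submodel)$stable
    out <- data.frame(beta = b, R0 = rr, lambda_star = 0,
                      branch = "addiction-free", stable = dfe_st)
    ee <- endemic_equilibria(p, submodel, n_scan = n_scan)
    if (length(ee$roots))
      out <- rbind(out, data.frame(
        beta = b, R0 = rr, lambda_star = ee$roots, branch = "endemic",
        stable = vapply(ee$reports, function(r)
          identical(r$stability, "locally stable"), logical(1))))
    out
  })
  do.call(rbind, rows)
}

#' Centre-manifold bifurcation coefficients of the dual model
#'
#' Scales the dissemination rate of the dominant pathway so that the dual
#' model's reproduction number equals one (critical value `beta_star`), takes
#' right/left null vectors `u`, `v` of the Jacobian at the addiction-free
#' equilibrium (normalized so `v . u = 1`, with the critical pathway's exposed
#' component of `u` positive, the convention under which the bifurcating
#' branch points into the positive cone), and evaluates the bifurcation
#' coefficients
#' \deqn{a = \sum v_k u_i u_j \partial^2 h_k/\partial z_i \partial z_j, \qquad
#'       b = \sum v_k u_i \partial^2 h_k/\partial z_i \partial \beta}
#' by central finite differences of the right-hand side. Backward bifurcation
#' is declared iff `a > 0` and `b > 0`.
#'
#' @param params an [addiction_params()] object.
#' @param h_rel relative step for the second-order differences.
#' @return List with `beta_star`, `pathway`, `u`, `v`, `a`, `b`, `backward`,
#'   and `zero_eigenvalue` (the residual magnitude of the critical eigenvalue).
#' @export
center_manifold_coefficients <- function(params, h_rel = 1e-4) {
  rn <- reproduction_numbers(params)
  pathway <- if (rn["R0A"] >= rn["R0S"]) "alcohol" else "smoking"
  bkey <- if (pathway == "alcohol") "beta1" else "beta2"
  if (rn[["R0AS"]] <= 0) stop("reproduction number is zero; no critical beta")
  p <- params
  p[[bkey]] <- p[[bkey]] / rn[["R0AS"]]  # R0 is linear in beta
  beta_star <- p[[bkey]]
  nm <- state_names("full")
  x0 <- addiction_free_equilibrium(p, "full")
  f <- function(x, pp) addiction_rhs(0, stats::setNames(x, nm), pp, "full",
                                     .check = FALSE)
  J <- pracma::jacobian(function(x) f(x, p), x0)
  ev <- eigen(J)
  ord <- order(Mod(ev$values))
  if (Mod(ev$values[ord[1]]) > 1e-6)
    stop("no zero eigenvalue at beta_star")
  if (Mod(ev$values[ord[2]]) < 1e-6)
    stop("zero eigenvalue is not simple within tolerance")
  u <- Re(ev$vectors[, ord[1]])
  evl <- eigen(t(J))
  ordl <- order(Mod(evl$values))
  v <- Re(evl$vectors[, ordl[1]])
  exposed <- if (pathway == "alcohol") "EA" else "ES"
  if (u[match(exposed, nm)] < 0) u <- -u
  v <- v / sum(v * u)
  scale <- max(abs(x0))
  h <- h_rel * scale
  a <- sum(v * ((f(x0 + h * u, p) - 2 * f(x0, p) + f(x0 - h * u, p)) / h^2))
  db <- 1e-6 * beta_star
  pp <- p; pp[[bkey]] <- beta_star + db
  pm <- p; pm[[bkey]] <- beta_star - db
  hh <- 1e-5 * scale
  Ju_p <- (f(x0 + hh * u, pp) - f(x0 - hh * u, pp)) / (2 * hh)
  Ju_m <- (f(x0 + hh * u, pm) - f(x0 - hh * u, pm)) / (2 * hh)
  b <- sum(v * (Ju_p - Ju_m)) / (2 * db)
  list(beta_star = beta_star, pathway = pathway,
       u = stats::setNames(u, nm), v = stats::setNames(v, nm),
       a = a, b = b, backward = (a > 0 && b > 0),
       zero_eigenvalue = Mod(ev$values[ord[1]]))
}
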