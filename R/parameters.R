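#' Model parameters for the dual-addiction system
#'
#' Constructs the full parameter set of the smoking-alcohol dual-addiction
#' compartmental model. All arguments default to the baseline calibration used
#' throughout the package's analyses (annual rates; recruitment in persons per
#' year). Any subset can be overridden by name.
#'
#' Parameter roles:
#' \describe{
#'   \item{K, mu}{recruitment rate (persons/year) and natural death rate (1/year).}
#'   \item{pi}{fraction of recruits entering the protected class, in \[0, 1\].}
#'   \item{delta}{protection (education) rate of at-risk individuals (1/year).}
#'   \item{delta1, rho1}{susceptibility modification of protected individuals
#'     to smoking resp. alcohol exposure (dimensionless).}
#'   \item{delta2, delta3, rho2, rho3}{cross-addiction modification multipliers
#'     on the incidence experienced by already-addicted classes (dimensionless).}
#'   \item{beta1, beta2}{alcohol resp. smoking dissemination rates (1/year).}
#'   \item{alpha1, gamma1}{progression from exposed to addicted (alcohol,
#'     smoking; 1/year).}
#'   \item{alpha2, gamma2}{progression from addicted to permanently addicted
#'     (1/year).}
#'   \item{alpha}{progression from dually addicted to permanently dually
#'     addicted (1/year).}
#'   \item{eps1, eps2, eps3}{improvement (rehabilitation) rates of the alcohol,
#'     smoking and dual addicted classes (1/year).}
#'   \item{theta1, theta2}{weighting (>= 1) of the dual-addicted classes in the
#'     alcohol resp. smoking force of addiction.}
#'   \item{dS, dA, dPS, dPA, dC, dSA}{addiction-related death rates of the
#'     addicted, permanently addicted and dual classes (1/year).}
#' }
#'
#' The constructor stops on hard violations (negative rates, `pi` outside
#' \[0, 1\], `theta` below 1) and emits a warning for the soft constraint
#' conflicts reported by [validate_params()].
#'
#' @param ... named parameter overrides.
#' @param .check if `FALSE`, skip validation (used internally by numeric
#'   differentiation, which perturbs parameters by tiny amounts).
#' @return A named list of class `"addiction_params"`.
#' @examples
#' p <- addiction_params()
#' p$beta1
#' addiction_params(alpha1 = 0.0003)$alpha1
#' @export
addiction_params <- function(..., .check = TRUE) {
  p <- default_params()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- lapply(over, as.numeric)
  }
  class(p) <- "addiction_params"
  if (.check) {
    v <- validate_params(p)
    hard <- v[v$severity == "violation", , drop = FALSE]
    if (nrow(hard))
      stop("invalid parameters:\n  ", paste(hard$message, collapse = "\n  "))
    soft <- v[v$severity == "warning", , drop = FALSE]
    if (nrow(soft))
      warning(paste(soft$message, collapse = "; "), call. = FALSE)
  }
  p
}

# Baseline calibration. The progression rate alpha1 is listed twice in the
# source calibration (0.0002 and 0.0003); the first value is the default.
default_params <- function() {
  list(
    K = 20, mu = 0.0135, pi = 0.5, delta = 0.21,
    delta1 = 1.1, delta2 = 1.1, delta3 = 1.1,
    rho1 = 1.2, rho2 = 1.2, rho3 = 1.2,
    eps1 = 0.223, eps2 = 0.01, eps3 = 0.313,
    beta1 = 0.75, beta2 = 0.38,
    alpha1 = 0.0002, alpha2 = 0.56, alpha = 0.54,
    gamma1 = 0.01, gamma2 = 0.321,
    theta1 = 1.05, theta2 = 1.05,
    dS = 0.035, dA = 0.075, dPS = 0.87, dPA = 0.091,
    dC = 0.11, dSA = 0.23
  )
}

#' Validate a parameter set
#'
#' Pure report of constraint violations. Hard violations make the model
#' ill-posed (negative rates, `mu` or `K` not positive, `pi` outside \[0, 1\],
#' `theta1`/`theta2` below 1). Soft warnings flag the documented tension in the
#' baseline calibration: the protected-class modification multipliers
#' `delta1` and `rho1` are described as reductions (< 1) yet the baseline
#' assigns 1.1 and 1.2. Only nonnegativity is enforced for `delta2`, `delta3`,
#' `rho2`, `rho3`, whose published constraint strings are not self-consistent.
#'
#' @param params an [addiction_params()] object (or plain named list).
#' @return A data frame with columns `field`, `severity`
#'   (`"violation"`/`"warning"`) and `message`; zero rows when clean.
#' @examples
#' validate_params(addiction_params())          # two warnings, no violations
#' @export
validate_params <- function(params) {
  out <- data.frame(field = character(), severity = character(),
                    message = character(), stringsAsFactors = FALSE)
  add <- function(field, severity, message)
    rbind(out, data.frame(field = field, severity = severity,
                          message = message, stringsAsFactors = FALSE))
  need <- names(default_params())
  missing <- setdiff(need, names(params))
  if (length(missing))
    return(add(paste(missing, collapse = ","), "violation",
               paste("missing parameter(s):", paste(missing, collapse = ", "))))
  for (nm in need) {
    x <- params[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      out <- add(nm, "violation", paste0(nm, " must be a finite number"))
    else if (x < 0)
      out <- add(nm, "violation", paste0(nm, " = ", x, " is negative"))
  }
  if (nrow(out)) return(out)
  if (params$mu <= 0) out <- add("mu", "violation", "mu must be > 0")
  if (params$K <= 0)  out <- add("K", "violation", "K must be > 0")
  if (params$pi > 1)  out <- add("pi", "violation", "pi must lie in [0, 1]")
  for (nm in c("theta1", "theta2"))
    if (params[[nm]] < 1)
      out <- add(nm, "violation", paste0(nm, " = ", params[[nm]], " but must be >= 1"))
  for (nm in c("delta1", "rho1"))
    if (params[[nm]] >= 1)
      out <- add(nm, "warning",
                 paste0(nm, " = ", params[[nm]],
                        " >= 1: protected individuals are modelled as MORE",
                        " susceptible than unprotected ones"))
  out
}

#' @export
print.addiction_params <- function(x, ...) {
  cat("Dual-addiction model parameters (rates per year):\n")
  print(unlist(x))
  invisible(x)
}

#' Compartment state vectors
#'
#' Builds a named state vector for the full dual-addiction model (11
#' compartments) or one of its single-addiction sub-models (6 compartments).
#' Compartments are person counts: `S` at-risk, `P` protected, `ES`/`IS`/`PS`
#' smoking exposed/addicted/permanently addicted, `EA`/`IA`/`PA` the alcohol
#' analogues, `CSA`/`PSA` dually resp. permanently dually addicted, `T`
#' improved (rehabilitated).
#'
#' @param S,P,ES,IS,PS,EA,IA,PA,CSA,PSA,T compartment sizes (nonnegative).
#' @param submodel `"full"`, `"alcohol"` or `"smoking"`; sub-models keep only
#'   their own addiction chain.
#' @return Named numeric vector.
#' @examples
#' addiction_state()                      # default initial condition
#' addiction_state(submodel = "alcohol")
#' @export
addiction_state <- function(S = 800, P = 300, ES = 60, IS = 40, PS = 20,
                            EA = 60, IA = 40, PA = 20, CSA = 20, PSA = 10,
                            T = 30, submodel = "full") {
  submodel <- match.arg(submodel, c("full", "alcohol", "smoking"))
  x <- c(S = S, P = P, ES = ES, IS = IS, PS = PS, EA = EA, IA = IA,
         PA = PA, CSA = CSA, PSA = PSA, T = T)
  if (any(!is.finite(x)) || any(x < 0))
    stop("compartment sizes must be finite and nonnegative")
  x[state_names(submodel)]
}

state_names <- function(submodel) {
  switch(submodel,
         full    = c("S", "P", "ES", "IS", "PS", "EA", "IA", "PA", "CSA", "PSA", "T"),
         alcohol = c("S", "P", "EA", "IA", "PA", "T"),
         smoking = c("S", "P", "ES", "IS", "PS", "T"),
         stop("unknown submodel: ", submodel))
}
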