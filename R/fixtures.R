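#' Seeded random parameter fixtures
#'
#' Draws valid random parameter sets for property-style testing. Regimes:
#' \describe{
#'   \item{`generic`}{broad log-uniform draws over epidemiologically plausible
#'     ranges; always passes [validate_params()] without hard violations.}
#'   \item{`forward`}{generic draws constrained to `rho1 >= 1` and
#'     `delta1 >= 1`, a region in which the transcritical bifurcation of the
#'     sub-models is provably forward (the protected class is at least as
#'     susceptible as the at-risk class, so no endemic state can persist
#'     below threshold).}
#'   \item{`backward-candidate`}{searches a region capable of backward
#'     bifurcation — protective modification (`rho1 < 1`) combined with high
#'     addiction mortality (`dA >> mu`), fast progression (`alpha1 >> mu`),
#'     high protection uptake (`delta >> mu`) and small protected recruitment
#'     `pi`, with `beta1` rescaled so the alcohol pathway sits just below
#'     threshold — until a draw with two positive endemic roots is found
#'     (bounded number of attempts; errors if exhausted). `beta2` is scaled
#'     down so the alcohol pathway dominates the dual model.}
#' }
#'
#' @param seed integer seed (same seed, same fixture).
#' @param regime `"generic"`, `"forward"` or `"backward-candidate"`.
#' @param r0_target for `"backward-candidate"`: the sub-threshold reproduction
#'   number at which the two-root criterion is checked.
#' @param max_attempts attempt budget for the backward-candidate search.
#' @return An [addiction_params()] object; for `"backward-candidate"` it
#'   carries attributes `roots` (the two endemic forces) and `attempts`.
#' @export
fixture_params <- function(seed, regime = c("generic", "forward",
                                            "backward-candidate"),
                           r0_target = 0.95, max_attempts = 200) {
  regime <- match.arg(regime)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (regime != "backward-candidate") {
    draw <- function() {
      lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
      over <- list(
        K = lu(5, 100), mu = lu(0.005, 0.1), pi = stats::runif(1, 0.05, 0.95),
        delta = lu(0.02, 1),
        delta1 = lu(0.2, 2), delta2 = lu(0.5, 2), delta3 = lu(0.5, 2),
        rho1 = lu(0.2, 2), rho2 = lu(0.5, 2), rho3 = lu(0.5, 2),
        eps1 = lu(0.01, 1), eps2 = lu(0.01, 1), eps3 = lu(0.01, 1),
        beta1 = lu(0.05, 2), beta2 = lu(0.05, 2),
        alpha1 = lu(0.005, 1), alpha2 = lu(0.01, 1), alpha = lu(0.05, 1),
        gamma1 = lu(0.005, 1), gamma2 = lu(0.01, 1),
        theta1 = stats::runif(1, 1, 2), theta2 = stats::runif(1, 1, 2),
        dS = lu(0.01, 0.5), dA = lu(0.01, 0.5), dPS = lu(0.01, 1),
        dPA = lu(0.01, 1), dC = lu(0.02, 1), dSA = lu(0.02, 1))
      if (regime == "forward") {
        over$rho1 <- stats::runif(1, 1, 2)
        over$delta1 <- stats::runif(1, 1, 2)
      }
      suppressWarnings(do.call(addiction_params, over))
    }
    return(draw())
  }
  for (attempt in seq_len(max_attempts)) {
    p <- suppressWarnings(addiction_params(
      K = 20,
      mu = stats::runif(1, 0.005, 0.02),
      pi = stats::runif(1, 0, 0.2),
      delta = stats::runif(1, 0.5, 2),
      rho1 = stats::runif(1, 0.1, 0.6),
      alpha1 = stats::runif(1, 2, 8),
      alpha2 = stats::runif(1, 0.005, 0.05),
      eps1 = stats::runif(1, 0.005, 0.05),
      dA = stats::runif(1, 10, 30),
      dPA = stats::runif(1, 0.005, 0.05)))
    p$beta1 <- p$beta1 / r0(p, "alcohol") * r0_target
    p$beta2 <- p$beta2 / r0(p, "smoking") * 0.1 * r0_target
    ee <- endemic_equilibria(p, "alcohol", n_scan = 4000)
    if (length(ee$roots) == 2L) {
      attr(p, "roots") <- ee$roots
      attr(p, "attempts") <- attempt
      return(p)
    }
  }
  stop("backward-candidate search exhausted after ", max_attempts,
       " attempts")
}
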