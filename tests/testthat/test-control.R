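test_that("the strategy catalogue lists the nine documented combinations", {
  cat9 <- strategy_catalog()
  expect_length(cat9, 9)
  expect_named(cat9, LETTERS[1:9])
  expect_identical(cat9$A, 1:3)
  expect_identical(cat9$B, 4:6)
  expect_identical(cat9$D, c(1L, 2L, 3L, 5L))
  expect_identical(cat9$I, 1:6)
  for (id in setdiff(names(cat9), "B"))
    expect_true(all(1:3 %in% cat9[[id]]))
  expect_error(coaddiction:::strategy_mask("Z"), "unknown strategy")
})

test_that("controlled RHS matches an independent transcription", {
  set.seed(106)
  p <- table_params()
  for (k in 1:10) {
    x <- random_full_state()
    w <- stats::runif(6)
    expect_equal(controlled_rhs(0, x, w, p), oracle_controlled_rhs(x, w, p),
                 tolerance = 1e-13)
  }
  expect_error(controlled_rhs(0, addiction_state(), rep(2, 6), p), "\\[0, 1\\]")
})

test_that("control limits reduce the system as expected", {
  p <- table_params()
  x <- random_full_state()
  # In the controlled system as printed, w = 0 switches off the protection
  # flow (w3 * delta) AND the three rehabilitation flows (w4..w6 multiply
  # eps2, eps1, eps3), so the no-control limit equals the uncontrolled model
  # with delta and the improvement rates set to zero.
  p0 <- table_params(delta = 0, eps1 = 0, eps2 = 0, eps3 = 0)
  expect_equal(controlled_rhs(0, x, rep(0, 6), p),
               addiction_rhs(0, x, p0, "full"), tolerance = 1e-13)
  # with w3 = 1 the protection flow alone is restored
  p3 <- table_params(eps1 = 0, eps2 = 0, eps3 = 0)
  expect_equal(controlled_rhs(0, x, c(0, 0, 1, 0, 0, 0), p),
               addiction_rhs(0, x, p3, "full"), tolerance = 1e-13)
  # full protection: no force of addiction enters any exposed class
  x2 <- x; x2[c("ES", "EA")] <- 0
  d <- controlled_rhs(0, x2, c(1, 1, 1, 0, 0, 0), p)
  expect_equal(d[["ES"]], 0)
  expect_equal(d[["EA"]], 0)
})

test_that("objective functional integrates the running cost exactly", {
  p <- table_params()
  w <- control_weights()
  times <- seq(0, 5, length.out = 101)
  zero <- data.frame(t = times, matrix(0, 101, 11))
  names(zero) <- c("t", full_names)
  zero$S <- 100
  expect_equal(objective_functional(zero, matrix(0, 101, 6), w), 0)
  # constant controls at 0.5 with no addicted burden: J = 6 * (10/2) * .25 * 5
  expect_equal(objective_functional(zero, matrix(0.5, 101, 6), w), 37.5)
  # constant integrand c over the horizon integrates to c * T_F
  zero$IA <- 2
  expect_equal(objective_functional(zero, matrix(0, 101, 6), w),
               7 * 2 * 5)
  expect_error(objective_functional(zero, matrix(0, 50, 6), w),
               "grids do not match")
})

test_that("the Hamiltonian is consistent with its defining pieces", {
  set.seed(107)
  p <- table_params()
  w <- control_weights()
  x <- random_full_state()
  # adjoint = 0, controls = 0: only the burden term remains
  expect_equal(hamiltonian(x, rep(0, 6), rep(0, 11), w, p),
               sum(w$D * x[c("IS", "PS", "IA", "PA", "CSA", "PSA")]))
  # dH/df_i recovers the i-th controlled RHS component (linearity in f)
  wv <- stats::runif(6)
  f <- stats::rnorm(11)
  cr <- controlled_rhs(0, x, wv, p)
  for (i in c(1, 4, 9, 11)) {
    ei <- numeric(11); ei[i] <- 1
    expect_equal(hamiltonian(x, wv, f + ei, w, p) -
                   hamiltonian(x, wv, f, w, p),
                 cr[[i]], tolerance = 1e-9)
  }
})

test_that("adjoint system is the negative state gradient of the Hamiltonian", {
  set.seed(108)
  p <- table_params()
  w <- control_weights()
  for (k in 1:10) {
    x <- random_full_state()
    wv <- stats::runif(6)
    f <- stats::rnorm(11)
    ar <- adjoint_rhs(0, x, wv, f, w, p)
    for (i in seq_len(11)) {
      h <- 1e-6 * max(1, abs(x[[i]]))
      xp <- x; xp[[i]] <- x[[i]] + h
      xm <- x; xm[[i]] <- x[[i]] - h
      fd <- (hamiltonian(xp, wv, f, w, p) - hamiltonian(xm, wv, f, w, p)) /
        (2 * h)
      expect_lt(abs(ar[i] + fd) / max(1, abs(fd)), 1e-6)
    }
  }
})

test_that("adjoint structure: terminal sources and the rehabilitated costate", {
  p <- table_params()
  w <- control_weights()
  x <- addiction_state(S = 500, P = 300, ES = 0, IS = 0, PS = 0, EA = 0,
                       IA = 0, PA = 0, CSA = 0, PSA = 0, T = 40)
  # all addicted classes empty, f = 0 (the transversality state): the only
  # sources are the -D_i burden weights in the addicted costates
  d <- adjoint_rhs(0, x, rep(0.3, 6), rep(0, 11), w, p)
  expect_equal(d[c(4, 5, 7, 8, 9, 10)], -w$D)
  expect_equal(d[c(1, 2, 3, 6, 11)], rep(0, 5))
  # df11/dt = mu * f11 wherever the forces of addiction vanish; at general
  # states -dH/dx additionally carries the standard-incidence feedback of the
  # rehabilitated class through the total population N (the simplified
  # published equation drops it; see the methods vignette)
  set.seed(109)
  for (k in 1:5) {
    xx <- x; xx[c("S", "P", "T")] <- stats::runif(3, 10, 500)
    f <- stats::rnorm(11)
    expect_equal(adjoint_rhs(0, xx, stats::runif(6), f, w, p)[11],
                 p$mu * f[11], tolerance = 1e-12)
    xg <- random_full_state()
    lamA <- force_of_addiction(xg, p, "alcohol")
    expect_gt(lamA, 0)   # feedback term present at general states
  }
})

test_that("published costate transcription agrees where it is typo-free", {
  set.seed(110)
  p <- table_params()
  w <- control_weights()
  for (k in 1:5) {
    # at addiction-free states the forces vanish and the published
    # susceptible/protected/exposed/rehabilitated costate equations coincide
    # with -dH/dx (at general states they omit the standard-incidence
    # population feedback)
    x <- addiction_state(S = stats::runif(1, 50, 500),
                         P = stats::runif(1, 50, 500), ES = 0, IS = 0,
                         PS = 0, EA = 0, IA = 0, PA = 0, CSA = 0, PSA = 0,
                         T = stats::runif(1, 1, 100))
    wv <- stats::runif(6)
    f <- stats::rnorm(11)
    mine <- adjoint_rhs(0, x, wv, f, w, p)
    printed <- coaddiction:::adjoint_rhs_printed(0, x, wv, f, w, p)
    expect_equal(printed[c(1, 2, 3, 6, 11)], mine[c(1, 2, 3, 6, 11)],
                 tolerance = 1e-10)
  }
  # ... while (at least) the IS-costate carries documented transcription
  # errors (w5*eps2 where w4*eps2 belongs, missing force-gradient terms)
  x <- random_full_state()
  f <- stats::rnorm(11)
  wv <- c(0.2, 0.2, 0.2, 0.9, 0.1, 0.2)
  expect_gt(abs(coaddiction:::adjoint_rhs_printed(0, x, wv, f, w, p)[4] -
                  adjoint_rhs(0, x, wv, f, w, p)[4]), 1e-8)
})

test_that("pointwise control update minimizes the Hamiltonian with clipping", {
  p <- table_params()
  w <- control_weights()
  x <- random_full_state()
  # zero adjoint: every control cost is pure effort, minimizer 0
  expect_equal(control_update(x, rep(0, 11), w, p), rep(0, 6))
  # enormous effort weights push all controls to zero
  whuge <- control_weights(psi = rep(1e12, 6))
  expect_lt(max(control_update(x, stats::rnorm(11, 0, 10), whuge, p)), 1e-6)
  # w3 characterization: clip(delta * S * (f1 - f2) / psi3) on a state where
  # only the protection flow is active
  xq <- addiction_state(S = 100, P = 50, ES = 0, IS = 0, PS = 0, EA = 0,
                        IA = 0, PA = 0, CSA = 0, PSA = 0, T = 0)
  f <- numeric(11); f[1] <- 2; f[2] <- 1
  upd <- control_update(xq, f, w, p, mask = 3)
  expect_equal(upd[3], min(1, 0.21 * 100 * (2 - 1) / 10))   # clipped at 1
  expect_equal(upd[-3], rep(0, 5))
  # interior case
  f2 <- numeric(11); f2[1] <- 0.2; f2[2] <- 0.1
  expect_equal(control_update(xq, f2, w, p, mask = 3)[3],
               0.21 * 100 * 0.1 / 10, tolerance = 1e-10)
  # brute-force minimization oracle over a control grid
  set.seed(111)
  fr <- stats::rnorm(11)
  xr <- random_full_state()
  upd <- control_update(xr, fr, w, p)
  for (i in 1:6) {
    grid <- seq(0, 1, length.out = 201)
    Hvals <- vapply(grid, function(wi) {
      wv <- upd; wv[i] <- wi
      hamiltonian(xr, wv, fr, w, p)
    }, numeric(1))
    expect_lte(hamiltonian(xr, upd, fr, w, p), min(Hvals) + 1e-8)
  }
})

test_that("forward-backward sweep: masks, admissibility, improvement", {
  p <- table_params()
  w <- control_weights()
  sol <- forward_backward_sweep(p, w, "A", t_final = 5, n_steps = 150)
  expect_true(sol$converged)
  W <- as.matrix(sol$controls[paste0("w", 1:6)])
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(unname(W[, 4:6]), matrix(0, nrow(W), 3))  # inactive exactly 0
  expect_lte(sol$objective, sol$objective_uncontrolled)
  # J history non-increasing after the first iteration (1% slack)
  if (length(sol$objective_history) > 1) {
    J <- sol$objective_history
    expect_true(all(diff(J) <= 0.01 * J[-length(J)]))
  }
  # terminal transversality
  expect_equal(unname(as.numeric(sol$adjoint[nrow(sol$adjoint),
                                             paste0("f", 1:11)])),
               rep(0, 11))
  # optimum beats random admissible constant controls under the same mask
  set.seed(112)
  for (k in 1:15) {
    wc <- numeric(6)
    wc[1:3] <- stats::runif(3)
    expect_lte(sol$objective,
               constant_control_objective(p, wc, w) + 1e-6)
  }
})

test_that("prohibitive effort cost recovers the uncontrolled solution", {
  p <- table_params()
  whuge <- control_weights(psi = rep(1e9, 6))
  sol <- forward_backward_sweep(p, whuge, "I", t_final = 5, n_steps = 120)
  W <- as.matrix(sol$controls[paste0("w", 1:6)])
  expect_lt(max(abs(W)), 1e-5)
  expect_equal(sol$objective, sol$objective_uncontrolled, tolerance = 1e-6)
})
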