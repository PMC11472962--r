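test_that("addiction-free equilibrium matches the closed form", {
  p <- table_params()
  dfe <- addiction_free_equilibrium(p, "full")
  expect_equal(dfe[["S"]], 10 / 0.2235, tolerance = 1e-12)   # 44.743
  expect_equal(dfe[["P"]], 1436.7, tolerance = 1e-4)
  expect_equal(dfe[["S"]] + dfe[["P"]], p$K / p$mu, tolerance = 1e-12)
  expect_true(all(dfe[c("ES", "IS", "PS", "EA", "IA", "PA", "CSA",
                        "PSA", "T")] == 0))
  # limit case pi = 1: nobody is recruited at risk
  p1 <- table_params(pi = 1)
  dfe1 <- addiction_free_equilibrium(p1, "alcohol")
  expect_equal(dfe1[["S"]], 0)
  expect_equal(dfe1[["P"]], p1$K / p1$mu)
  # equilibrium property for every submodel
  for (sm in c("full", "alcohol", "smoking")) {
    d <- addiction_rhs(0, addiction_free_equilibrium(p, sm), p, sm)
    expect_lt(max(abs(d)), 1e-12)
  }
})

test_that("closed-form reproduction numbers: zero, linearity, NGM agreement", {
  p <- table_params()
  expect_equal(r0(table_params(beta1 = 0), "alcohol"), 0)
  expect_equal(r0(table_params(beta1 = 1.5), "alcohol"),
               2 * r0(p, "alcohol"), tolerance = 1e-14)
  expect_equal(r0(p, "alcohol"), ngm_r0(p, "alcohol"), tolerance = 1e-10)
  expect_equal(r0(p, "alcohol"), 0.0954, tolerance = 1e-3)
  rn <- reproduction_numbers(p)
  expect_identical(rn[["R0AS"]], max(rn[["R0A"]], rn[["R0S"]]))
  expect_equal(ngm_r0(p, "dual"), rn[["R0AS"]], tolerance = 1e-10)
})

test_that("closed form equals the NGM spectral radius on random draws", {
  for (k in 1:25) {
    p <- fixture_params(600 + k, "generic")
    expect_equal(r0(p, "alcohol"), ngm_r0(p, "alcohol"),
                 tolerance = 1e-8)
    expect_equal(r0(p, "smoking"), ngm_r0(p, "smoking"),
                 tolerance = 1e-8)
  }
})

test_that("fixed-point residual vanishes at the addiction-free state and roots", {
  p <- table_params()
  expect_equal(endemic_fixed_point_map(p, "alcohol", 0), 0)
  p2 <- table_params()
  p2$beta2 <- p2$beta2 / r0(p2, "smoking") * 2        # R0S = 2
  ee <- endemic_equilibria(p2, "smoking")
  expect_length(ee$roots, 1)
  expect_lt(abs(endemic_fixed_point_map(p2, "smoking", ee$roots)), 1e-10)
  # residual changes sign on (0, beta] above threshold
  g <- endemic_fixed_point_map(p2, "smoking",
                               seq(1e-6, p2$beta2, length.out = 500))
  expect_true(any(diff(sign(g)) != 0))
})

test_that("endemic root counts follow the threshold case table", {
  set.seed(104)
  for (k in 1:6) {
    p <- fixture_params(700 + k, "forward")
    for (target in c(0.7, 1.6)) {
      pp <- p
      pp$beta1 <- p$beta1 / r0(p, "alcohol") * target
      ee <- endemic_equilibria(pp, "alcohol", n_scan = 2000)
      expect_length(ee$roots, if (target > 1) 1L else 0L)
      expect_gt(ee$coefficients[["c2"]], 0)
      expect_equal(sign(ee$coefficients[["c0"]]), sign(1 - target))
    }
  }
})

test_that("backward-bifurcation fixtures show two sub-threshold equilibria", {
  bp <- fixture_params(42, "backward-candidate")
  expect_lt(r0(bp, "alcohol"), 1)
  ee <- endemic_equilibria(bp, "alcohol")
  expect_length(ee$roots, 2)
  expect_lt(ee$coefficients[["c1"]], 0)
  expect_gt(ee$coefficients[["c0"]], 0)
  # classic stability layout: lower branch unstable, upper stable, DFE stable
  stab <- vapply(ee$reports, function(r) r$stability, character(1))
  expect_identical(stab, c("unstable", "locally stable"))
  dfe <- addiction_free_equilibrium(bp, "alcohol")
  expect_true(jacobian_eigenvalues(bp, dfe, "alcohol")$stable)
})

test_that("Routh-Hurwitz cubic verdicts match explicit roots", {
  expect_true(routh_hurwitz_cubic(6, 11, 6))     # roots -1, -2, -3
  expect_false(routh_hurwitz_cubic(1, 1, -1))    # c < 0
  expect_false(routh_hurwitz_cubic(1, 1, 2))     # a b < c
  expect_false(all(Re(polyroot(c(2, 1, 1, 1))) < 0))
  set.seed(105)
  for (k in 1:100) {
    co <- stats::rnorm(3, 0, 3)
    expect_identical(routh_hurwitz_cubic(co[1], co[2], co[3]),
                     all(Re(polyroot(c(co[3], co[2], co[1], 1))) < 0))
  }
})

test_that("DFE stability flips with the reproduction number", {
  p <- table_params()
  for (target in c(0.5, 2)) {
    pp <- p
    pp$beta1 <- p$beta1 / r0(p, "alcohol") * target
    dfe <- addiction_free_equilibrium(pp, "alcohol")
    je <- jacobian_eigenvalues(pp, dfe, "alcohol")
    if (target < 1) expect_lt(je$max_real, 0) else expect_gt(je$max_real, 0)
  }
  expect_error(jacobian_eigenvalues(p, addiction_state(), "full"),
               "not an equilibrium")
})

test_that("bifurcation curve has the expected branch structure", {
  p <- table_params()
  bstar <- p$beta1 / r0(p, "alcohol")
  bc <- bifurcation_curve(p, "alcohol", bstar * c(0.6, 0.9, 1.1, 1.4),
                          n_scan = 1500)
  # the addiction-free branch exists for every beta
  expect_equal(sum(bc$branch == "addiction-free"), 4)
  # forward regime: endemic branch only above threshold
  expect_identical(bc$R0[bc$branch == "endemic"] > 1,
                   rep(TRUE, sum(bc$branch == "endemic")))
  # backward regime: sub-threshold interval carries two endemic branches
  bp <- fixture_params(42, "backward-candidate")
  bps <- bp$beta1 / r0(bp, "alcohol")
  bcb <- bifurcation_curve(bp, "alcohol", bps * c(0.95, 1.05), n_scan = 1500)
  sub <- bcb[bcb$R0 < 1 & bcb$branch == "endemic", ]
  expect_equal(nrow(sub), 2)
  expect_identical(sub$stable[order(sub$lambda_star)], c(FALSE, TRUE))
  expect_error(bifurcation_curve(p, "alcohol", c(2, 1)), "increasing")
})

test_that("centre-manifold coefficients locate the threshold and its direction", {
  p <- table_params()
  cm <- center_manifold_coefficients(p)
  pp <- p
  pp[[if (cm$pathway == "alcohol") "beta1" else "beta2"]] <- cm$beta_star
  expect_equal(r0(pp, "dual"), 1, tolerance = 1e-8)
  expect_lt(cm$zero_eigenvalue, 1e-6)
  expect_gt(cm$b, 0)
  expect_lt(cm$a, 0)          # baseline calibration bifurcates forward
  expect_false(cm$backward)
  # the two backward-bifurcation detectors agree on both fixture types
  bp <- fixture_params(42, "backward-candidate")
  cmb <- center_manifold_coefficients(bp)
  expect_identical(cmb$pathway, "alcohol")
  expect_gt(cmb$a, 0)
  expect_gt(cmb$b, 0)
  expect_true(cmb$backward)
  fp <- fixture_params(43, "forward")
  cmf <- center_manifold_coefficients(fp)
  expect_lt(cmf$a, 0)
  expect_gt(cmf$b, 0)
})
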