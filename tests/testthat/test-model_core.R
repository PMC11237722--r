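test_that("presets carry the default parameterization of each mode", {
  comp <- preset_params("competition")
  expect_equal(comp$R, 2)
  expect_equal(comp$kappa_E, 0)
  expect_equal(comp$kappa_S, 0)
  expect_equal(comp$beta_ES, 1)
  expect_equal(comp$beta_SE, 1)

  mut <- preset_params("mutualism")
  expect_equal(mut$R, 1)
  expect_equal(mut$kappa_E, 1)
  expect_equal(mut$kappa_S, 1)
  expect_equal(mut$beta_ES, 0)
  expect_equal(mut$beta_SE, 0)
  expect_equal(mut$delta_G, 0.03)

  for (p in list(comp, mut)) {
    expect_equal(p$mu_E, 0.5)
    expect_equal(p$mu_S, 0.5)
    expect_equal(p$alpha_ES, 1)
    expect_equal(unname(unlist(p[c("gamma_EG", "gamma_SG", "gamma_SP",
                                   "gamma_EP")])), rep(20, 4))
    expect_equal(unname(unlist(p[c("sigma_EG", "sigma_SG", "sigma_SP",
                                   "sigma_EP")])), rep(0.001, 4))
    expect_equal(unname(unlist(p[c("delta_E", "delta_S", "delta_G",
                                   "delta_P")])), rep(0.03, 4))
  }
})

test_that("parameter validation rejects negative and missing fields", {
  expect_error(community_params(mu_E = -0.1), "non-negative")
  expect_error(community_params(R = NA_real_), "finite")
  bad <- unclass(preset_params("mutualism"))
  bad$R <- NULL
  expect_error(phagetrade:::validate_params(bad), "missing")
})

test_that("rhs vanishes at the origin for arbitrary parameters", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params(sample(c("competition", "mutualism"), 1))
    expect_equal(unname(community_rhs(c(E = 0, S = 0, G = 0, P = 0), p)),
                 rep(0, 4))
  }
})

test_that("rhs matches hand evaluation at competition defaults", {
  # E = S = 1, no phage: 0.5 * 1 * (2 - 1 - 1) - 0.03 = -0.03 per species
  d <- community_rhs(community_state(1, 1, 0, 0),
                     preset_params("competition"))
  expect_equal(d[["E"]], -0.03)
  expect_equal(d[["S"]], -0.03)
  expect_equal(d[["G"]], 0)
  expect_equal(d[["P"]], 0)
})

test_that("symmetric phage-free mutualism equilibrium is a root of rhs", {
  x <- mutualism_prey_roots()[1]  # (0.94 + sqrt(0.6436)) / 2
  expect_equal(x, 0.8711, tolerance = 1e-4)
  d <- community_rhs(community_state(x, x, 0, 0), preset_params("mutualism"))
  expect_lt(max(abs(d)), 1e-9)
})

test_that("kappa = 0 recovers plain Lotka-Volterra competition growth", {
  set.seed(7)
  p <- preset_params("competition")
  for (i in 1:20) {
    st <- community_state(runif(1, 0, 3), runif(1, 0, 3),
                          runif(1, 0, 50), runif(1, 0, 50))
    d <- community_rhs(st, p)
    lv_E <- p$mu_E * st[["E"]] * (p$R - st[["E"]] - p$beta_ES * st[["S"]]) -
      p$sigma_EG * st[["G"]] * st[["E"]] - p$delta_E * st[["E"]]
    expect_equal(d[["E"]], lv_E)
  }
  # including the 0/0 point where the partner is absent
  d0 <- community_rhs(community_state(1, 0, 0, 0), p)
  expect_equal(d0[["E"]], 0.5 * (2 - 1) - 0.03)
})

test_that("rhs preserves prey symmetry for swap-invariant parameters", {
  set.seed(23)
  for (i in 1:25) {
    p <- random_symmetric_params(sample(c("competition", "mutualism"), 1))
    x <- runif(1, 0, 2)
    g <- runif(1, 0, 100)
    d <- community_rhs(community_state(x, x, g, 0), p)
    expect_identical(d[["E"]], d[["S"]])
  }
})

test_that("rhs rejects negative states", {
  expect_error(community_rhs(c(E = -0.1, S = 1, G = 0, P = 0),
                             preset_params("mutualism")), "negative")
})

test_that("apply_cost rescales the intended field only", {
  comp <- preset_params("competition")
  b5 <- apply_cost(comp, "burst", 5)
  expect_equal(b5$gamma_SP, 100)
  expect_equal(b5$gamma_SG, 20)
  expect_equal(b5$gamma_EG, 20)
  expect_equal(comp$gamma_SP, 20)  # input unmodified

  a3 <- apply_cost(comp, "attachment", 3)
  expect_equal(a3$sigma_SP, 0.003)
  expect_equal(a3$sigma_SG, 0.001)

  m1 <- apply_cost(preset_params("mutualism"), "mortality", 1)
  expect_equal(unname(unlist(m1[c("delta_E", "delta_S", "delta_G",
                                  "delta_P")])), rep(0.0067, 4))
  m4 <- apply_cost(preset_params("mutualism"), "mortality", 4)
  expect_equal(m4$delta_G, 4 * 0.0067)
  expect_equal(m4$delta_P, 0.0067)

  expect_identical(apply_cost(comp, "burst", 1), comp)
  expect_error(apply_cost(comp, "lysis", 2))
  expect_error(apply_cost(comp, "burst", -1))
})

test_that("apply_cost composes idempotently (cost is absolute)", {
  set.seed(5)
  for (kind in c("burst", "attachment", "mortality")) {
    p <- random_params("competition", spread = 3)
    r1 <- runif(1, 0.5, 8); r2 <- runif(1, 0.5, 8)
    expect_equal(apply_cost(apply_cost(p, kind, r1), kind, r2),
                 apply_cost(p, kind, r2))
  }
})

test_that("inert specialist-on-E fields are stored but never used", {
  p <- preset_params("mutualism")
  q <- p; q$gamma_EP <- 1000; q$sigma_EP <- 5
  st <- community_state(0.4, 0.6, 3, 7)
  expect_identical(community_rhs(st, p), community_rhs(st, q))
  expect_identical(community_jacobian(st, p), community_jacobian(st, q))
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(41)
  h <- 1e-6
  for (i in 1:12) {
    p <- random_params(sample(c("competition", "mutualism"), 1), spread = 3)
    x <- c(E = runif(1, 0.01, 2), S = runif(1, 0.01, 2),
           G = runif(1, 0, 60), P = runif(1, 0, 60))
    J <- community_jacobian(x, p)
    Jfd <- matrix(0, 4, 4)
    for (j in 1:4) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      Jfd[, j] <- (phagetrade:::rhs_raw(xp, p) -
                     phagetrade:::rhs_raw(xm, p)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)), 1e-5)
  }
})

test_that("parameter records round-trip through YAML and JSON configs", {
  p <- apply_cost(preset_params("competition"), "burst", 2.5)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_equal(read_params(f), p)
  }
  expect_error(write_params(p, withr::local_tempfile(fileext = ".toml")),
               "dialect")
})
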