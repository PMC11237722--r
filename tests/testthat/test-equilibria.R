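test_that("phage-free fixed points match the closed-form solutions", {
  # competition: single-prey 1.94, symmetric pair on the line E + S = 1.94
  fps <- enumerate_fixed_points(preset_params("competition"))
  tab <- fixed_point_table(fps)
  expect_true(any(abs(tab$E - 1.94) < 1e-6 & tab$S == 0 & tab$G == 0 &
                    tab$P == 0))
  expect_true(any(abs(tab$E - 0.97) < 1e-6 & abs(tab$S - 0.97) < 1e-6 &
                    tab$G == 0 & tab$P == 0))
  expect_true(all(tab$residual < 1e-9))
  expect_true(any(tab$E == 0 & tab$S == 0 & tab$G == 0 & tab$P == 0))

  # mutualism: both roots of x^2 - 0.94x + 0.06 = 0, plus the origin
  fps <- enumerate_fixed_points(preset_params("mutualism"))
  tab <- fixed_point_table(fps)
  roots <- mutualism_prey_roots()
  for (x in roots)
    expect_true(any(abs(tab$E - x) < 1e-6 & abs(tab$S - x) < 1e-6 &
                      tab$G == 0 & tab$P == 0))
  # no single-prey state under obligate mutualism
  expect_false(any(tab$E > 0 & tab$S == 0))
})

test_that("stability classification reflects the Jacobian spectrum", {
  mut <- preset_params("mutualism")
  fps <- enumerate_fixed_points(mut)
  tab <- fixed_point_table(fps)
  # the origin is stable under obligate mutualism: growth shuts off, -delta remains
  expect_equal(tab$stability[tab$E == 0 & tab$S == 0 & tab$G == 0 &
                               tab$P == 0], "stable")
  # the low-density prey root is an unstable (Allee-type) point
  x_lo <- mutualism_prey_roots()[2]
  expect_equal(tab$stability[abs(tab$E - x_lo) < 1e-6 & tab$G == 0 &
                               tab$P == 0], "unstable")
  # the phage-free competition pair is invadable by the generalist
  comp_tab <- fixed_point_table(enumerate_fixed_points(
    preset_params("competition")))
  expect_equal(comp_tab$stability[abs(comp_tab$E - 0.97) < 1e-6 &
                                    abs(comp_tab$S - 0.97) < 1e-6],
               "unstable")
  # prey + generalist equilibria form a neutral line: marginal, never stable
  esg <- comp_tab[comp_tab$G > 0 & comp_tab$P == 0, ]
  expect_gt(nrow(esg), 0)
  expect_true(all(esg$stability == "marginal"))
  expect_true(all(abs(esg$max_re_eig) < 1e-7))
  # within the prey-only block the competition pair is attracting
  J <- community_jacobian(c(E = 0.97, S = 0.97, G = 0, P = 0),
                          preset_params("competition"))
  ev2 <- eigen(J[1:2, 1:2], only.values = TRUE)$values
  expect_true(all(Re(ev2) < 0) || any(abs(Re(ev2)) < 1e-7))
  # and the phage-free mutualism pair is attracting in its prey block
  x_hi <- mutualism_prey_roots()[1]
  Jm <- community_jacobian(c(E = x_hi, S = x_hi, G = 0, P = 0), mut)
  expect_true(all(Re(eigen(Jm[1:2, 1:2], only.values = TRUE)$values) < 0))
  # classification refuses points that are not actually roots
  bogus <- structure(list(state = c(E = 0.5, S = 0.5, G = 1, P = 1),
                          presence = c(E = TRUE, S = TRUE, G = TRUE,
                                       P = TRUE),
                          eigenvalues = NULL, stability = NA, residual = 1),
                     class = "fixed_point")
  expect_error(classify_stability(bogus, mut), "residual")
})

test_that("stable points attract and unstable points repel nearby trajectories", {
  set.seed(59)
  for (mode in c("competition", "mutualism")) {
    p <- apply_cost(preset_params(mode), "burst", 3)
    fps <- enumerate_fixed_points(p)
    n_stable <- 0; n_unstable <- 0
    for (fp in fps) {
      re_max <- max(Re(fp$eigenvalues))
      if (fp$stability == "stable" && n_stable < 4) {
        n_stable <- n_stable + 1
        pert <- pmax(fp$state + runif(4, -1e-3, 1e-3) *
                       ifelse(fp$state > 0, 1, 0), 0)
        ss <- run_to_steady_state(p, pert, t_max = 5e4)
        expect_lt(max(abs(ss$final_state - fp$state)), 1e-4)
      } else if (fp$stability == "unstable" && re_max > 1e-3 &&
                 n_unstable < 4) {
        n_unstable <- n_unstable + 1
        pert <- fp$state + 1e-3  # push into every direction, incl. invaders
        ss <- run_to_steady_state(p, pert, t_max = 5e4)
        expect_gt(max(abs(ss$final_state - fp$state)), 1e-2)
      }
    }
  }
})

test_that("S* report reproduces the closed forms and the cost requirement", {
  mut <- preset_params("mutualism")
  # defaults: both products 0.02, delta 0.03, E = 0.5
  rep <- sstar_criterion(mut, E_level = 0.5)
  expect_equal(rep$S_P_star, 1.5)
  expect_equal(rep$S_G_star, 1.0)
  expect_false(rep$inequality_holds)
  # equal products can never favor the specialist, whatever E
  for (E in c(0, 0.2, 1, 5))
    expect_false(sstar_criterion(mut, E)$inequality_holds)
  # E = 0 reduces to a pure product comparison
  adv <- apply_cost(mut, "burst", 1.5)
  expect_true(sstar_criterion(adv, 0)$inequality_holds)
  expect_false(sstar_criterion(apply_cost(mut, "burst", 0.9),
                               0)$inequality_holds)
})

test_that("S* criterion is invariant under gamma <-> sigma rescaling", {
  set.seed(13)
  for (i in 1:20) {
    p <- preset_params("mutualism")
    p$gamma_SP <- runif(1, 10, 60)
    p$sigma_SP <- runif(1, 5e-4, 5e-3)
    E <- runif(1, 0, 1.5)
    base <- sstar_criterion(p, E)
    c_ <- runif(1, 0.2, 5)
    q <- p
    q$gamma_EG <- p$gamma_EG * c_; q$gamma_SG <- p$gamma_SG * c_
    q$gamma_SP <- p$gamma_SP * c_; q$gamma_EP <- p$gamma_EP * c_
    q$sigma_EG <- p$sigma_EG / c_; q$sigma_SG <- p$sigma_SG / c_
    q$sigma_SP <- p$sigma_SP / c_; q$sigma_EP <- p$sigma_EP / c_
    resc <- sstar_criterion(q, E)
    expect_equal(resc$inequality_holds, base$inequality_holds)
    expect_equal(resc$S_P_star, base$S_P_star)
  }
})

test_that("S* criterion rejects asymmetric generalists and mixed deltas", {
  p <- preset_params("mutualism")
  p$gamma_EG <- 25
  expect_error(sstar_criterion(p, 0.5), "equal burst")
  q <- preset_params("mutualism")
  q$delta_P <- 0.05
  expect_error(sstar_criterion(q, 0.5), "common death")
})

test_that("cost thresholds: burst and attachment agree on the product scale", {
  th_burst <- find_cost_threshold("mutualism", "burst", "only_stable_is_ESP",
                                  bracket = c(1.5, 4))
  th_att <- find_cost_threshold("mutualism", "attachment",
                                "only_stable_is_ESP", bracket = c(1.5, 4))
  expect_equal(th_burst, th_att, tolerance = 5e-3)
  # and the simulated dominance crossing sits below the stability threshold
  th_cross <- find_cost_threshold("mutualism", "burst", "density_crossing",
                                  bracket = c(1.5, 4), t_max = 2e4)
  expect_lt(th_cross, th_burst)
})

test_that("threshold search errors when the indicator never flips", {
  # competition never favors the specialist in forward simulation
  expect_error(
    find_cost_threshold("competition", "burst", "density_crossing",
                        bracket = c(1, 50), t_max = 1e4),
    "constant")
})

test_that("generalist exclusion is monotone in the cost ratio", {
  th <- 2.3  # measured stability threshold at mutualism defaults
  grid <- seq(1.2, 6, length.out = 20)
  flags <- vapply(grid, function(r) {
    phagetrade:::only_stable_is_esp(
      enumerate_fixed_points(apply_cost(preset_params("mutualism"),
                                        "burst", r)))
  }, logical(1))
  expect_true(all(flags[grid > th + 0.05]))
  expect_false(any(flags[grid < th - 0.05]))
  first_true <- which(flags)[1]
  expect_true(all(flags[first_true:length(flags)]))
})
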