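test_that("Nernst potentials match the closed form", {
  expect_equal(nernst(-1, 10, 10), 0)
  expect_equal(nernst(-1, 13.5, 133.5, 31), -60.05, tolerance = 1e-3)
  expect_equal(nernst(-1, 14.1, 24, 31), -13.94, tolerance = 1e-3)
  # direct closed-form cross-check at 1e-12
  rtf <- 8.314 * (31 + 273.15) / 96485 * 1e3
  expect_equal(nernst(-1, 25, 133.5, 31), -rtf * log(133.5 / 25),
               tolerance = 1e-12)
  expect_error(nernst(-1, 0, 133.5), "positive")
  expect_error(nernst(-1, 5, -1), "positive")
})

test_that("combined GABA reversal is the conductance-weighted mean", {
  expect_equal(e_gaba(-70, -14, p = 0), -70)
  expect_equal(e_gaba(-60.1, -13.9, 0.18), (-60.1 + 0.18 * -13.9) / 1.18,
               tolerance = 1e-12)
  expect_equal(e_gaba(-60.1, -13.9, 0.18), -53.05, tolerance = 1e-2)
  expect_equal(e_gaba(-42, -42, 0.7), -42)
})

test_that("flux-to-concentration conversion", {
  expect_equal(apply_flux(0, 1, 1), 0)
  # 1 pA for 1 ms into 1 um3
  expect_equal(apply_flux(1e-3, 1, 1), 1e-3 * 1 / (96485 * 1) * 1e6,
               tolerance = 1e-12)
  expect_equal(apply_flux(1e-3, 1, 1), 1.0364e-2, tolerance = 1e-4)
  expect_equal(apply_flux(1e-3, 2, 1), apply_flux(1e-3, 1, 1) / 2)
  expect_error(apply_flux(1, 0, 1), "positive")
})

test_that("shell geometry partitions the node cylinder", {
  m <- build_ball_and_stick(n_dendrite_nodes = 5)
  st <- ion_state(m, 5)
  nd <- st$nodes
  vol_cyl <- pi * (nd$diam / 2)^2 * nd$dx
  expect_equal(rowSums(st$geom$vol), vol_cyl, tolerance = 1e-12)
  expect_equal(rowSums(st$geom$cross), pi * (nd$diam / 2)^2, tolerance = 1e-12)
  expect_true(all(st$geom$iface > 0))
})

test_that("radial step conserves moles and preserves uniform profiles", {
  m <- build_ball_and_stick(n_dendrite_nodes = 3)
  st <- ion_state(m, 8)
  st2 <- radial_step(st, 0.025)
  expect_equal(st2$cl, st$cl, tolerance = 1e-12)
  # perturbed outer shell: node moles conserved per step
  st$cl[2, 5] <- 20
  m0 <- sum(st$cl[2, ] * st$geom$vol[2, ])
  st3 <- st
  for (i in 1:50) st3 <- radial_step(st3, 0.025)
  expect_equal(sum(st3$cl[2, ] * st3$geom$vol[2, ]), m0, tolerance = 1e-9)
  # relaxes toward uniformity
  expect_lt(diff(range(st3$cl[2, ])), diff(range(st$cl[2, ])))
})

test_that("slowest radial decay rate matches the dense eigenvalue oracle", {
  m <- build_ball_and_stick(n_dendrite_nodes = 1, dendrite_length = 2,
                            dendrite_diameter = 4)
  st <- ion_state(m, 10)
  i <- 2  # the dendritic node
  vol <- st$geom$vol[i, ]; ifa <- st$geom$iface[i, ]; dr <- st$geom$dr[i]
  d_cl <- st$diffusion$d_cl
  # dense exchange operator: dC/dt = V^-1 L C
  L <- matrix(0, 5, 5)
  for (k in 1:4) {
    g <- d_cl * ifa[k] / dr
    L[k, k] <- L[k, k] - g; L[k, k + 1] <- L[k, k + 1] + g
    L[k + 1, k + 1] <- L[k + 1, k + 1] - g; L[k + 1, k] <- L[k + 1, k] + g
  }
  A <- diag(1 / vol) %*% L
  ev <- sort(Re(eigen(A)$values))
  lambda_slow <- -ev[4]  # slowest nonzero decay rate, 1/ms
  # measure the decay rate of the deviation from equilibrium via the
  # implicit update at small dt
  st$cl[i, ] <- 10 + c(0, 0, 0, 0, 1)
  dt <- 1e-3
  for (k in 1:2000) st <- radial_step(st, dt)
  mean_conc <- sum(st$cl[i, ] * vol) / sum(vol)
  a1 <- st$cl[i, ] - mean_conc
  st <- radial_step(st, dt)
  a2 <- st$cl[i, ] - mean_conc
  rate <- -log(max(abs(a2)) / max(abs(a1))) / dt
  expect_equal(rate, lambda_slow, tolerance = 0.01)
})

test_that("longitudinal step: uniform invariance, conservation, 2Dt variance", {
  cab <- morphology(data.frame(name = "dend", length = 100, diam = 1,
                               nseg = 51, parent = NA, attach = 0))
  st <- ion_state(cab, 5)
  st2 <- longitudinal_step(st, 0.05)
  expect_equal(st2$cl, st$cl, tolerance = 1e-12)
  # point bolus mid-cable
  mid <- 26
  st$cl[mid, ] <- st$cl[mid, ] + 100
  tot0 <- chloridyn:::total_moles(st)["cl"]
  x <- st$nodes$path_um
  dt <- 0.05; nstep <- 40  # 2 ms total, spread ~ 2.8 um << cable length
  s <- st
  for (k in seq_len(nstep)) s <- longitudinal_step(s, dt)
  expect_equal(chloridyn:::total_moles(s)[["cl"]], tot0[[1]], tolerance = 1e-9)
  w <- rowSums(s$cl * s$geom$vol) - 5 * rowSums(s$geom$vol)  # excess moles
  w <- pmax(w, 0); w <- w / sum(w)
  mu <- sum(w * x)
  varx <- sum(w * (x - mu)^2)
  expect_equal(varx, 2 * 2 * (nstep * dt), tolerance = 0.05)
})

test_that("relaxation transport: rest invariance, rate, bimodal branch", {
  m <- build_ball_and_stick(n_dendrite_nodes = 2)
  st <- ion_state(m, 10)
  st2 <- relaxation_step(st, 1)
  expect_equal(st2$cl, st$cl, tolerance = 1e-12)
  # above rest: passive efflux branch, instantaneous rate (10-30)/321 mM/s
  st$cl[, ] <- 30
  dt <- 0.1
  st3 <- relaxation_step(st, dt)
  rate_per_s <- (st3$cl[1, 5] - 30) / dt * 1e3
  expect_equal(rate_per_s, (10 - 30) / 321, tolerance = 1e-3)
  # below rest: NKCC1-like uptake branch (tau = 174 s)
  st$cl[, ] <- 5
  st4 <- relaxation_step(st, dt)
  rate_up <- (st4$cl[1, 5] - 5) / dt * 1e3
  expect_equal(rate_up, (10 - 5) / 174, tolerance = 1e-3)
  # exact exponential update
  st$cl[, ] <- 30
  st5 <- relaxation_step(st, 5000)
  expect_equal(st5$cl[1, 1], 10 + 20 * exp(-5000 / 321e3), tolerance = 1e-12)
})
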