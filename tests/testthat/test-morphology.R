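test_that("ball-and-stick construction matches the stated geometry", {
  m <- build_ball_and_stick(20, 200, 1, 103)
  expect_s3_class(m, "morphology")
  expect_equal(nrow(m$sections), 2)
  expect_equal(m$sections$nseg[m$sections$name == "dend"], 103)
  expect_equal(m$sections$length[m$sections$name == "dend"], 200)
  # soma is an isopotential cylinder with length = diameter (sphere area)
  soma <- m$sections[m$sections$name == "soma", ]
  expect_equal(soma$length, soma$diam)
  expect_equal(sum(m$sections$nseg), nrow(chloridyn:::morph_nodes(m)))

  long <- build_ball_and_stick(20, 1000, 1, 103)
  expect_equal(long$sections$length[2], 1000)
  expect_equal(long$sections$nseg[2], 103)

  expect_error(build_ball_and_stick(20, 200, 0, 103), "positive")
  expect_error(build_ball_and_stick(20, 200, 1, 0), "n_dendrite_nodes")
})

test_that("node discretization places centers at (i-0.5)/n and links parents", {
  m <- build_ball_and_stick(20, 200, 1, 4)
  nd <- chloridyn:::morph_nodes(m)
  expect_equal(nd$x[nd$section == "dend"], (1:4 - 0.5) / 4)
  expect_equal(nd$parent[2], 1L)           # first dendrite node -> soma
  expect_equal(nd$parent[3:5], 2:4)
  # probe maps to the nearest node center
  expect_equal(chloridyn:::probe_node(nd, "dend", 0), 2L)
  expect_equal(chloridyn:::probe_node(nd, "dend", 1), 5L)
})

test_that("CA3-like surrogate has the stated section/segment counts", {
  m <- build_ca3_like()
  s <- m$sections
  expect_equal(nrow(s), 58)  # soma + trunk + 56 dendrites
  expect_true(all(s$nseg[s$name != "soma"] == 9))
  expect_equal(sum(grepl("^dend", s$name)), 56)
  expect_true(all(s$parent[grepl("^dend", s$name)] == "trunk"))
  expect_error(build_ca3_like(n_dendrites = 0), ">= 1")
})

test_that("morphology validation rejects broken trees", {
  secs <- data.frame(name = c("a", "b"), length = c(10, 10), diam = c(1, 1),
                     nseg = c(1, 1), parent = c(NA, "zzz"), attach = c(0, 1))
  expect_error(morphology(secs), "unknown parent")
  secs$parent <- c(NA, "b")  # self-parenting (forward reference)
  expect_error(morphology(secs), "precede")
  secs$parent <- c(NA, "a"); secs$length <- c(-1, 10)
  expect_error(morphology(secs), "positive")
})

test_that("isopotential input resistance matches the closed form", {
  soma <- morphology(data.frame(name = "soma", length = 20, diam = 20,
                                nseg = 1, parent = NA, attach = 0,
                                role = "soma"))
  # R = 1/(g * pi d^2) for the sphere-area convention
  expect_equal(input_resistance(soma, 1e-3), 1 / (1e-3 * pi * 400e-8) / 1e6,
               tolerance = 1e-10)
  # linearity: doubling g halves R
  expect_equal(input_resistance(soma, 2e-3), input_resistance(soma, 1e-3) / 2)
  expect_error(input_resistance(soma, 0), "positive")
})

test_that("sealed-cable input resistance matches R_inf coth(l/lambda)", {
  cab <- morphology(data.frame(name = "dend", length = 200, diam = 1,
                               nseg = 400, parent = NA, attach = 0))
  rm_ohm_cm2 <- 1e3  # 1 kOhm cm2 = 1/g_pas at 1 mS/cm2
  lam <- sqrt(rm_ohm_cm2 * 1e-4 / (4 * 34.5))          # cm
  rinf <- sqrt(rm_ohm_cm2 * 34.5) / (pi / 2 * (1e-4)^1.5) / 1e6  # MOhm
  expected <- rinf / tanh(200e-4 / lam)
  expect_equal(input_resistance(cab, 1e-3), expected, tolerance = 0.01)
})

test_that("steady-state voltage on a uniform cable decays as exp(-x/lambda)", {
  cab <- morphology(data.frame(name = "dend", length = 2000, diam = 1,
                               nseg = 800, parent = NA, attach = 0))
  sol <- steady_voltage(cab, 1e-3, inj_node = 1L, inj_nA = 0.1)
  lam_um <- sqrt((1e3 * 1) / (4 * 34.5)) * 1e2  # lambda in um for d = 1 um
  x <- sol$nodes$path_um
  pick <- vapply(c(100, 200, 300, 400, 500), function(d) which.min(abs(x - d)), 1L)
  att <- sol$v[pick] / sol$v[1]
  expected <- exp(-(x[pick] - x[1]) / lam_um)
  expect_equal(att, expected, tolerance = 0.01)
})

test_that("dendrite length calibration by bisection hits achievable targets", {
  target <- 50
  L <- calibrate_dendrite_length(target_rin = target, bounds = c(5, 500))
  r <- input_resistance(build_ca3_like(dendrite_length = L))
  expect_equal(r, target, tolerance = 1e-3)
  # monotone decrease of R_in with dendrite length
  r_short <- input_resistance(build_ca3_like(dendrite_length = 20))
  r_long <- input_resistance(build_ca3_like(dendrite_length = 300))
  expect_gt(r_short, r_long)
  # unreachable target (soma caps the whole-cell R_in) warns
  expect_warning(calibrate_dendrite_length(target_rin = 188.2,
                                           bounds = c(5, 500)),
                 "achievable range")
})

test_that("SWC parsing: chains, diameters, soma handling, errors", {
  # 3 collinear points, two 50 um edges, radius 0.5 -> one section,
  # length 100 um, diameter 1 um
  swc <- c("1 3 0 0 0 0.5 -1", "2 3 50 0 0 0.5 1", "3 3 100 0 0 0.5 2")
  m <- read_swc(swc)
  expect_equal(nrow(m$sections), 1)
  expect_equal(m$sections$length, 100)
  expect_equal(m$sections$diam, 1)

  # orphan (forward) parent reference is a parse error with line number
  expect_error(read_swc(c("1 1 0 0 0 5 -1", "2 3 0 0 0 1 9")), "line 2")
  expect_error(read_swc("1 1 0 0 0 5"), "malformed")

  # soma-only file -> single isopotential section
  m2 <- read_swc("1 1 0 0 0 7.5 -1")
  expect_equal(nrow(m2$sections), 1)
  expect_equal(m2$sections$role, "soma")
  expect_equal(m2$sections$diam, 15)
  expect_equal(m2$sections$length, m2$sections$diam)

  # branched: soma + two daughters from one neurite
  swc3 <- c("1 1 0 0 0 5 -1", "2 3 5 0 0 0.5 1", "3 3 55 0 0 0.5 2",
            "4 3 105 0 0 0.5 3", "5 3 55 50 0 0.4 3")
  m3 <- read_swc(swc3)
  expect_equal(nrow(m3$sections), 4)  # soma + parent chain + 2 daughters
  expect_setequal(m3$sections$role, c("soma", "dend"))
})
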