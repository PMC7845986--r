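test_that("synapse placement rules respect counts and regions", {
  m <- build_ca3_like()
  loc <- place_synapses(m, 534, seed = 1)
  expect_equal(nrow(loc), 534)
  expect_true(all(grepl("^dend|^trunk", loc$section)))
  expect_true(all(loc$x >= 0 & loc$x <= 1))

  co <- place_synapses(m, 107, "colocalized", seed = 2, with = loc)
  expect_equal(nrow(co), 107)
  key <- paste(loc$section, loc$x)
  expect_true(all(paste(co$section, co$x) %in% key))

  dist <- place_synapses(m, 100, "distal25", seed = 3)
  expect_true(all(dist$x >= 0.75))
  prox <- place_synapses(m, 100, "proximal25", seed = 3)
  expect_true(all(prox$x <= 0.25))

  expect_error(place_synapses(m, 10, sections = "no_such"), "zero dendritic")
})

test_that("GDP schedules have one event per synapse, inside the window", {
  m <- build_ca3_like()
  sp <- gdp_spec()
  g <- gdp_schedule(sp, m, seed = 7)
  expect_equal(nrow(g$gaba), 534)
  expect_equal(nrow(g$ampa), 107)
  expect_equal(nrow(g$schedule), 534 + 107)
  expect_equal(sum(grepl("^gdp_gaba", g$schedule$synapse)), 534)
  expect_true(all(g$schedule$time >= 0 & g$schedule$time <= sp$window))
  # determinism
  g2 <- gdp_schedule(sp, m, seed = 7)
  expect_identical(g$schedule, g2$schedule)
  expect_identical(g$gaba, g2$gaba)
  g3 <- gdp_schedule(sp, m, seed = 8)
  expect_false(identical(g$schedule$time, g3$schedule$time))
})

test_that("truncated-normal GDP timing matches its parameters at n = 10000", {
  set.seed(42)
  t_comp <- chloridyn:::rnorm_trunc(10000, 600, 90, 0, 1300)
  expect_equal(mean(t_comp), 600, tolerance = 0.01)
  expect_equal(sd(t_comp), 90, tolerance = 0.05)
  # wide (printed) sigma with truncation: near-uniform over the window
  t_wide <- chloridyn:::rnorm_trunc(10000, 600, 9000, 0, 1300)
  expect_equal(mean(t_wide), 650, tolerance = 0.05)
  expect_equal(sd(t_wide), 1300 / sqrt(12), tolerance = 0.05)
})

test_that("Poisson train statistics and correlation modes", {
  # per-synapse mode: 100 synapses x 20 Hz x 1 s = 2000 expected events
  sp2 <- train_spec(rate = 20, duration = 1000, rate_mode = "per_synapse")
  sch2 <- train_schedule(sp2, seed = 1)
  n2 <- sum(grepl("^tr_gaba", sch2$synapse))
  expect_lt(abs(n2 - 2000) / 2000, 0.1)   # ~4.5 SD of Poisson(2000)
  # population mode (default): 20 Hz aggregate -> ~20 events, averaged
  # over seeds to beat Poisson noise
  counts <- vapply(1:40, function(sd) {
    sch <- train_schedule(train_spec(rate = 20, duration = 1000), seed = sd)
    sum(grepl("^tr_gaba", sch$synapse))
  }, 1)
  expect_lt(abs(mean(counts) - 20) / 20, 0.2)
  sch <- train_schedule(train_spec(), seed = 1)
  expect_true(all(sch$time >= 0 & sch$time <= 1000))

  corr <- train_schedule(train_spec(mode = "correlated"), seed = 2)
  tg <- sort(corr$time[grepl("^tr_gaba", corr$synapse)])
  ta <- sort(corr$time[grepl("^tr_ampa", corr$synapse)])
  expect_identical(tg, ta)

  empty <- train_schedule(train_spec(duration = 0), seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("decorrelation enforces the pairwise refractory distance", {
  set.seed(5)
  gaba <- runif(20, 0, 1000)
  ampa <- runif(20, 0, 1000)
  for (r in c(5, 11, 37)) {
    out <- decorrelate(ampa, gaba, refractory = r, window = 1000)
    expect_equal(length(out), length(ampa))
    # exhaustive brute-force pairwise check
    dmin <- min(abs(outer(out, gaba, "-")))
    expect_gt(dmin, r)
  }
  # refractory 0 returns input unchanged
  expect_identical(decorrelate(ampa, gaba, 0, 1000), ampa)
  # infeasible: dense GABA grid leaves no room
  dense <- seq(0, 100, by = 1)
  expect_error(decorrelate(c(50), dense, refractory = 20, window = 100),
               "infeasible")
})

test_that("refractory trains have empty central correlogram bins", {
  sch <- train_schedule(train_spec(mode = "refractory", refractory = 11),
                        seed = 3)
  ta <- sch$time[grepl("^tr_ampa", sch$synapse)]
  tg <- sch$time[grepl("^tr_gaba", sch$synapse)]
  cc <- crosscorrelogram(ta, tg, bin = 1, window = 50)
  expect_true(all(cc$count[abs(cc$lag) <= 10.5] == 0))
  expect_gt(sum(cc$count[abs(cc$lag) > 11.5]), 0)
})

test_that("latency scans produce one schedule per latency", {
  ls <- latency_scan(500, seq(-49, 100, by = 1))
  expect_equal(length(ls), 150)
  s0 <- ls[["0"]]
  expect_equal(s0$time[s0$synapse == "ampa"], s0$time[s0$synapse == "gaba"])
  sm <- ls[["-49"]]
  expect_equal(sm$time[sm$synapse == "ampa"], 451)
})

test_that("schedules are pure functions of (spec, seed) and round-trip CSV", {
  a <- train_schedule(train_spec(), seed = 11)
  b <- train_schedule(train_spec(), seed = 11)
  expect_identical(a, b)
  f <- tempfile(fileext = ".csv")
  write_schedule(a, f)
  back <- read_schedule(f)
  expect_equal(back$synapse, a$synapse)
  expect_equal(back$time, a$time, tolerance = 1e-12)
  unlink(f)
})
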