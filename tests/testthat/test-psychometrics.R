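# Trial scheduling, simulated observers, cumulative-Gaussian fitting and the
# bias-corrected illusion velocity.

test_that("velocityGrid builds the inclusive rounded grid", {
  g <- velocityGrid()
  expect_length(g, 15L)
  expect_equal(g[1], -2.1)
  expect_equal(g[15], 2.1)
  expect_equal(unique(round(diff(g), 10)), 0.3)
  expect_equal(velocityGrid(0, 0, 0.3), 0)
  expect_equal(velocityGrid(-0.3, 0.3, 0.3), c(-0.3, 0, 0.3))
})

test_that("makeSchedule balances conditions and permutes reproducibly", {
  sch <- makeSchedule(reps = 30L, seed = 5L)
  expect_identical(nrow(sch), 900L)
  counts <- table(sch$stimulus_type, sch$velocity_deg_per_s)
  expect_true(all(counts == 30L))
  expect_identical(makeSchedule(reps = 30L, seed = 5L), sch)

  one <- makeSchedule(velocities = 0, types = "original", reps = 1L)
  expect_identical(nrow(one), 1L)

  sch2 <- makeSchedule(reps = 30L, seed = 6L)
  expect_false(identical(sch2$velocity_deg_per_s, sch$velocity_deg_per_s))
  key <- function(s) sort(paste(s$stimulus_type, s$velocity_deg_per_s, s$rep_index))
  expect_identical(key(sch2), key(sch))          # same multiset of trials
})

test_that("simulateObserver honours the psychometric model in its limits", {
  sch <- makeSchedule(reps = 30L, seed = 1L)
  # near-zero sigma: a step function at mu
  resp <- simulateObserver(0.45, 1e-6, sch, seed = 2L)
  tab <- responseTable(resp)
  expect_true(all(tab$n_ccw[tab$velocity_deg_per_s > 0.45] == tab$n_presented[tab$velocity_deg_per_s > 0.45]))
  expect_true(all(tab$n_ccw[tab$velocity_deg_per_s < 0.45] == 0))

  # mu 0 on the symmetric grid: overall CCW fraction near 1/2
  resp0 <- simulateObserver(0, 0.4, sch, seed = 3L)
  expect_equal(mean(resp0$response == "CCW"), 0.5, tolerance = 0.05)

  # full lapse: guessing at every velocity
  respL <- simulateObserver(0.4, 0.4, sch, seed = 4L, lapse = 1)
  tabL <- responseTable(respL)
  expect_true(all(abs(tabL$n_ccw / tabL$n_presented - 0.5) < 0.31))
  expect_equal(mean(respL$response == "CCW"), 0.5, tolerance = 0.06)
})

test_that("fitPsychometric recovers parameters from noise-free proportions", {
  v <- velocityGrid()
  mkTab <- function(mu, sigma, n = 30) {
    data.frame(velocity_deg_per_s = v, n_presented = n,
               n_ccw = n * pnorm((v - mu) / sigma))
  }
  f <- fitPsychometric(mkTab(0.5, 0.3))
  expect_lt(abs(f@mu - 0.5), 1e-3)
  expect_lt(abs(f@sigma - 0.3), 1e-3)
  expect_equal(f@cancellationVelocity, f@mu)

  f0 <- fitPsychometric(mkTab(0, 0.5))
  expect_lt(abs(f0@mu), 1e-3)

  # equivariance: velocity shift moves mu; velocity scaling scales mu, sigma
  tab <- mkTab(0.4, 0.4)
  shifted <- transform(tab, velocity_deg_per_s = velocity_deg_per_s + 0.9)
  fs <- fitPsychometric(shifted)
  expect_lt(abs(fs@mu - 1.3), 1e-3)
  scaled <- transform(tab, velocity_deg_per_s = velocity_deg_per_s * 2)
  fk <- fitPsychometric(scaled)
  expect_lt(abs(fk@mu - 0.8), 1e-3)
  expect_lt(abs(fk@sigma - 0.8), 1e-3)
})

test_that("degenerate response tables are rejected with guidance", {
  v <- velocityGrid()
  allCW <- data.frame(velocity_deg_per_s = v, n_presented = 30, n_ccw = 0)
  expect_error(fitPsychometric(allCW), "not identifiable")
  allCCW <- data.frame(velocity_deg_per_s = v, n_presented = 30, n_ccw = 30)
  expect_error(fitPsychometric(allCCW), "not identifiable")
  few <- data.frame(velocity_deg_per_s = c(-1, 1), n_presented = 30,
                    n_ccw = c(3, 27))
  expect_error(fitPsychometric(few), "3 distinct velocities")
})

test_that("maximum-likelihood fitting agrees with least squares on clean data", {
  v <- velocityGrid()
  tab <- data.frame(velocity_deg_per_s = v, n_presented = 30,
                    n_ccw = round(30 * pnorm((v - 0.3) / 0.5)))
  fl <- fitPsychometric(tab, method = "ls")
  fm <- fitPsychometric(tab, method = "ml")
  expect_lt(abs(fl@mu - fm@mu), 0.05)
  expect_lt(abs(fl@sigma - fm@sigma), 0.1)
})

test_that("illusionVelocity combines cancellation velocities per the nulling rule", {
  v <- velocityGrid()
  mkFit <- function(mu) fitPsychometric(data.frame(
    velocity_deg_per_s = v, n_presented = 30,
    n_ccw = 30 * pnorm((v - mu) / 0.4)))
  same <- illusionVelocity(mkFit(0.2), mkFit(0.2))
  expect_equal(same@combined, 0, tolerance = 1e-6)

  iv <- illusionVelocity(mkFit(-0.3), mkFit(0.3))
  expect_equal(iv@combined, 0.3, tolerance = 1e-3)

  swapped <- illusionVelocity(mkFit(0.3), mkFit(-0.3))
  expect_equal(swapped@combined, -iv@combined, tolerance = 1e-6)
})

test_that("an observer with opposite shifts for mirrored designs is recovered end-to-end", {
  sch <- makeSchedule(reps = 30L, seed = 11L)
  delta <- 0.25
  resp <- simulateObserver(c(original = -delta, reversed = delta), 0.4, sch,
                           seed = 12L)
  tab <- responseTable(resp)
  iv <- illusionVelocity(
    fitPsychometric(tab[tab$stimulus_type == "original", ]),
    fitPsychometric(tab[tab$stimulus_type == "reversed", ]))
  expect_lt(abs(iv@combined - delta), 0.1)
})
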