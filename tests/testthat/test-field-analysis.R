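test_that("the Coulomb field matches closed-form benchmarks", {
  ## unit charge at 1 A: 14.3996 V/A = 1439.96 MV/cm, pointing away
  co <- rbind(c(0, 0, 0), c(1, 0, 0))
  E <- fieldAtPoint(co, c(1, 0), point = c(1, 0, 0), exclude = 2)
  expect_equal(sqrt(sum(E^2)), 1439.96, tolerance = 1e-12)
  expect_gt(E[1], 0)

  ## two equal charges symmetric about the point cancel
  co2 <- rbind(c(-2, 0, 0), c(2, 0, 0))
  expect_equal(fieldAtPoint(co2, c(0.7, 0.7), c(0, 0, 0)), c(0, 0, 0),
               tolerance = 1e-12)

  ## far field of a point dipole: 2 ke q d / r^3 on axis, within 1%
  q <- 0.5; dsep <- 0.5; r <- 20
  co3 <- rbind(c(dsep / 2, 0, 0), c(-dsep / 2, 0, 0))
  E3 <- fieldAtPoint(co3, c(q, -q), c(r, 0, 0))
  expect_equal(E3[1], 2 * 1439.96 * q * dsep / r^3, tolerance = 0.01)

  expect_error(fieldAtPoint(co, c(1, 0), point = c(0, 0, 0)), "singularity")
})

test_that("the bond-projected field follows the sign convention and hand arithmetic", {
  ## +0.5 e on the C->N axis, 3 A beyond N: -80.0 at N, -41.6 at C
  co <- rbind(c(0, 0, 0), c(1.16, 0, 0), c(1.16 + 3, 0, 0))
  f <- projectedField(co, c(0.2, -0.2, 0.5), probe = c(1, 2))
  atN <- -1439.96 * 0.5 / 9
  atC <- -1439.96 * 0.5 / 4.16^2
  expect_equal(f, (atN + atC) / 2, tolerance = 1e-9)
  expect_lt(f, 0)
  ## no environment charges -> zero
  expect_equal(projectedField(co[1:2, ], c(0.2, -0.2), probe = c(1, 2)), 0)
  ## midpoint evaluation as alternative convention
  fm <- projectedField(co, c(0, 0, 0.5), probe = c(1, 2),
                       evaluate = "midpoint")
  expect_equal(fm, -1439.96 * 0.5 / (3 + 0.58)^2, tolerance = 1e-9)
})

test_that("fields superpose and obey the inverse-square scaling", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    co <- matrix(rnorm(3 * n, sd = 4), n, 3)
    co <- co[sqrt(rowSums(co^2)) > 1, , drop = FALSE]
    q <- runif(nrow(co), -1, 1)
    total <- fieldAtPoint(co, q, c(0, 0, 0))
    parts <- Reduce(`+`, lapply(seq_len(nrow(co)), function(j)
      fieldAtPoint(co[j, , drop = FALSE], q[j], c(0, 0, 0))))
    expect_lt(max(abs(total - parts)), 1e-9)
    s <- 1.7
    expect_equal(fieldAtPoint(co * s, q, c(0, 0, 0)), total / s^2,
                 tolerance = 1e-12)
  }
})

test_that("the vectorised Coulomb engine equals the naive loop oracle on random frames", {
  set.seed(7)
  maxDev <- 0
  for (i in 1:100) {
    n <- sample(8:30, 1)
    co <- matrix(rnorm(3 * n, sd = 6), n, 3)
    co[1, ] <- c(0, 0, 0)
    co[2, ] <- c(1.16, 0, 0)
    keep <- c(TRUE, TRUE, sqrt(rowSums(co[-(1:2), , drop = FALSE]^2)) > 2)
    co <- co[keep, , drop = FALSE]
    q <- runif(nrow(co), -1, 1)
    got <- projectedField(co, q, probe = c(1, 2))
    want <- naiveProjected(co, q, probe = c(1, 2))
    maxDev <- max(maxDev, abs(got - want))
  }
  expect_lt(maxDev, 1e-8)
})

test_that("hydrogen-bond classification applies inclusive cutoffs", {
  mkFrame <- function(dist, angDeg) {
    rD <- c(1.16 + dist, 0, 0)
    ## hydrogen 1 A from D, rotated angDeg away from the D->N direction
    toN <- c(1.16, 0, 0) - rD
    toN <- toN / sqrt(sum(toN^2))
    a <- angDeg * pi / 180
    rH <- rD + cos(a) * toN + sin(a) * c(0, 1, 0)
    rbind(c(0, 0, 0), c(1.16, 0, 0), rD, rH)
  }
  donors <- data.frame(d = 3, h = 4, element = "O")
  cls <- function(dist, ang)
    classifyHbond(mkFrame(dist, ang), 2, donors)$bonded
  expect_true(cls(2.9, 10))
  expect_false(cls(4.01, 0))
  expect_true(cls(4.0, 0))       # distance boundary inclusive
  expect_true(cls(3.0, 29.99))   # just inside the angular cutoff
  expect_false(cls(3.0, 30.5))
  expect_error(classifyHbond(mkFrame(2.9, 0), 2,
                             data.frame(d = 3, h = NA)),
               "hydrogen")

  ## exhaustive grid against the independently coded checker (grid points
  ## chosen off the exact cutoffs, where both codes would share the same
  ## floating-point boundary sensitivity)
  for (dist in seq(2.51, 4.51, by = 0.25))
    for (ang in seq(0.5, 60.5, by = 5)) {
      fr <- mkFrame(dist, ang)
      want <- naiveHbond(fr[2, ], fr[3, ], fr[4, ], 4.0, 30)
      expect_identical(cls(dist, ang), want)
    }

  ## monotonicity: enlarging either cutoff never unlabels a bonded frame
  set.seed(13)
  for (i in 1:50) {
    fr <- mkFrame(runif(1, 2.5, 4.5), runif(1, 0, 60))
    base <- classifyHbond(fr, 2, donors, hbondCriteria(4.0, 30))$bonded
    bigger <- classifyHbond(fr, 2, donors, hbondCriteria(4.5, 40))$bonded
    if (base) expect_true(bigger)
  }
})

test_that("trajectory analysis recovers the generator's two-state ground truth", {
  m <- trajectoryModel(occupancy = 0.7,
                       stateMeans_MVcm = c(bonded = -75, free = -30),
                       nFrames = 2500, nReplicates = 4)
  tr <- generateTrajectory(m, seed = 1)
  out <- analyzeTrajectory(tr)
  s <- out$summary

  expect_equal(s@populations[["bonded"]], 0.7, tolerance = 0.015)
  expect_lt(abs(s@stateMeans[["bonded"]] + 75), 1)
  expect_lt(abs(s@stateMeans[["free"]] + 30), 1)
  ## classifier labels match the generator's hidden states
  expect_gt(mean((out$records$hbond) ==
                 (tr@stateLabels == "bonded")), 0.999)
  ## overall mean equals the population-weighted state means
  w <- sum(s@populations * s@stateMeans[names(s@populations)])
  expect_equal(w, s@overallMean, tolerance = 1e-9)
  expect_length(s@replicateMeans, 4)
})

test_that("a single-frame trajectory summarises to that frame's record", {
  m <- trajectoryModel(occupancy = 1, nFrames = 1, nReplicates = 1,
                       jitterSD_A = 0)
  tr <- generateTrajectory(m, seed = 2)
  out <- analyzeTrajectory(tr)
  expect_identical(nrow(out$records), 1L)
  expect_equal(out$summary@overallMean, out$records$field_MVcm[1])
  expect_equal(out$summary@aggregateMean, out$records$field_MVcm[1])
})

test_that("state-resolved recovery holds across occupancies", {
  for (p in c(0.1, 0.5, 0.9)) {
    m <- trajectoryModel(occupancy = p, nFrames = 2000, nReplicates = 1)
    tr <- generateTrajectory(m, seed = round(1000 * p))
    s <- analyzeTrajectory(tr)$summary
    expect_lt(abs(s@populations[["bonded"]] - p), 0.03)
    expect_lt(abs(s@stateMeans[["bonded"]] -
                  m@stateMeans_MVcm[["bonded"]]), 2)
  }
})

test_that("the apo preset is less hydrogen-bonded than the holo preset", {
  sApo <- analyzeTrajectory(generateTrajectory(
    trajectoryPreset("apo_F92", nFrames = 800, nReplicates = 2),
    seed = 3))$summary
  sHolo <- analyzeTrajectory(generateTrajectory(
    trajectoryPreset("holo_F92", nFrames = 800, nReplicates = 2),
    seed = 4))$summary
  expect_lt(sApo@populations[["bonded"]], sHolo@populations[["bonded"]])
  expect_gt(sApo@overallMean, sHolo@overallMean)   # less negative field
})
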