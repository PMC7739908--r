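test_that("generators are deterministic under a fixed seed", {
  flow <- straightFlow()
  spec <- marginationSpec(nRbc = 500, nPlt = 100, seed = 9)
  s1 <- synthCellSnapshots(spec, flow, T = 0.05, dtSnap = 5e-3)
  s2 <- synthCellSnapshots(spec, flow, T = 0.05, dtSnap = 5e-3)
  expect_identical(s1@data, s2@data)

  es <- experimentSpec(seed = 9, tOcclusion = 10, duration = 15)
  expect_identical(synthMassTrace(es)@mass, synthMassTrace(es)@mass)
  i1 <- synthImageStack(es)
  i2 <- synthImageStack(es)
  expect_identical(i1$stack@frames, i2$stack@frames)
})

test_that("every snapshot conserves the cell census", {
  flow <- straightFlow()
  spec <- marginationSpec(nRbc = 800, nPlt = 150, seed = 13)
  s <- synthCellSnapshots(spec, flow, T = 0.05, dtSnap = 5e-3)
  per <- table(s@data$t)
  expect_true(all(per == 950))
  perType <- table(s@data$t, s@data$type)
  expect_true(all(perType[, "RBC"] == 800))
  expect_true(all(perType[, "PLT"] == 150))
})

test_that("structureless spec yields a uniform platelet distribution", {
  flow <- straightFlow()
  spec <- marginationSpec(cflWidth = 0, enhancement = 1, sliver = 0,
                          nRbc = 0, nPlt = 4000, seed = 0)
  s <- synthCellSnapshots(spec, flow, T = 0.015, dtSnap = 5e-3)
  y <- s@data$y[s@data$t == 0.005]
  h <- table(cut(y, seq(0, 130e-6, length.out = 14)))
  p <- chisq.test(h)$p.value
  expect_gt(p, 0.01)
})

test_that("wall-band enrichment converges to the prescribed factor", {
  flow <- straightFlow()
  spec <- marginationSpec(enhancement = 2, nRbc = 0, nPlt = 1e4,
                          sliver = 0, seed = 19)
  s <- synthCellSnapshots(spec, flow, T = 0.015, dtSnap = 5e-3)
  y <- s@data$y[s@data$t == 0.005]
  H <- 130e-6
  dWall <- pmin(y, H - y)
  band <- mean(dWall < 5e-6) / (10e-6 / H)         # density in the band
  core <- mean(dWall > 10e-6 & dWall < 60e-6) / (100e-6 / H)
  expect_equal(band / core, 2, tolerance = 0.05)
})

test_that("infeasible cell counts are rejected", {
  flow <- straightFlow()
  expect_stenoError(
    synthCellSnapshots(marginationSpec(nRbc = 5e7, nPlt = 0), flow,
                       T = 0.05, dtSnap = 5e-3),
    "stenoflowSpecError")
  expect_stenoError(
    synthCellSnapshots(marginationSpec(nRbc = 10, nPlt = 10), flow,
                       T = 0.004, dtSnap = 5e-3),
    "stenoflowSpecError")
})

test_that("mass traces encode the programmed flow and occlusion", {
  spec <- experimentSpec(balanceNoise = 0, evapRate = 0, tOcclusion = 40,
                         duration = 60, seed = 3)
  tr <- synthMassTrace(spec)
  # exactly piecewise linear: slope rho*Q, then flat
  expect_equal(diff(tr@mass[1:40]), rep(1025 * 2.4e-9, 39))
  expect_equal(diff(tr@mass[42:61]), rep(0, 19))
  expect_equal(occlusionTime(tr)$time, 40)

  # the reference trace carries evaporation only
  spec2 <- experimentSpec(balanceNoise = 0, tOcclusion = 40, duration = 60,
                          seed = 3)
  tr2 <- synthMassTrace(spec2)
  expect_equal(diff(tr2@refMass), rep(spec2@evapRate, 60))
})

test_that("smooth ramp-down plateaus at the reduced total volume", {
  spec <- experimentSpec(balanceNoise = 0, evapRate = 0, tOcclusion = 40,
                         duration = 60, rampDuration = 5, seed = 3)
  tr <- synthMassTrace(spec)
  expect_equal(max(tr@mass), 1025 * 2.4e-9 * (40 - 5 / 2))
  expect_equal(tr@mass[61], max(tr@mass))
  # monotone non-decreasing throughout
  expect_true(all(diff(tr@mass) > -1e-18))
})

test_that("image stacks embed the clot and the exact corner pixels", {
  spec <- experimentSpec(tOcclusion = 10, duration = 15, imageNoise = 0,
                         clotCenter = 100e-6, seed = 21)
  si <- synthImageStack(spec)
  expect_equal(si$corners@chamber, "vanRooij")
  # the corner separation equals the throat length in pixels
  sep <- (si$corners@xMarks[["throat_end"]] -
          si$corners@xMarks[["throat_start"]]) * spec@pixelSize
  expect_equal(sep, throatLength(spec@geometry), tolerance = 0.02)
  # amplitude grows monotonically up to the occlusion frame
  n <- dim(si$stack@frames)[3L]
  amps <- vapply(seq_len(n), function(k) max(si$stack@frames[, , k]),
                 numeric(1))
  kOcc <- which.min(abs(si$stack@timestamps - 10))
  expect_true(all(diff(amps[1:kOcc]) >= -1e-12))

  # a zero-amplitude clot leaves a degenerate profile
  spec0 <- experimentSpec(tOcclusion = 10, duration = 15, imageNoise = 0,
                          clotAmplitude = 0, seed = 21)
  si0 <- synthImageStack(spec0)
  prof0 <- intensityProfile(si0$stack, n, si0$corners)
  expect_true(prof0@degenerate)
})

test_that("out-of-view clot centres are rejected", {
  expect_stenoError(experimentSpec(clotCenter = 500e-6),
                    "stenoflowSpecError")
  expect_stenoError(experimentSpec(tOcclusion = 200, duration = 100),
                    "stenoflowSpecError")
})
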