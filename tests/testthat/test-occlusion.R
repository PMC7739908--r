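test_that("evaporation correction is exact on linear traces", {
  tt <- 0:100
  # zero-slope reference leaves the trace untouched
  tr <- massTrace(tt, 1e-3 * tt, refTime = tt, refMass = rep(0.05, 101))
  expect_equal(correctEvaporation(tr)@mass, tr@mass)

  # reference slope -r, trace slope q - r  ->  corrected slope q
  q <- 2.46e-6; r <- 2e-8
  tr2 <- massTrace(tt, (q - r) * tt, refTime = tt, refMass = 0.05 - r * tt)
  corr <- correctEvaporation(tr2)
  expect_equal(diff(corr@mass), rep(q, 100))

  # disjoint supports cannot be aligned
  tr3 <- massTrace(tt, q * tt, refTime = tt + 500, refMass = rep(0.05, 101))
  expect_stenoError(correctEvaporation(tr3), "stenoflowAlignmentError")
})

test_that("flow rate is the mass slope over density", {
  tt <- 0:60
  tr <- massTrace(tt, 2.46e-6 * tt, rho = 1025)
  expect_equal(flowRate(tr, c(0, 60)), 2.46e-6 / 1025)
  expect_equal(flowRate(tr, c(0, 60)) * 1e9, 2.4, tolerance = 1e-6)
  expect_stenoError(flowRate(tr, c(0, 3)), "stenoflowWindowError")
})

test_that("programmed flow rate survives evaporation and noise within 1%", {
  spec <- experimentSpec(seed = 42)
  tr <- synthMassTrace(spec)
  corr <- correctEvaporation(tr)
  q <- flowRate(corr, window = c(5, 55))
  expect_equal(q, 2.4e-9, tolerance = 0.01)

  # evaporation-only trace: corrected flow indistinguishable from zero
  spec0 <- experimentSpec(Q = 1e-18, seed = 43)
  tr0 <- correctEvaporation(synthMassTrace(spec0))
  expect_lt(abs(flowRate(tr0, c(5, 55))), 3 * 1e-6 / 1025 / 50)
})

test_that("occlusion time follows the plateau rules", {
  # strictly unimodal: exact argmax
  tt <- 0:200
  m <- -(tt - 120)^2
  occ <- occlusionTime(massTrace(tt, m * 1e-9 + 1), epsilon = 1e-10)
  expect_equal(occ$time, 120)
  expect_length(occ$flags, 0L)

  # interior plateau 100..104 s at the maximum: centre 102 s
  m2 <- c(1e-6 * (0:99), rep(1e-4, 5), 1e-4 - 1e-6 * (1:96))
  occ2 <- occlusionTime(massTrace(tt, m2), epsilon = 1e-8)
  expect_equal(occ2$time, 102)

  # still rising at the last sample: right-censored
  occ3 <- occlusionTime(massTrace(tt, 2.46e-6 * tt), epsilon = 2e-6)
  expect_true("right_censored" %in% occ3$flags)
})

test_that("programmed occlusion time is detected within one sample", {
  # noise-free, evaporation-free: exactly piecewise linear, t* exact
  spec <- experimentSpec(balanceNoise = 0, evapRate = 0, tOcclusion = 60,
                         seed = 2)
  occ <- occlusionTime(synthMassTrace(spec))
  expect_equal(occ$time, 60)

  # with noise and evaporation, after correction: within one sample
  spec2 <- experimentSpec(tOcclusion = 60, seed = 4)
  corr <- correctEvaporation(synthMassTrace(spec2))
  occ2 <- occlusionTime(corr)
  expect_lte(abs(occ2$time - 60), 1 / spec2@balanceRate)
})

test_that("intensity profiles locate synthetic clots to the pixel", {
  spec <- experimentSpec(tOcclusion = 20, duration = 30, clotCenter = 85e-6,
                         seed = 8)
  si <- synthImageStack(spec)
  prof <- intensityProfile(si$stack, dim(si$stack@frames)[3L], si$corners)
  expect_false(prof@degenerate)
  d <- occlusionDistance(prof)
  expect_lte(abs(as.numeric(d) - 85e-6), spec@pixelSize)
})

test_that("degenerate flat frames are flagged and refuse a distance", {
  frames <- array(0.5, dim = c(50, 80, 2))
  st <- imageStack(frames, c(0.5, 1), 2e-6, "WB")
  corners <- cornerAnnotation(
    data.frame(x = c(30, 30, 60, 60), z = c(10, 40, 10, 40)))
  prof <- intensityProfile(st, 1L, corners)
  expect_true(prof@degenerate)
  expect_true(all(prof@intensity == 0))
  expect_stenoError(occlusionDistance(prof),
                    "stenoflowDegenerateProfileError")
})

test_that("inversion makes PRP and WB renderings of one clot agree", {
  mk <- function(modality) {
    spec <- experimentSpec(tOcclusion = 10, duration = 15,
                           clotCenter = 120e-6, imageNoise = 0,
                           modality = modality, seed = 5)
    synthImageStack(spec)
  }
  wb <- mk("WB"); prp <- mk("PRP")
  n <- dim(wb$stack@frames)[3L]
  pw <- intensityProfile(wb$stack, n, wb$corners)
  pp <- intensityProfile(prp$stack, n, prp$corners)
  expect_equal(pp@x, pw@x)
  expect_lt(max(abs(pp@intensity - pw@intensity)), 1e-6)
  expect_equal(as.numeric(occlusionDistance(pp)),
               as.numeric(occlusionDistance(pw)))
  # both invert orders expose the same peak
  pp2 <- intensityProfile(prp$stack, n, prp$corners, invertOrder = "after")
  expect_equal(as.numeric(occlusionDistance(pp2)),
               as.numeric(occlusionDistance(pp)))
})

test_that("ties resolve to the most upstream maximum and are flagged", {
  I <- rep(0.2, 100); I[c(40, 70)] <- 1
  prof <- new("IntensityProfile", x = (seq_len(100) - 20) * 2e-6,
              intensity = I, modality = "WB", inverted = FALSE,
              degenerate = FALSE)
  d <- occlusionDistance(prof)
  expect_equal(as.numeric(d), (40 - 20) * 2e-6)
  expect_true(attr(d, "tie"))
})

test_that("a brighter downstream blob never moves the peak upstream", {
  nz <- 60; nx <- 200
  corners <- cornerAnnotation(
    data.frame(x = c(50, 50, 120, 120), z = c(10, 50, 10, 50)))
  blob <- function(cx, amp) {
    gx <- amp * exp(-(seq_len(nx) - cx)^2 / (2 * 8^2))
    0.4 + matrix(rep(gx, each = nz), nz, nx)
  }
  base <- blob(80, 0.3)
  st1 <- imageStack(array(base, c(nz, nx, 1)), 1, 2e-6, "WB")
  d1 <- as.numeric(occlusionDistance(intensityProfile(st1, 1, corners)))
  for (cx2 in c(100, 140, 180)) {
    f2 <- base + blob(cx2, 0.5) - 0.4
    st2 <- imageStack(array(f2, c(nz, nx, 1)), 1, 2e-6, "WB")
    d2 <- as.numeric(occlusionDistance(intensityProfile(st2, 1, corners)))
    expect_gte(d2, d1)
  }
})

test_that("profile aggregation averages on the common grid", {
  spec <- experimentSpec(tOcclusion = 10, duration = 15, imageNoise = 0,
                         clotCenter = 80e-6, seed = 6)
  si <- synthImageStack(spec)
  n <- dim(si$stack@frames)[3L]
  p1 <- intensityProfile(si$stack, n, si$corners)
  agg1 <- aggregateProfiles(list(p1))
  expect_equal(agg1$mean, p1@intensity[p1@x >= min(agg1$x) &
                                       p1@x <= max(agg1$x)])
  agg2 <- aggregateProfiles(list(p1, p1))
  expect_equal(agg2$mean, agg1$mean)

  spec2 <- experimentSpec(tOcclusion = 10, duration = 15, imageNoise = 0,
                          clotCenter = 90e-6, seed = 6)
  si2 <- synthImageStack(spec2)
  p2 <- intensityProfile(si2$stack, n, si2$corners)
  agg <- aggregateProfiles(list(p1, p2))
  peak <- agg$x[which.max(agg$mean)]
  expect_gte(peak, 80e-6)
  expect_lte(peak, 90e-6)
})

test_that("the full pipeline localizes clots at the pixel level", {
  for (modality in c("WB", "PRP")) {
    for (x0 in c(0, 50e-6, 150e-6, 285e-6)) {
      spec <- experimentSpec(tOcclusion = 20, duration = 30,
                             clotCenter = x0, modality = modality,
                             seed = 100 + round(x0 * 1e6))
      si <- synthImageStack(spec)
      tr <- synthMassTrace(spec)
      res <- analyzeOcclusion(si$stack, tr, si$corners)
      expect_lte(abs(res@time - 20), 1)
      expect_lte(abs(res@distance - x0), spec@pixelSize)
    }
  }
})
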