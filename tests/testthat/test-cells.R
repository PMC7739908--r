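# snapshot series built by hand: 60 snapshots every 5 ms
snapTimes <- seq(0.005, 0.300, by = 0.005)

test_that("flux map applies the presence-count definition literally", {
  # one stationary platelet: 60 presences over 0.30 s -> 200 / s in its bin
  d <- data.frame(t = snapTimes, id = 1L, type = "PLT",
                  x = 101e-6, y = 51e-6, z = 25e-6)
  s <- makeSeries(d)
  m <- fluxMap(s, "PLT", bins = 2e-6, window = c(0, 0.300))
  expect_equal(sum(mapValues(m) > 0), 1L)
  expect_equal(max(mapValues(m)), 60 / 0.300)

  # no platelets at all -> all-zero map
  dR <- transform(d, type = "RBC")
  m0 <- fluxMap(makeSeries(dR), "PLT", bins = 2e-6, window = c(0, 0.300))
  expect_true(all(mapValues(m0) == 0))
})

test_that("flux conservation: bin sum times window equals total presences", {
  set.seed(7)
  n <- 400
  d <- do.call(rbind, lapply(snapTimes, function(tt)
    data.frame(t = tt, id = seq_len(n), type = "PLT",
               x = runif(n, 0, 572e-6), y = runif(n, 0, 130e-6),
               z = runif(n, 0, 50e-6))))
  s <- makeSeries(d)
  m <- fluxMap(s, "PLT", bins = 4e-6, window = c(0, 0.300))
  expect_equal(sum(mapValues(m)) * 0.300, n * length(snapTimes))
})

test_that("homogeneous Poisson flux matches the closed-form rate", {
  set.seed(11)
  lambda <- 3                       # expected platelets per bin per snapshot
  bins <- 10e-6
  Lx <- 570e-6; H <- 130e-6
  nbx <- Lx / bins; nby <- H / bins
  nPer <- lambda * nbx * nby
  d <- do.call(rbind, lapply(snapTimes, function(tt) {
    n <- rpois(1, nPer)
    data.frame(t = tt, id = seq_len(n), type = "PLT",
               x = runif(n, 0, Lx), y = runif(n, 0, H),
               z = runif(n, 0, 50e-6))
  }))
  s <- cellSnapshotSeries(d, bounds = c(xmin = 0, xmax = Lx, ymin = 0,
                                        ymax = H, zmin = 0, zmax = 50e-6))
  m <- fluxMap(s, "PLT", bins = bins, window = c(0, 0.300))
  expected <- lambda * length(snapTimes) / 0.300
  sdBin <- sqrt(lambda * length(snapTimes)) / 0.300   # Poisson error
  frac3sigma <- mean(abs(mapValues(m) - expected) <= 3 * sdBin)
  expect_gt(frac3sigma, 0.99)
  expect_equal(mean(mapValues(m)), expected, tolerance = 0.02)
})

test_that("empty or single-snapshot windows raise a window error", {
  d <- data.frame(t = snapTimes, id = 1L, type = "PLT",
                  x = 101e-6, y = 51e-6, z = 25e-6)
  s <- makeSeries(d)
  expect_stenoError(fluxMap(s, "PLT", window = c(0.9, 1.0)),
                    "stenoflowWindowError")
})

test_that("residence time is the diameter-translocation time", {
  # constant speed 0.01 m/s: residence = 2 um / 0.01 = 200 us
  v <- 0.01
  d <- data.frame(t = snapTimes, id = 1L, type = "PLT",
                  x = (10e-6 + v * snapTimes) %% 572e-6,
                  y = 51e-6, z = 25e-6)
  s <- makeSeries(d)
  m <- residenceTimeMap(s, bins = 2e-6, window = c(0, 0.300))
  vals <- mapValues(m)
  expect_equal(mean(vals[!is.na(vals)]), 2e-6 / v, tolerance = 1e-9)

  # stationary platelet: censored at the window length, bin left undefined
  d2 <- data.frame(t = snapTimes, id = 1L, type = "PLT",
                   x = 101e-6, y = 51e-6, z = 25e-6)
  m2 <- residenceTimeMap(makeSeries(d2), bins = 2e-6, window = c(0, 0.300))
  expect_true(all(is.na(mapValues(m2))))
  expect_equal(sum(m2@extra$censored), length(snapTimes))
  expect_equal(m2@extra$censoredTime, 0.300)
})

test_that("x-periodic trajectories are unwrapped by minimum image", {
  # fast platelet crossing the periodic seam each step
  Lx <- 572e-6
  v <- 0.05                          # 250 um per 5 ms step
  d <- data.frame(t = snapTimes, id = 1L, type = "PLT",
                  x = (500e-6 + v * snapTimes) %% Lx,
                  y = 51e-6, z = 25e-6)
  m <- residenceTimeMap(makeSeries(d), bins = 2e-6, window = c(0, 0.300))
  vals <- mapValues(m)
  expect_equal(mean(vals[!is.na(vals)]), 2e-6 / v, tolerance = 1e-6)
})

test_that("advected platelets recover the local velocity profile", {
  flow <- straightFlow()
  spec <- marginationSpec(cflWidth = 0, enhancement = 1, sliver = 0,
                          nRbc = 0, nPlt = 400, jitterSigma = 1e-12,
                          seed = 3)
  s <- synthCellSnapshots(spec, flow, T = 0.1, dtSnap = 5e-3)
  m <- residenceTimeMap(s, bins = 10e-6, window = c(0, 0.1))
  yc <- binCentersY(m)
  H <- 130e-6
  Q2D <- 2.4e-9 / 480e-6
  vals <- mapValues(m)
  # compare mid-channel bins, whose platelets are fast enough to
  # translocate within a step
  for (j in which(yc > 20e-6 & yc < 110e-6)) {
    got <- vals[, j]
    got <- got[!is.na(got)]
    if (!length(got)) next
    u <- 6 * Q2D / H^3 * yc[j] * (H - yc[j])
    expect_equal(mean(got), 2e-6 / u, tolerance = 0.05)
  }
})

test_that("duplicate trajectory records raise a trajectory error", {
  d <- data.frame(t = rep(snapTimes[1:2], each = 2), id = 1L, type = "PLT",
                  x = 1e-6, y = 1e-6, z = 1e-6)
  expect_stenoError(residenceTimeMap(makeSeries(d)),
                    "stenoflowTrajectoryError")
})

test_that("volume fraction recovers a known uniform density", {
  set.seed(5)
  Lx <- 572e-6; H <- 130e-6; Wz <- 50e-6
  n <- 8000
  d <- do.call(rbind, lapply(snapTimes[1:20], function(tt)
    data.frame(t = tt, id = seq_len(n), type = "RBC",
               x = runif(n, 0, Lx), y = runif(n, 0, H),
               z = runif(n, 0, Wz))))
  s <- makeSeries(d)
  # 13 um bins tile the 572 x 130 um domain exactly
  m <- rbcVolumeFraction(s, bins = 13e-6, window = c(0, 0.1))
  phiExp <- n * 90e-18 / (Lx * H * Wz)
  expect_equal(mean(mapValues(m)), phiExp, tolerance = 0.02)

  # no red cells -> zero everywhere; configuration error without V_RBC
  dP <- transform(d[d$t == snapTimes[1] | d$t == snapTimes[2], ], type = "PLT")
  m0 <- rbcVolumeFraction(makeSeries(dP), bins = 10e-6)
  expect_true(all(mapValues(m0) == 0))
  expect_stenoError(
    rbcVolumeFraction(makeSeries(d, cellVolumes = c(PLT = 6e-18))),
    "stenoflowConfigurationError")

  # all red cells in the lower half -> upper-half bins empty
  dL <- d[d$t %in% snapTimes[1:2], ]
  dL$y <- dL$y / 2
  mL <- rbcVolumeFraction(makeSeries(dL), bins = 10e-6)
  upper <- binCentersY(mL) > H / 2 + 1e-9
  expect_true(all(mapValues(mL)[, upper] == 0))
})

test_that("cell-depleted-layer detector handles constructed profiles", {
  mkPhi <- function(vals, bins = 2e-6, H = 130e-6) {
    ny <- H / bins
    v <- matrix(rep(vals, each = 5), nrow = 5)
    new("BinnedFieldMap", xEdges = seq(0, 5 * bins, by = bins),
        yEdges = seq(0, H, by = bins), values = v,
        kind = "volume_fraction", window = c(0, 1), extra = list())
  }
  H <- 130e-6; bins <- 2e-6
  yc <- seq(bins / 2, H - bins / 2, by = bins)
  # step profile: 0 below 5 um, 0.33 beyond (both walls)
  vals <- ifelse(yc < 5e-6 | yc > H - 5e-6, 0, 0.33)
  prof <- cflThickness(mkPhi(vals), "glass")
  expect_true(all(abs(prof@delta - 5e-6) <= bins))
  profTop <- cflThickness(mkPhi(vals), "pdms")
  expect_true(all(abs(profTop@delta - 5e-6) <= bins))

  # empty map: capped at the lumen half-height and flagged
  p0 <- cflThickness(mkPhi(rep(0, length(yc))), "glass")
  expect_true(all(p0@flagged))
  expect_equal(p0@delta, rep(H / 2, 5))

  # uniform haematocrit: layer collapses to under one bin
  pU <- cflThickness(mkPhi(rep(0.33, length(yc))), "glass")
  expect_true(all(pU@delta <= bins))
})

test_that("generator-prescribed depletion widths are recovered", {
  flow <- straightFlow()
  for (dstar in c(3e-6, 5e-6, 8e-6)) {
    spec <- marginationSpec(cflWidth = dstar, nRbc = 6000, nPlt = 200,
                            seed = 17)
    s <- synthCellSnapshots(spec, flow, T = 0.1, dtSnap = 5e-3)
    phi <- rbcVolumeFraction(s, bins = 2e-6, window = c(0, 0.1))
    for (w in c("glass", "pdms")) {
      prof <- cflThickness(phi, w)
      expect_equal(median(prof@delta), dstar, tolerance = 2e-6 / dstar)
    }
  }
})

test_that("wall-band flux ratio recovers the margination factor two", {
  # platelet y-positions persist across snapshots, so the statistical power
  # comes from the platelet count, not the snapshot count: run the recovery
  # at a count where sampling error is well inside the tolerance
  flow <- straightFlow()
  wb <- marginationSpec(enhancement = 2, nRbc = 0, nPlt = 5e4, seed = 23)
  prp <- marginationSpec(enhancement = 1, nRbc = 0, nPlt = 5e4, seed = 29)
  sWb <- synthCellSnapshots(wb, flow, T = 0.05, dtSnap = 5e-3)
  sPrp <- synthCellSnapshots(prp, flow, T = 0.05, dtSnap = 5e-3)
  band <- function(s) {
    m <- fluxMap(s, "PLT", bins = 2.5e-6, window = c(0, 0.05))
    yc <- binCentersY(m)
    H <- 130e-6
    sum(mapValues(m)[, yc < 5e-6 | yc > H - 5e-6])
  }
  ratio <- band(sWb) / band(sPrp)
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("flux ratio is invariant to snapshot frequency", {
  flow <- straightFlow()
  wb <- marginationSpec(enhancement = 2, nRbc = 0, nPlt = 800, seed = 31)
  prp <- marginationSpec(enhancement = 1, nRbc = 0, nPlt = 800, seed = 37)
  band <- function(spec, dt) {
    s <- synthCellSnapshots(spec, flow, T = 0.30, dtSnap = dt)
    m <- fluxMap(s, "PLT", bins = 2.5e-6, window = c(0, 0.30))
    sum(mapValues(m)[, binCentersY(m) < 5e-6])
  }
  r1 <- band(wb, 5e-3) / band(prp, 5e-3)
  r2 <- band(wb, 2.5e-3) / band(prp, 2.5e-3)
  expect_equal(r1, r2, tolerance = 0.10)
})
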