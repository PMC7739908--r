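test_that("plane-Poiseuille limit is recovered within 1 percent", {
  f <- straightFlow()
  g <- straightGeom()
  H <- channelHeight(g); W <- channelWidth(g); Q <- f@Q
  Q2D <- Q / W
  uex <- 6 * Q2D / H^3 * f@y * (H - f@y)
  unum <- f@ux[1L, ]
  expect_lt(sqrt(sum((unum - uex)^2) / sum(uex^2)), 0.01)

  # wall shear against the closed form 6Q/(W H^2)
  sf <- shearFields(f, prpFluid())
  gw <- 6 * Q / (W * H^2)
  expect_equal(abs(sf$gammaDot[1L, 1L]), gw, tolerance = 0.01)

  # offset profile is constant and matches the linear shear profile
  p <- wallProfile(f, prpFluid(), g, "glass", offset = 1e-6)
  pex <- gw * (1 - 2 * 1e-6 / H)
  expect_equal(abs(p@gammaDot), rep(pex, length(p@gammaDot)),
               tolerance = 0.01)
})

test_that("flow rate is matched and conserved at every x-station", {
  f <- vrFlow()
  qx <- achievedFlowRate(f)
  expect_equal(mean(qx), 2.4e-9, tolerance = 0.005)
  expect_lt((max(qx) - min(qx)) / mean(qx), 0.001)

  # continuity through the throat: mean velocity ~ Q/(W hs)
  g <- vrGeom()
  bx <- bumpX(g)
  hs <- throatHeight(g)
  iThroat <- which.min(abs(f@x - (bx[["contraction_end"]] + throatLength(g) / 2)))
  uMean <- sum(f@ux[iThroat, ]) * f@dx / hs
  expect_equal(uMean, 2.4e-9 / (480e-6 * hs), tolerance = 0.02)
})

test_that("zero target flow returns an identically zero field", {
  m <- rasterizeGeometry(straightGeom(), 2e-6)
  f0 <- solveFlow(m, prpFluid(), Q = 0)
  expect_true(all(f0@ux == 0) && all(f0@uy == 0))
  expect_identical(f0@bodyForce, 0)
  expect_true(f0@converged)
})

test_that("uniform translation has zero xy shear", {
  f <- straightFlow()
  fu <- f
  fu@ux <- matrix(0.01, nrow(f@ux), ncol(f@ux))
  fu@uy <- matrix(0, nrow(f@ux), ncol(f@ux))
  fu@omega <- matrix(0, nrow(f@ux), ncol(f@ux))
  fu@nodeType <- matrix(1L, nrow(f@ux), ncol(f@ux))
  sf <- shearFields(fu, prpFluid())
  expect_equal(max(abs(sf$gammaDot)), 0)
})

test_that("Newtonian closure and the WB/PRP stress ratio are exact", {
  f <- straightFlow()
  prp <- prpFluid(); wb <- wholeBloodFluid()
  sPrp <- shearFields(f, prp)
  sWb <- shearFields(f, wb)
  expect_equal(sPrp$tau, dynamicViscosity(prp) * sPrp$gammaDot)
  # equal flow rate: identical shear-rate fields, stresses scale with mu
  expect_equal(sWb$gammaDot, sPrp$gammaDot)
  ratio <- dynamicViscosity(wb) / dynamicViscosity(prp)
  expect_equal(sWb$tau, sPrp$tau * ratio)
  expect_equal(ratio, (1060 * 3.3) / (1025 * 1.1))
})

test_that("stenotic solution is fore-aft symmetric in the Stokes regime", {
  f <- vrFlow()
  g <- vrGeom()
  bx <- bumpX(g)
  xc <- (bx[["contraction_start"]] + bx[["expansion_end"]]) / 2
  d <- seq(0, 250e-6, by = 5e-6)
  worst <- 0
  for (yy in c(10e-6, 20e-6, 32.5e-6, 50e-6, 60e-6)) {
    a <- velocityAt(f, xc + d, rep(yy, length(d)))$ux
    b <- velocityAt(f, xc - d, rep(yy, length(d)))$ux
    worst <- max(worst, max(abs(a - b)) / max(abs(a)))
  }
  expect_lt(worst, 0.02)
})

test_that("throat shear is high and near the parallel-plate estimate", {
  f <- vrFlow()
  g <- vrGeom()
  p <- wallProfile(f, prpFluid(), g, "pdms", offset = 1e-6)
  bx <- bumpX(g)
  xm <- (bx[["contraction_end"]] + bx[["expansion_start"]]) / 2
  gm <- abs(p@gammaDot[which.min(abs(p@x - xm))])
  oracle <- 6 * 2.4e-9 / (480e-6 * throatHeight(g)^2)
  expect_gt(gm, 3000)
  expect_equal(gm, oracle, tolerance = 0.10)
  expect_equal(length(p@x), nrow(wallOffsetSamples(g, "pdms", 1e-6,
                                                   spacing = f@dx)))
})

test_that("glass-wall shear peaks opposite the throat", {
  f <- vrFlow()
  g <- vrGeom()
  p <- wallProfile(f, prpFluid(), g, "glass", offset = 1e-6)
  bx <- bumpX(g)
  xPeak <- p@x[which.max(abs(p@gammaDot))]
  expect_gte(xPeak, bx[["contraction_start"]])
  expect_lte(xPeak, bx[["expansion_end"]])
})

test_that("Reynolds number follows the printed convention", {
  g <- vrGeom()
  re <- reynoldsNumber(2.1e-9, g, prpFluid())
  expect_equal(re, 4, tolerance = 0.05)
  expect_equal(reynoldsNumber(4.2e-9, g, prpFluid()), 2 * re)
  expect_equal(reynoldsNumber(2.1e-9, g, wholeBloodFluid()), 1.33,
               tolerance = 0.01)
})

test_that("solver input errors are classed", {
  m <- rasterizeGeometry(straightGeom(), 2e-6)
  expect_stenoError(solveFlow(m, prpFluid(), Q = -1e-9),
                    "stenoflowValidationError")
  f <- straightFlow()
  fBad <- f
  fBad@converged <- FALSE
  expect_stenoError(shearFields(fBad, prpFluid()), "stenoflowStateError")
})
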