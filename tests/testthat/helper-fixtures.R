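# shared fixtures; heavyweight solves are memoised so the suite pays for
# each of them once

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

vrGeom <- function() vanRooijGeometry()

# canonical stenotic solve used by the flow and acceptance tests
# (0.5 um grid, the working PRP flow rate)
vrFlow <- function() memo("vrFlow", {
  solveFlow(rasterizeGeometry(vrGeom(), 0.5e-6), prpFluid(), Q = 2.4e-9)
})

# near-degenerate stenosis: geometrically a plain rectangular channel
# (the bump is ~1e-13 m tall, far below any cell centre)
straightGeom <- function(H = 130e-6, L = 60e-6, W = 480e-6)
  chamberGeometry(H = H, W = W, s = 1e-9, theta = 80, Ls = L / 10,
                  upstream = L / 3, L = L)

straightFlow <- function(dx = 1e-6, Q = 2.4e-9) memo(
  paste0("straight", dx, "_", Q),
  solveFlow(rasterizeGeometry(straightGeom(), dx), prpFluid(), Q = Q)
)

# hand-built snapshot series on a straight-channel domain
makeSeries <- function(data, H = 130e-6, Lx = 572e-6, W = 50e-6, ...) {
  cellSnapshotSeries(data,
    bounds = c(xmin = 0, xmax = Lx, ymin = 0, ymax = H,
               zmin = 0, zmax = W), ...)
}

expect_stenoError <- function(expr, subclass) {
  expect_error(expr, class = subclass)
}
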