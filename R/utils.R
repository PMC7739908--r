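# internal helpers shared across modules

# classed condition so callers can catch specific failure modes
stopSteno <- function(subclass, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(subclass, "stenoflowError", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  )
  stop(cond)
}

# construct an S4 object, re-classing any validity failure
newValidated <- function(Class, errClass, ...) {
  tryCatch(new(Class, ...), error = function(e)
    stopSteno(errClass, "%s", conditionMessage(e)))
}

assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopSteno("stenoflowValidationError", "'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0)
    stopSteno("stenoflowValidationError", "'%s' must be strictly positive", name)
  invisible(x)
}

# bilinear interpolation on a regular node grid; x may be periodic.
# M is an Nx-by-Ny matrix with M[i, j] the value at (xg[i], yg[j]).
bilinearAt <- function(xq, yq, xg, yg, M, periodicX = FALSE, Lx = NULL) {
  dxg <- xg[2L] - xg[1L]
  dyg <- yg[2L] - yg[1L]
  nx <- length(xg)
  ny <- length(yg)
  ux <- (xq - xg[1L]) / dxg
  uy <- (yq - yg[1L]) / dyg
  if (periodicX) {
    nper <- if (is.null(Lx)) nx else round(Lx / dxg)
    ux <- ux %% nper
    i0 <- floor(ux)
    fx <- ux - i0
    i0 <- (as.integer(i0) %% nper) + 1L
    i1 <- (i0 %% nper) + 1L
  } else {
    ux <- pmin(pmax(ux, 0), nx - 1L)
    i0 <- pmin(floor(ux), nx - 2L)
    fx <- ux - i0
    i0 <- as.integer(i0) + 1L
    i1 <- i0 + 1L
  }
  uy <- pmin(pmax(uy, 0), ny - 1L)
  j0 <- pmin(floor(uy), ny - 2L)
  fy <- uy - j0
  j0 <- as.integer(j0) + 1L
  j1 <- j0 + 1L
  M[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    M[cbind(i1, j0)] * fx * (1 - fy) +
    M[cbind(i0, j1)] * (1 - fx) * fy +
    M[cbind(i1, j1)] * fx * fy
}

# circular shifts along the first (x) dimension of a matrix
shiftXm <- function(M) M[c(nrow(M), seq_len(nrow(M) - 1L)), , drop = FALSE]
shiftXp <- function(M) M[c(seq_len(nrow(M))[-1L], 1L), , drop = FALSE]
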