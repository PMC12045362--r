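#' @include AllClasses.R
NULL

## Joint-state bookkeeping. s = (n-1)*3 + c with per-lobe codes
## 1 apo, 2 Ca-bound, 3 Ca+peptide. Fluorescent = at least one lobe in 3.
.FLUOR_STATES <- c(3L, 6L, 7L, 8L, 9L)
.N_OF_STATE <- rep(1:3, each = 3)
.C_OF_STATE <- rep(1:3, times = 3)

#' Pseudo-first-order calcium on-rate of a lobe
#'
#' The calcium on-rate is tied to the off-rate through the apparent
#' dissociation constant and Hill coefficient:
#' \deqn{k_{on} = k_{off} (ca / K_a)^H}
#' so that at equilibrium the bound fraction follows a Hill curve with
#' midpoint \code{Ka} and exponent \code{hill}, and \code{kon == koffCa}
#' exactly at \code{ca == Ka}.
#'
#' @param lobe a \linkS4class{LobeKinetics}
#' @param ca free calcium concentration (uM), nonnegative
#' @return on-rate (1/s)
#' @export
lobeOnRate <- function(lobe, ca) {
  if (any(ca < 0)) stop("calcium concentration must be nonnegative")
  lobe@koffCa * (ca / lobe@Ka)^lobe@hill
}

## 3x3 generator of one lobe at fixed calcium; columns sum to zero,
## dx/dt = G x with x = (apo, ca, pep).
.lobeGenerator <- function(lobe, ca) {
  kon <- lobeOnRate(lobe, ca)
  matrix(c(-kon,            lobe@koffCa,                      0,
            kon, -(lobe@koffCa + lobe@konPep),     lobe@koffPep,
              0,            lobe@konPep,          -lobe@koffPep),
         nrow = 3, byrow = TRUE)
}

#' Build the 9x9 transition-rate generator at fixed calcium
#'
#' The two lobes transition independently (no cross-lobe rate coupling) but
#' occupancy is tracked jointly, so the joint generator is the Kronecker sum
#' of the two 3-state lobe generators. Columns sum to zero (probability
#' conservation); the only nonzero off-diagonal rates change exactly one
#' lobe's state by one step (apo <-> Ca, Ca <-> Ca+peptide).
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param ca free calcium (uM)
#' @return a 9x9 rate matrix Q such that d(occupancy)/dt = Q occupancy
#' @export
buildGenerator <- function(sensor, ca) {
  if (ca < 0) stop("calcium concentration must be nonnegative")
  gN <- .lobeGenerator(sensor@lobeN, ca)
  gC <- .lobeGenerator(sensor@lobeC, ca)
  ## x indexed c-fastest: Q = gN (+) gC = kron(gN, I) + kron(I, gC)
  kronecker(gN, diag(3)) + kronecker(diag(3), gC)
}

## 3-state birth-death stationary distribution of one lobe (exact).
.lobeStationary <- function(lobe, ca) {
  kon <- lobeOnRate(lobe, ca)
  w <- c(1, kon / lobe@koffCa,
         (kon / lobe@koffCa) * (lobe@konPep / lobe@koffPep))
  w / sum(w)
}

#' Steady-state sensor occupancy at fixed calcium
#'
#' Because the per-lobe chains are birth-death processes with lobe-local
#' rates, the joint stationary distribution factorizes exactly into the
#' product of the per-lobe stationary distributions; no iterative null-space
#' solve is required.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param ca free calcium (uM)
#' @return a \linkS4class{SensorState}
#' @export
steadyState <- function(sensor, ca) {
  if (ca < 0) stop("calcium concentration must be nonnegative")
  piN <- .lobeStationary(sensor@lobeN, ca)
  piC <- .lobeStationary(sensor@lobeC, ca)
  x <- as.numeric(kronecker(piN, piC))
  if (any(!is.finite(x)))
    stop("steady-state solve failed: non-finite occupancy (ca = ", ca, ")")
  SensorState(x)
}

## Fluorescent-class occupancy of a 9-vector or 9 x T matrix.
.phiOf <- function(x) {
  if (is.matrix(x)) colSums(x[.FLUOR_STATES, , drop = FALSE])
  else sum(x[.FLUOR_STATES])
}

## Zero-calcium and saturating fluorescent-class occupancies.
.phiRange <- function(sensor) {
  phi0 <- .phiOf(steadyState(sensor, 0)@occupancy)
  phiSat <- .phiOf(steadyState(sensor, 1e6)@occupancy)
  if (abs(phiSat - phi0) < 1e-12)
    stop("degenerate sensor: saturating and zero-calcium fluorescence equal")
  c(phi0 = phi0, phiSat = phiSat)
}

#' Fluorescence readout of a sensor state
#'
#' All configurations in which at least one lobe is calcium-bound with the
#' peptide bound contribute equally to fluorescence. In \code{stopped_flow}
#' mode the readout is normalized between 0 (zero-calcium steady state) and
#' 1 (saturating steady state). In \code{cell} mode it is scaled to 1 at
#' zero calcium and \code{Rf} at saturation:
#' F = 1 + (Rf - 1) (phi - phi0) / (phiSat - phi0).
#'
#' @param state a \linkS4class{SensorState} (or 9 x T occupancy matrix)
#' @param sensor a \linkS4class{SensorModel}
#' @param mode "cell" or "stopped_flow"
#' @return dimensionless fluorescence (vector if a matrix was given)
#' @export
fluorescence <- function(state, sensor, mode = c("cell", "stopped_flow")) {
  mode <- match.arg(mode)
  x <- if (is(state, "SensorState")) state@occupancy else state
  phi <- .phiOf(x)
  pr <- .phiRange(sensor)
  u <- (phi - pr["phi0"]) / (pr["phiSat"] - pr["phi0"])
  if (mode == "stopped_flow") unname(u)
  else unname(1 + (sensor@Rf - 1) * u)
}

#' Fractional fluorescence change
#'
#' @param fCurrent instantaneous fluorescence
#' @param fBasal steady-state fluorescence at basal calcium (> 0)
#' @return (fCurrent - fBasal) / fBasal
#' @export
dffValue <- function(fCurrent, fBasal) {
  if (any(fBasal <= 0)) stop("basal fluorescence must be > 0")
  (fCurrent - fBasal) / fBasal
}

## Matrix exponential of a small matrix by scaling and squaring with a
## truncated Taylor series; adequate and fast for 3x3 generators.
.expmSmall <- function(A) {
  nrm <- max(colSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^j
  E <- diag(nrow(A))
  term <- E
  for (k in 1:14) {
    term <- As %*% term / k
    E <- E + term
  }
  for (k in seq_len(j)) E <- E %*% E
  E
}

## Per-lobe propagators over one step of length dt at fixed calcium.
.lobePropagators <- function(sensor, ca, dt) {
  list(PN = .expmSmall(.lobeGenerator(sensor@lobeN, ca) * dt),
       PC = .expmSmall(.lobeGenerator(sensor@lobeC, ca) * dt))
}

#' Propagate sensor occupancy along a calcium trajectory
#'
#' Time integration of the master equation under a piecewise-constant
#' calcium trajectory (one value per step of length \code{dt}). Each step
#' applies the exact matrix exponential of the joint generator, computed as
#' the Kronecker product of the two 3x3 lobe propagators, so the scheme is
#' unconditionally stable for arbitrarily stiff rate ratios.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param initial a \linkS4class{SensorState}
#' @param caTrajectory free-calcium value per step (uM, nonnegative)
#' @param dt step length (s)
#' @return a 9 x (length(caTrajectory) + 1) occupancy matrix whose first
#'   column is the initial state
#' @export
propagateSensor <- function(sensor, initial, caTrajectory, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(caTrajectory < 0)) stop("calcium trajectory must be nonnegative")
  n <- length(caTrajectory)
  out <- matrix(NA_real_, 9, n + 1)
  M <- matrix(initial@occupancy, 3, 3)  # M[c, n], c fastest
  out[, 1] <- as.numeric(M)
  same <- n > 0 && all(caTrajectory == caTrajectory[1])
  if (same) P <- .lobePropagators(sensor, caTrajectory[1], dt)
  for (i in seq_len(n)) {
    if (!same) P <- .lobePropagators(sensor, caTrajectory[i], dt)
    M <- P$PC %*% M %*% t(P$PN)
    out[, i + 1] <- as.numeric(M)
  }
  if (any(!is.finite(out)) || any(out < -1e-6))
    stop("sensor integration failure: negative or non-finite occupancy")
  rownames(out) <- names(stateNames(numeric(9)))
  out
}

#' Classify occupancy into kinetic-role state classes
#'
#' Decomposes occupancy into the four classes used to explain use-dependent
#' slowing: \code{fast_fluorescent} (fluorescent without C-lobe peptide
#' engagement), \code{slow_fluorescent} (fluorescent with the C-lobe in the
#' Ca+peptide configuration), \code{slow_nonfluorescent} (non-fluorescent
#' with the C-lobe calcium-loaded), and \code{nonfluorescent_other}.
#' The four classes partition the 9 joint states.
#'
#' @param trajectory a \linkS4class{SensorState} or 9 x T occupancy matrix
#' @return a 4 x T matrix (or named 4-vector) of class occupancies
#' @export
classifyStates <- function(trajectory) {
  x <- if (is(trajectory, "SensorState")) matrix(trajectory@occupancy)
       else trajectory
  cls <- rbind(
    fast_fluorescent    = colSums(x[c(7, 8), , drop = FALSE]),
    slow_fluorescent    = colSums(x[c(3, 6, 9), , drop = FALSE]),
    slow_nonfluorescent = colSums(x[c(2, 5), , drop = FALSE]),
    nonfluorescent_other = colSums(x[c(1, 4), , drop = FALSE]))
  if (ncol(cls) == 1L) cls[, 1] else cls
}
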