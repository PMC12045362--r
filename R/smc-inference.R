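#' @include AllClasses.R sensor-kinetics.R cell-model.R
NULL

#' Construct an inference configuration
#'
#' Defaults are the package's documented desk-scale budget: 64 particles
#' and 40 particle-Gibbs iterations with a 25\% burn-in.
#'
#' @param nParticles number of particles (>= 2)
#' @param nIterations particle-Gibbs iterations
#' @param binDt bin width (s); NA uses the trace's sample interval (spikes
#'   are binary per bin, so at most one spike per bin)
#' @param priors named list of log-normal prior specs, each
#'   \code{list(meanlog, sdlog)}, for aCa, gTotal, pumpVmax, Rf, sigma,
#'   rateHz, driftScale; missing entries get defaults centred on the
#'   supplied cell model
#' @param proposalScales named list of Metropolis log-scale proposal SDs
#' @param seed integer seed
#' @param generativeModel "biophysical" or "linear_ar"
#' @return an \linkS4class{InferenceConfig}
#' @export
inferenceConfig <- function(nParticles = 64, nIterations = 40, binDt = NA,
                            priors = list(), proposalScales = list(),
                            seed = 1,
                            generativeModel = c("biophysical", "linear_ar")) {
  generativeModel <- match.arg(generativeModel)
  new("InferenceConfig", nParticles = as.integer(nParticles),
      nIterations = as.integer(nIterations), binDt = as.numeric(binDt),
      priors = priors, proposalScales = proposalScales,
      seed = as.integer(seed), generativeModel = generativeModel)
}

.thetaNames <- c("aCa", "gTotal", "pumpVmax", "Rf", "sigma", "rateHz",
                 "driftScale")

.defaultPriors <- function(cell, sensor) {
  list(aCa = list(meanlog = log(cell@aCa), sdlog = 0.5),
       gTotal = list(meanlog = log(cell@gTotal), sdlog = 0.5),
       pumpVmax = list(meanlog = log(cell@pumpVmax), sdlog = 0.5),
       Rf = list(meanlog = log(sensor@Rf), sdlog = 0.3),
       sigma = list(meanlog = log(0.1), sdlog = 1),
       rateHz = list(meanlog = log(5), sdlog = 1),
       driftScale = list(meanlog = log(0.02), sdlog = 1))
}

.defaultScales <- function() {
  list(aCa = 0.08, gTotal = 0.08, pumpVmax = 0.08, Rf = 0.05,
       sigma = 0.08, rateHz = 0.15, driftScale = 0.2)
}

#' Gaussian observation log-likelihood
#'
#' Log-density of observed dF/F values under the observation model
#' y ~ Normal(prediction, sigma); the per-bin prediction is the modelled
#' dF/F plus the latent baseline.
#'
#' @param y observed value(s)
#' @param pred predicted value(s)
#' @param sigma observation noise SD (> 0)
#' @return the summed log-density
#' @export
obsLogLik <- function(y, pred, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  sum(dnorm(y, pred, sigma, log = TRUE))
}

## Model context shared by the SMC sweeps: propagator table and
## fluorescence normalization constants.
.smcContext <- function(sensor, cell, dt, nGrid = 400) {
  nFine <- max(1L, as.integer(ceiling(dt / 6.25e-5)))
  nCoarse <- max(1L, as.integer(ceiling(dt / 1e-3)))
  tab <- .cppBuildTable(
    list(koffCa = sensor@lobeN@koffCa, Ka = sensor@lobeN@Ka,
         hill = sensor@lobeN@hill, konPep = sensor@lobeN@konPep,
         koffPep = sensor@lobeN@koffPep),
    list(koffCa = sensor@lobeC@koffCa, Ka = sensor@lobeC@Ka,
         hill = sensor@lobeC@hill, konPep = sensor@lobeC@konPep,
         koffPep = sensor@lobeC@koffPep),
    dt, as.integer(nGrid), 1e-4, 200, nFine, nCoarse)
  pr <- .phiRange(sensor)
  list(PNf = tab$PNf, PCf = tab$PCf, PNc = tab$PNc, PCc = tab$PCc,
       caGrid = tab$caGrid, nFine = nFine, nCoarse = nCoarse,
       relaxBins = as.integer(ceiling(0.010 / dt)),
       phi0 = unname(pr["phi0"]), phiSat = unname(pr["phiSat"]),
       phiBasal = .phiOf(steadyState(sensor, cell@caBasal)@occupancy),
       nCa = sensor@nCaPerLobe,
       x0 = steadyState(sensor, cell@caBasal)@occupancy,
       cellList = list(kappaB = cell@kappaB, pumpKm = cell@pumpKm,
                       storeInVmax = cell@storeInVmax,
                       storeInKm = cell@storeInKm,
                       storeOutVmax = cell@storeOutVmax,
                       storeOutKm = cell@storeOutKm,
                       storeCaBasal = .storeRest(cell),
                       slowFrac = cell@slowFrac, slowK = cell@slowK,
                       caBasal = cell@caBasal),
       dt = dt)
}

## Deterministic binned dF/F prediction for a spike vector under theta.
.predictBins <- function(spikes, theta, ctx) {
  as.numeric(.cppSimBins(as.integer(spikes), theta, ctx$cellList, ctx,
                         ctx$x0, ctx$dt))
}

#' One conditional SMC sweep
#'
#' Runs a conditional particle filter in which particle 0 follows the
#' reference trajectory and its ancestor index is redrawn each bin by
#' ancestor-sampling weights (transition density times one-step-lookahead
#' likelihood under the reference continuation). Non-reference particles
#' propose spikes from Bernoulli(rateHz * dt) and advance the bouton model
#' deterministically. Returns one trajectory drawn from the genealogy.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param theta named list with aCa, gTotal, pumpVmax, Rf, sigma, rateHz,
#'   driftScale
#' @param reference list with integer \code{spikes} and numeric
#'   \code{baseline}, both of the trace's length
#' @param config an \linkS4class{InferenceConfig}
#' @param ctx model context from the internal context builder (built by
#'   \code{\link{pgasInfer}}; pass its \code{ctx} to reuse)
#' @return list with \code{spikes}, \code{baseline}
#' @export
conditionalSMC <- function(trace, theta, reference, config, ctx) {
  stopifnot(length(reference$spikes) == length(trace@dff))
  n <- length(trace@dff)
  ## bin j covers [(j-1) dt, j dt) and is observed by sample j+1; the last
  ## interval has no observation and is reported as spike-free
  out <- if (config@generativeModel == "linear_ar") {
    ar <- ctx$arPars
    .cppCSMCAr(trace@dff[-1], theta$aCa, ar$a1, ar$a2, theta$rateHz,
               theta$driftScale, theta$sigma,
               as.integer(reference$spikes[-n]),
               as.numeric(reference$baseline[-n]),
               config@nParticles, ctx$dt)
  } else {
    .cppCSMC(trace@dff[-1], theta, ctx$cellList, ctx, ctx$x0,
             as.integer(reference$spikes[-n]),
             as.numeric(reference$baseline[-n]),
             config@nParticles, ctx$dt)
  }
  list(spikes = c(as.integer(out$spikes), 0L),
       baseline = c(as.numeric(out$baseline),
                    tail(as.numeric(out$baseline), 1)))
}

## Joint log-posterior of theta given the latent trajectory.
.logPost <- function(y, traj, theta, priors, ctx, arPars = NULL) {
  ## bin j is observed by sample j + 1; the last bin is unobserved
  n <- length(y)
  sp <- traj$spikes[-n]
  bl <- traj$baseline[-n]
  pred <- if (is.null(arPars)) .predictBins(sp, theta, ctx)
          else as.numeric(.cppSimBinsAr(as.integer(sp),
                                        theta$aCa, arPars$a1, arPars$a2))
  ll <- obsLogLik(y[-1], pred + bl, theta$sigma)
  p <- min(theta$rateHz * ctx$dt, 0.95)
  ns <- sum(sp)
  ll <- ll + ns * log(p) + (length(sp) - ns) * log1p(-p)
  db <- diff(bl)
  sdStep <- theta$driftScale * sqrt(ctx$dt)
  ll <- ll + sum(dnorm(db, 0, sdStep, log = TRUE))
  for (nm in names(priors)) {
    pr <- priors[[nm]]
    ll <- ll + dnorm(log(theta[[nm]]), pr$meanlog, pr$sdlog, log = TRUE)
  }
  ll
}

#' Metropolis-within-Gibbs parameter update
#'
#' One sweep of log-scale random-walk Metropolis updates over the
#' estimated parameters (calcium influx per spike, sensor concentration,
#' extrusion rate, dynamic range, observation noise, spike rate, baseline
#' drift scale), conditional on the latent trajectory. Satisfies detailed
#' balance with respect to the conditional posterior.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param trajectory list with \code{spikes}, \code{baseline}
#' @param theta current named parameter list
#' @param config an \linkS4class{InferenceConfig} (priors and proposal
#'   scales are read from it; both must be fully populated)
#' @param ctx model context (see \code{\link{conditionalSMC}})
#' @param arPars optional AR(2) coefficients for the linear model
#' @param update names of the parameters to update
#' @return list with \code{theta}, \code{logPost}, \code{accepted} (named
#'   logical)
#' @export
updateParameters <- function(trace, trajectory, theta, config, ctx,
                             arPars = NULL,
                             update = intersect(.thetaNames,
                                                names(config@proposalScales))) {
  priors <- config@priors
  scales <- config@proposalScales
  y <- trace@dff
  lp <- .logPost(y, trajectory, theta, priors, ctx, arPars)
  accepted <- setNames(logical(length(update)), update)
  for (nm in update) {
    sc <- scales[[nm]]
    if (is.null(sc) || sc <= 0) next
    cand <- theta
    cand[[nm]] <- exp(log(theta[[nm]]) + rnorm(1, 0, sc))
    lpc <- tryCatch(.logPost(y, trajectory, cand, priors, ctx, arPars),
                    error = function(e) -Inf)
    if (is.finite(lpc) && log(runif(1)) < lpc - lp) {
      theta <- cand; lp <- lpc; accepted[nm] <- TRUE
    }
  }
  list(theta = theta, logPost = lp, accepted = accepted)
}

#' Fit an AR(2) kernel to the single-spike response
#'
#' Simulates the noiseless single-spike dF/F response of the given
#' sensor/cell pair at the bin rate and fits the per-spike fixed-amplitude
#' AR(2) kernel used by the linear generative model: amplitude A is the
#' first-bin response and (a1, a2) minimize the squared one-step linear
#' prediction error of the kernel tail.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param cell a \linkS4class{CellParams}
#' @param rate bin rate (Hz)
#' @param duration kernel support (s)
#' @return list with A, a1, a2 and the kernel vector
#' @export
fitArKernel <- function(sensor, cell, rate, duration = 0.6) {
  cell@sigma <- 0
  tr <- simulateCell(cell, sensor, SpikeTrain(0), duration, rate)
  k <- tr@dff[-1]  # response from the first post-spike bin
  n <- length(k)
  X <- cbind(k[2:(n - 1)], k[1:(n - 2)])
  yv <- k[3:n]
  ab <- qr.solve(X, yv)
  ## guard: keep the AR(2) stable
  if (abs(ab[2]) >= 1) ab[2] <- sign(ab[2]) * 0.999
  list(A = k[1], a1 = ab[1], a2 = ab[2], kernel = k)
}

#' AR(2) impulse response
#'
#' @param A amplitude; @param a1,a2 AR coefficients; @param n length
#' @return numeric vector h with h[1] = A and
#'   h[t] = a1 h[t-1] + a2 h[t-2]
#' @export
arImpulseResponse <- function(A, a1, a2, n) {
  as.numeric(.cppSimBinsAr(as.integer(c(1, rep(0, n - 1))), A, a1, a2))
}

#' Particle Gibbs with ancestor sampling spike inference
#'
#' Alternates conditional SMC sweeps over the latent spike/baseline
#' trajectory with Metropolis-within-Gibbs updates of the cell parameters,
#' under either the biophysical generative model or a linear AR(2)
#' baseline ("Linear SMC"). Per-bin spike probabilities are the mean of the
#' sampled indicators after a 25\% burn-in; MAP spikes come from
#' \code{\link{mapSpikes}}. Deterministic given \code{config@seed}.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param sensor a \linkS4class{SensorModel}
#' @param config an \linkS4class{InferenceConfig}
#' @param cell starting \linkS4class{CellParams} (prior centres)
#' @param keepTrajectories if TRUE, the post-burn-in sampled spike trains
#'   (one per iteration, as spike times) are kept in
#'   \code{config$sampledTrains} of the result, mirroring the
#'   single-trajectory spike displays used to compare generative models
#' @return a \linkS4class{PosteriorSummary}
#' @export
pgasInfer <- function(trace, sensor, config, cell = defaultCellParams(),
                      keepTrajectories = FALSE) {
  if (any(!is.finite(trace@dff))) stop("trace must be finite")
  dt <- if (is.na(config@binDt)) 1 / trace@rate else config@binDt
  if (abs(dt - 1 / trace@rate) > 1e-9)
    stop("binDt must equal the trace sample interval (one spike per bin)")
  priors <- utils::modifyList(.defaultPriors(cell, sensor), config@priors)
  scales <- utils::modifyList(.defaultScales(), config@proposalScales)
  cfg <- config
  cfg@priors <- priors
  cfg@proposalScales <- scales
  linear <- config@generativeModel == "linear_ar"
  ctx <- .smcContext(sensor, cell, dt)
  arPars <- if (linear) fitArKernel(sensor, cell, trace@rate) else NULL
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(config@seed)
  theta <- list(aCa = if (linear) arPars$A else cell@aCa,
                gTotal = cell@gTotal, pumpVmax = cell@pumpVmax,
                Rf = sensor@Rf,
                sigma = max(mad(diff(trace@dff)) / sqrt(2), 1e-3),
                rateHz = exp(priors$rateHz$meanlog),
                driftScale = exp(priors$driftScale$meanlog))
  if (linear) {
    ## amplitude prior for the AR model is centred on the fitted kernel
    priors$aCa <- list(meanlog = log(max(arPars$A, 1e-4)), sdlog = 0.5)
    cfg@priors <- priors
  }
  updateSet <- if (linear) c("aCa", "sigma", "rateHz", "driftScale")
               else c("aCa", "gTotal", "pumpVmax", "Rf", "sigma", "rateHz",
                      "driftScale")
  nBins <- length(trace@dff)
  ctx$arPars <- arPars
  traj <- list(spikes = integer(nBins), baseline = numeric(nBins))
  nIt <- config@nIterations
  spikeSum <- numeric(nBins)
  burn <- max(1L, floor(0.25 * nIt))
  samples <- matrix(NA_real_, nIt, length(.thetaNames),
                    dimnames = list(NULL, .thetaNames))
  logPost <- numeric(nIt)
  kept <- 0L
  sampledTrains <- if (keepTrajectories) vector("list", nIt - burn) else NULL
  centers <- ((seq_len(nBins) - 1) + 0.5) / trace@rate
  for (it in seq_len(nIt)) {
    traj <- conditionalSMC(trace, theta, traj, cfg, ctx)
    up <- updateParameters(trace, traj, theta, cfg, ctx, arPars,
                           update = updateSet)
    theta <- up$theta
    logPost[it] <- up$logPost
    samples[it, ] <- unlist(theta[.thetaNames])
    if (it > burn) {
      spikeSum <- spikeSum + traj$spikes
      kept <- kept + 1L
      if (keepTrajectories)
        sampledTrains[[kept]] <- centers[traj$spikes == 1L]
    }
  }
  prob <- spikeSum / max(kept, 1L)
  post <- new("PosteriorSummary", spikeProb = prob,
              mapSpikes = SpikeTrain(), paramSamples = as.data.frame(samples),
              logPost = logPost,
              config = list(nParticles = config@nParticles,
                            nIterations = nIt, binDt = dt,
                            seed = config@seed,
                            generativeModel = config@generativeModel,
                            burnIn = burn, priors = priors,
                            proposalScales = scales,
                            sampledTrains = sampledTrains))
  post@mapSpikes <- mapSpikes(post, rate = trace@rate)
  post
}

#' MAP spike train from posterior spike probabilities
#'
#' Bins with posterior spike probability above 0.5 are taken as spikes;
#' maximal runs of adjacent supra-threshold bins are merged into single
#' events placed at the probability-weighted centre of the run's bin
#' centres.
#'
#' @param posterior a \linkS4class{PosteriorSummary} (or a numeric
#'   probability vector)
#' @param rate bin rate (Hz)
#' @param threshold probability threshold (default 0.5)
#' @return a \linkS4class{SpikeTrain}
#' @export
mapSpikes <- function(posterior, rate, threshold = 0.5) {
  p <- if (is(posterior, "PosteriorSummary")) posterior@spikeProb
       else as.numeric(posterior)
  if (missing(rate) && is(posterior, "PosteriorSummary"))
    rate <- 1 / posterior@config$binDt
  above <- p > threshold
  if (!any(above)) return(SpikeTrain())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  centers <- ((seq_along(p) - 1) + 0.5) / rate
  times <- vapply(which(r$values), function(j) {
    idx <- starts[j]:ends[j]
    sum(centers[idx] * p[idx]) / sum(p[idx])
  }, numeric(1))
  SpikeTrain(sort(times))
}
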