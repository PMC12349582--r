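#' Generate synthetic soil-moisture and temperature forcings
#'
#' Produces per-grid series on the 8-day composite calendar. Both drivers
#' are a seasonal sinusoid plus mean-reverting AR(1) Gaussian anomalies:
#' temperature (clipped to \[-50, 50\] deg C) with weakly persistent
#' synoptic anomalies, soil moisture (clipped to \[0, 1000\] kg/m2) with
#' strongly persistent recharge/dry-down anomalies. Each grid receives a
#' static mean offset (sd `grid_sd_T` / `grid_sd_SM`) so cells differ.
#'
#' @param spec a [GridSpec-class].
#' @param years simulated years (>= 1).
#' @param params a [CouplingParams-class].
#' @param seed integer RNG seed; identical inputs give identical output.
#' @param start_year first calendar year of the simulation.
#' @return list with `calendar` (see [compositeCalendar()]) and matrices
#'   `soil_moisture`, `temperature` (grids x composites, rownames = grid ids).
#' @export
generateForcings <- function(spec, years, params = couplingParams(), seed = 1L,
                             start_year = 2001L) {
  years <- assertCount(years, "years")
  cal <- compositeCalendar(start_year, years)
  nt <- nrow(cal)
  ng <- length(spec@gridIds)
  set.seed(seed)

  offT <- stats::rnorm(ng, 0, params@gridSdT)
  offSM <- stats::rnorm(ng, 0, params@gridSdSM)

  seasT <- params@ampT * sin(2 * pi * (cal$doy - params@phaseT) / 365)
  seasSM <- params@ampSM * sin(2 * pi * (cal$doy - params@phaseSM) / 365)

  temperature <- matrix(NA_real_, ng, nt,
                        dimnames = list(spec@gridIds, NULL))
  soil_moisture <- temperature

  ## seasonal mean + AR(1) anomalies, mean-reverting to the seasonal cycle
  arSeries <- function(m, rho, sd) {
    eps <- stats::rnorm(length(m), 0, sd)
    s <- numeric(length(m))
    s[1] <- m[1] + eps[1]
    for (t in seq_along(m)[-1]) {
      s[t] <- m[t] + rho * (s[t - 1] - m[t - 1]) + eps[t]
    }
    s
  }
  for (g in seq_len(ng)) {
    temperature[g, ] <- clip(
      arSeries(params@meanT + offT[g] + seasT, params@arT, params@noiseSdT),
      -50, 50)
    soil_moisture[g, ] <- clip(
      arSeries(params@meanSM + offSM[g] + seasSM, params@arSM,
               params@noiseSdSM),
      0, 1000)
  }
  list(calendar = cal, soil_moisture = soil_moisture,
       temperature = temperature)
}

## Mean of the trailing `lag` values (inclusive); partial means at the start.
laggedMean <- function(x, lag) {
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - lag, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

## Min-max scale a vector to [0, 1]; constant vectors map to 0.5.
unitScale <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

## Phenological envelope in [floor, 1] as a function of day of year:
## Gaussian bump(s) around the peak day(s) over a constant off-season floor.
phenologyEnvelope <- function(doy, env) {
  e <- rowSums(vapply(env$peaks,
                      function(p) exp(-((doy - p) / env$width)^2),
                      numeric(length(doy))))
  fl <- if (is.null(env$floor)) 0 else env$floor
  fl + (1 - fl) * e / max(e)
}

#' Generate LAI coupled to the forcings with known dominance
#'
#' The latent growth signal is `G_t = lambda * S_t + (1 - lambda) * T_t`,
#' where `S` and `T` are the min-max-scaled trailing means of soil moisture
#' and temperature over the past `lag_steps` composites. LAI is the
#' vegetation-class phenological envelope times a logistic saturation of
#' `G_t` times the class maximum LAI, plus Gaussian noise, clipped to
#' \[0, 10\]. Double-season crops get a bimodal envelope (two intra-annual
#' peaks separated by a harvest dip); non-vegetated cells stay near zero.
#'
#' @param forcings output of [generateForcings()].
#' @param spec the [GridSpec-class] used to generate the forcings.
#' @param params a [CouplingParams-class].
#' @param seed integer RNG seed for the LAI noise.
#' @return matrix of LAI (grids x composites, m2/m2).
#' @export
generateLai <- function(forcings, spec, params = couplingParams(), seed = 1L) {
  cal <- forcings$calendar
  ng <- length(spec@gridIds)
  if (!identical(rownames(forcings$soil_moisture), spec@gridIds) ||
      !identical(rownames(forcings$temperature), spec@gridIds) ||
      ncol(forcings$soil_moisture) != nrow(cal) ||
      ncol(forcings$temperature) != nrow(cal)) {
    imvStop("forcings and grid spec are not on the same calendar/grid",
            "alignmentError")
  }
  set.seed(seed)
  lam <- params@dominanceLambda
  lai <- matrix(NA_real_, ng, nrow(cal), dimnames = list(spec@gridIds, NULL))
  for (g in seq_len(ng)) {
    sS <- unitScale(laggedMean(forcings$soil_moisture[g, ], params@lagSteps))
    sT <- unitScale(laggedMean(forcings$temperature[g, ], params@lagSteps))
    G <- lam * sS + (1 - lam) * sT
    sat <- stats::plogis((G - params@satMid) / params@satScale)
    env <- params@envelopes[[spec@landcover[g]]]
    shape <- phenologyEnvelope(cal$doy, env)
    lai[g, ] <- clip(shape * sat * env$lai_max +
                       stats::rnorm(nrow(cal), 0, params@noiseSdLAI), 0, 10)
  }
  lai
}

#' Simulate a full gridded dataset
#'
#' Runs [generateForcings()] and [generateLai()] and assembles a
#' [LaiGrids-class] container.
#'
#' @inheritParams generateForcings
#' @return A [LaiGrids-class] object; generator settings are recorded in
#'   `metadata()`.
#' @examples
#' x <- simulateLaiGrids(gridSpec(2, 2), years = 2, seed = 7)
#' dim(x)
#' @export
simulateLaiGrids <- function(spec, years, params = couplingParams(),
                             seed = 1L, start_year = 2001L) {
  f <- generateForcings(spec, years, params, seed = seed,
                        start_year = start_year)
  lai <- generateLai(f, spec, params, seed = seed + 1000L)
  se <- SummarizedExperiment(
    assays = list(soil_moisture = f$soil_moisture,
                  temperature = f$temperature, lai = lai),
    rowData = DataFrame(grid_id = spec@gridIds,
                        row = rep(seq_len(spec@nRows), each = spec@nCols),
                        col = rep(seq_len(spec@nCols), spec@nRows),
                        landcover = spec@landcover,
                        row.names = spec@gridIds),
    colData = DataFrame(f$calendar)
  )
  out <- new("LaiGrids", se)
  S4Vectors::metadata(out) <- list(
    seed = seed, years = years, start_year = start_year,
    dominance_lambda = params@dominanceLambda, lag_steps = params@lagSteps)
  out
}
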