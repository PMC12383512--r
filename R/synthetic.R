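#' Construct a SpeciesResponse
#'
#' @param curves data.frame with columns \code{covariate}, \code{optimum},
#'   \code{width}, \code{weight}: Gaussian response curves on the named
#'   covariates.
#' @param gamma Signed interspecific coupling coefficient; the species'
#'   final suitability is its base suitability modulated by
#'   \code{(1 + gamma * suitability_other)} (see \code{\link{trueSuitability}}).
#' @return A \linkS4class{SpeciesResponse}.
#' @export
SpeciesResponse <- function(curves, gamma = 0) {
  curves$covariate <- as.character(curves$covariate)
  new("SpeciesResponse", curves = curves, gamma = as.numeric(gamma))
}

#' Construct an EffortModel
#'
#' @param nVessels Fleet size (default 80).
#' @param monthlyBudget Effort days allocated per month (default 150).
#' @param k Concentration exponent, expected effort proportional to
#'   suitability^k (default 2).
#' @param q Catchability, tons per day at suitability 1 (default 1.5).
#' @param sigma Lognormal catch-noise dispersion (default 0.1).
#' @param floor Minimum suitability fished (default 0.05).
#' @param haulRate Hauls per effort day (default 2).
#' @return An \linkS4class{EffortModel}.
#' @export
EffortModel <- function(nVessels = 80L, monthlyBudget = 150, k = 2, q = 1.5,
                        sigma = 0.1, floor = 0.05, haulRate = 2) {
  new("EffortModel", nVessels = as.integer(nVessels),
      monthlyBudget = monthlyBudget, k = k, q = q, sigma = sigma,
      floor = floor, haulRate = haulRate)
}

## per-month mean offsets for surface temperature, June..November
.SEASONAL_T <- c(`6` = -2, `7` = 0, `8` = 1.5, `9` = 1, `10` = -1, `11` = -3.5)

#' Generate a synthetic environment stack
#'
#' Emulates the gridded monthly ocean covariates the pipeline consumes.
#' Temperature carries a southward-warming latitudinal gradient, a seasonal
#' cycle peaking in August, a mean decrease with depth (default lapse 0.045
#' degC per m, so the 200 m field averages 9 degC colder than the surface)
#' and smooth spatial noise per depth. SSH/SSS/Chl-a/U/V are smooth fields
#' with realistic magnitudes; EKE is computed from the U,V anomalies about
#' each layer's spatial mean as \code{0.5 * (u'^2 + v'^2)}; SSTA and ONI
#' are per-month basin scalars broadcast to all cells.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param years Integer vector of years (no duplicates).
#' @param months Months as numbers 6..11 or names June..November
#'   (no duplicates).
#' @param seed Integer seed; same seed reproduces the stack bit for bit.
#' @param landMask Optional logical per-cell mask (TRUE = land / missing).
#' @param lapse Temperature decrease per metre of depth (degC/m).
#' @return An \linkS4class{EnvStack}.
#' @export
generateEnvironment <- function(grid, years, months, seed, landMask = NULL,
                                lapse = 0.045) {
  months <- monthNumber(months)
  if (!all(months %in% 6:11))
    stop("months must lie within June..November (6..11)")
  if (anyDuplicated(years) || anyDuplicated(months))
    stop("duplicate (year, month) layers requested")
  if (nCells(grid) < 1L) stop("grid has no cells")
  set.seed(as.integer(seed))
  ni <- nLat(grid); nj <- nLon(grid); nc <- nCells(grid)
  cc <- cellCenters(grid)
  layers <- expand.grid(month = sort(months), year = sort(years))[, c("year", "month")]
  nl <- nrow(layers)
  depths <- c(T_0m = 0, T_50m = 50, T_100m = 100, T_150m = 150, T_200m = 200)
  assays <- lapply(covariateNames(), function(v) matrix(NA_real_, nc, nl))
  names(assays) <- covariateNames()
  ssta <- rnorm(nl, 0, 0.6)
  oni <- rnorm(nl, 0, 0.8)
  for (l in seq_len(nl)) {
    mo <- layers$month[l]
    yearShift <- rnorm(1, 0, 0.5)
    t0base <- 24 + .SEASONAL_T[as.character(mo)] + yearShift -
      0.8 * (cc$lat - grid@latMin)
    for (d in names(depths)) {
      noise <- .fieldToVector(.smoothField(ni, nj, scale = 8, sd = 1.5))
      assays[[d]][, l] <- t0base - lapse * depths[[d]] + noise
    }
    assays$SSH[, l] <- 0.5 - 0.02 * (cc$lat - mean(cc$lat)) +
      0.1 * .fieldToVector(.smoothField(ni, nj, scale = 10, sd = 1))
    assays$SSS[, l] <- 34 + 0.05 * (cc$lat - mean(cc$lat)) +
      0.4 * .fieldToVector(.smoothField(ni, nj, scale = 10, sd = 1))
    assays$Chl_a[, l] <- exp(-1 + 0.09 * (cc$lat - grid@latMin) +
      0.6 * .fieldToVector(.smoothField(ni, nj, scale = 8, sd = 1)))
    u <- 0.1 + 0.15 * .fieldToVector(.smoothField(ni, nj, scale = 6, sd = 1))
    v <- 0.02 + 0.15 * .fieldToVector(.smoothField(ni, nj, scale = 6, sd = 1))
    assays$U[, l] <- u
    assays$V[, l] <- v
    assays$EKE[, l] <- 0.5 * ((u - mean(u))^2 + (v - mean(v))^2)
    assays$SSTA[, l] <- ssta[l]
    assays$ONI[, l] <- oni[l]
  }
  EnvStack(grid, assays, layers$year, layers$month, mask = landMask)
}

## base suitability of one species on one covariate layer matrix:
## weight-normalized geometric mean of Gaussian responses, in [0, 1]
.baseSuitability <- function(layer, resp) {
  cv <- resp@curves
  missing <- setdiff(cv$covariate, colnames(layer))
  if (length(missing))
    stop("response references covariate(s) absent from the environment: ",
         paste(missing, collapse = ", "))
  w <- cv$weight / sum(cv$weight)
  z2 <- 0
  for (r in seq_len(nrow(cv))) {
    x <- layer[, cv$covariate[r]]
    z2 <- z2 + w[r] * ((x - cv$optimum[r]) / cv$width[r])^2
  }
  exp(-0.5 * z2)
}

#' Generative true suitability surfaces for two coupled species
#'
#' Base suitability per species is the weight-normalized geometric mean of
#' its Gaussian covariate responses (each in [0,1]). The interspecific
#' coupling then modulates each species by the other's base suitability:
#' with the default multiplicative rule, species B's final surface is
#' \code{base_B * (1 + gamma_B * base_A)}, renormalized per layer so that
#' its maximum equals \code{base_B}'s maximum, then clipped to [0,1] (and
#' symmetrically for A when \code{gamma_A != 0}). The renormalization
#' preserves the coupled species' dynamic range even where the two niches
#' barely overlap, and leaves Pearson correlations between the surfaces
#' untouched (it is a positive per-layer scaling); at \code{gamma = 0} the
#' final surface is exactly the base surface. These surfaces are the
#' generative truth used for effort allocation and for coupling-recovery
#' tests.
#'
#' @param env An \linkS4class{EnvStack}.
#' @param respA,respB \linkS4class{SpeciesResponse} for the two species.
#' @param speciesA,speciesB Species tags used on the returned surfaces.
#' @param coupling \code{"multiplicative"} (default) or \code{"additive"}
#'   (\code{(base + gamma * base_other) / (1 + max(gamma, 0))}, clipped).
#' @return Named list with elements \code{A} and \code{B}, each a list of
#'   \linkS4class{HSISurface} (role \code{"truth"}), one per (year, month)
#'   layer, named \code{"YYYY-MM"}.
#' @export
trueSuitability <- function(env, respA, respB, speciesA = "A", speciesB = "B",
                            coupling = c("multiplicative", "additive")) {
  coupling <- match.arg(coupling)
  cd <- SummarizedExperiment::colData(env)
  grid <- gridSpec(env)
  combine <- function(base, other, g) {
    raw <- if (coupling == "multiplicative")
      base * (1 + g * other)
    else
      base + g * other
    if (g == 0) return(.clip01(raw))
    rmax <- suppressWarnings(max(raw, na.rm = TRUE))
    if (!is.finite(rmax) || rmax <= 0) return(raw * 0)  # caught as all-zero below
    # renormalize per layer so the coupled field keeps the base field's
    # dynamic range (its maximum), then clip; monotone in 'other' cellwise
    .clip01(raw * (max(base, na.rm = TRUE) / rmax))
  }
  outA <- outB <- vector("list", ncol(env))
  for (l in seq_len(ncol(env))) {
    layer <- envLayer(env, cd$year[l], cd$month[l])
    baseA <- .baseSuitability(layer, respA)
    baseB <- .baseSuitability(layer, respB)
    finalA <- combine(baseA, baseB, respA@gamma)
    finalB <- combine(baseB, baseA, respB@gamma)
    for (nm in c("finalA", "finalB")) {
      v <- get(nm)
      if (all(is.na(v) | v == 0))
        stop("coupling produced an all-zero suitability surface (", nm,
             " at ", cd$year[l], "-", cd$month[l], ")")
    }
    outA[[l]] <- HSISurface(grid, finalA, speciesA, "truth", cd$year[l], cd$month[l])
    outB[[l]] <- HSISurface(grid, finalB, speciesB, "truth", cd$year[l], cd$month[l])
  }
  nm <- sprintf("%d-%02d", cd$year, cd$month)
  names(outA) <- names(outB) <- nm
  list(A = outA, B = outB)
}

#' Simulate one month of logbook records from a truth surface
#'
#' Expected effort per cell is proportional to \code{truth^k}, restricted
#' to cells at or above the detection floor; the monthly effort budget is
#' integerized by one multinomial draw (so total recorded effort equals the
#' budget exactly). Cell effort is split into vessel trips, and catch per
#' record is \code{q * effort * truth} times mean-one lognormal noise.
#' Record positions are uniform within the assigned cell.
#'
#' @param truth An \linkS4class{HSISurface} (any role; normally
#'   \code{"truth"}).
#' @param effortModel An \linkS4class{EffortModel}.
#' @param grid A \linkS4class{GridSpec} conformable with \code{truth}.
#' @param seed Integer seed.
#' @return data.frame with columns \code{date, lat, lon, species, catch_t,
#'   hauls, effort_days, vessel_id, vessel_length_m}.
#' @export
sampleLogbook <- function(truth, effortModel, grid, seed) {
  if (!.sameGrid(truth@grid, grid))
    stop("truth surface and grid are not conformable")
  em <- effortModel
  set.seed(as.integer(seed))
  v <- truth@values
  vmax <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(vmax) || vmax <= 0)
    stop("empty feasible region: truth surface has no positive cells")
  # scale by the max before powering so large k cannot underflow to all-zero
  w <- ifelse(is.na(v) | v < em@floor, 0, (v / vmax)^em@k)
  if (all(w == 0))
    stop("empty feasible region: no cell reaches the detection floor ", em@floor)
  effort <- as.vector(rmultinom(1, size = round(em@monthlyBudget), prob = w))
  fished <- which(effort > 0L)
  cc <- cellCenters(grid)
  vesselLen <- 40 + (seq_len(em@nVessels) * 7L) %% 21  # stable per vessel id
  E <- effort[fished]
  ntrip <- pmin(E, 1L + rpois(length(E), E / 7))
  # split each cell's effort days into its vessel trips
  splits <- lapply(seq_along(E), function(ix) {
    s <- as.vector(rmultinom(1, E[ix], rep(1, ntrip[ix])))
    s[s > 0L]
  })
  nrec <- lengths(splits)
  cell <- rep(fished, nrec)
  split <- unlist(splits)
  n <- length(split)
  vid <- sample.int(em@nVessels, n, replace = TRUE)
  noise <- if (em@sigma > 0) exp(rnorm(n, -em@sigma^2 / 2, em@sigma)) else rep(1, n)
  out <- data.frame(
    date = sprintf("%04d-%02d-%02d", truth@year, truth@month,
                   sample.int(28L, n, replace = TRUE)),
    lat = cc$lat[cell] + runif(n, -0.5, 0.5) * grid@res,
    lon = cc$lon[cell] + runif(n, -0.5, 0.5) * grid@res,
    species = truth@species,
    catch_t = em@q * split * v[cell] * noise,
    hauls = as.integer(round(split * em@haulRate)),
    effort_days = split,
    vessel_id = vid,
    vessel_length_m = vesselLen[vid])
  rownames(out) <- NULL
  out
}

#' Simulate a multi-month, two-species fishery
#'
#' Convenience wrapper looping \code{\link{sampleLogbook}} over every truth
#' surface of both species; each surface gets its own substream seed
#' derived from the root seed and the surface's (species, year, month), so
#' any single month can be regenerated independently.
#'
#' @param truths The two-species truth list from \code{\link{trueSuitability}}.
#' @param effortModel An \linkS4class{EffortModel} (shared by both fleets).
#' @param grid A \linkS4class{GridSpec}.
#' @param seed Integer root seed.
#' @return Combined logbook data.frame.
#' @export
simulateFishery <- function(truths, effortModel, grid, seed) {
  out <- lapply(c(truths$A, truths$B), function(s)
    sampleLogbook(s, effortModel, grid,
                  deriveSeed(seed, paste(s@species, s@year, s@month))))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
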