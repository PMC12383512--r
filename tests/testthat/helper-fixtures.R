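## Small grids, environments and surfaces built in code for the tests.

tinyGrid <- function() GridSpec(34, 35, 144, 145, 0.25)  # 4 x 4 cells

## deterministic tiny environment stack (values set by hand, not generated)
tinyEnv <- function(grid = tinyGrid(), years = 2020L, months = 6L,
                    mask = NULL, oni = 0.5, ssta = 0.3) {
  nl <- length(years) * length(months)
  layers <- expand.grid(month = months, year = years)
  nc <- nCells(grid)
  assays <- lapply(seq_along(covariateNames()), function(k) {
    matrix(rep(seq_len(nc) / nc + k, nl), nc, nl)
  })
  names(assays) <- covariateNames()
  assays$ONI[] <- oni
  assays$SSTA[] <- ssta
  EnvStack(grid, assays, layers$year, layers$month, mask = mask)
}

constantSurface <- function(value, grid = tinyGrid(), species = "A",
                            role = "truth", year = 2020L, month = 6L) {
  HSISurface(grid, rep(value, nCells(grid)), species, role, year, month)
}

## logbook row helper
logRow <- function(date, lat, lon, species = "A", catch = 1, hauls = 2,
                   effort = 1, vessel = 1L, len = 45) {
  data.frame(date = date, lat = lat, lon = lon, species = species,
             catch_t = catch, hauls = hauls, effort_days = effort,
             vessel_id = vessel, vessel_length_m = len)
}

## default two-species responses from the run configuration
defaultResponses <- function(gammaB = 0.8) {
  cfg <- defaultRunConfig(1)
  list(A = SpeciesResponse(cfg$species$A$curves, 0),
       B = SpeciesResponse(cfg$species$B$curves, gammaB))
}

## compact run configuration for end-to-end tests: 20 x 20 cells, two
## training years, two months; species optima recentred on the small
## window's covariate ranges so both niches live inside it
smallTestConfig <- function(seed = 1L) {
  cfg <- defaultRunConfig(seed)
  cfg$grid <- list(lat_min = 34, lat_max = 39, lon_min = 144, lon_max = 149,
                   res = 0.25)
  cfg$train_years <- 2019:2020
  cfg$predict_years <- 2021L
  cfg$months <- 6:7
  cfg$species$A$curves <- data.frame(
    covariate = c("T_0m", "Chl_a", "SSH"),
    optimum = c(20.5, 0.5, 0.5), width = c(1.2, 0.25, 0.15),
    weight = c(2, 1, 1))
  cfg$species$B$curves <- data.frame(
    covariate = c("T_50m", "Chl_a"),
    optimum = c(18.5, 0.45), width = c(2, 0.3), weight = c(1, 0.5))
  cfg$effort$monthly_budget <- 120
  cfg$model$ntree <- 30L
  cfg$validation$iterations <- 5L
  cfg
}
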