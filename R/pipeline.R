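#' Default run configuration
#'
#' One nested list drives the whole workflow: grid bounds, training and
#' prediction windows, the two species' response curves and coupling, the
#' effort model, model and validation settings, and the cohabitation
#' combiner. All randomness flows from the single \code{seed} through named
#' substreams. The defaults encode the study conditions: a 0.25-degree
#' grid over 34-45 N, 144-163 E, June-November, four training years and
#' one prediction year, two species with distinct thermal niches and a
#' one-way coupling of 0.8 from species A's suitability into species B.
#'
#' @param seed Integer root seed.
#' @return A named list (RunConfig).
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    grid = list(lat_min = 34, lat_max = 45, lon_min = 144, lon_max = 163,
                res = 0.25),
    train_years = 2017:2020,
    predict_years = 2021L,
    months = 6:11,
    species = list(
      A = list(name = "sardine",
               curves = data.frame(
                 covariate = c("T_0m", "T_100m", "Chl_a", "SSH", "SSS", "EKE"),
                 optimum = c(15, 10.5, 1.0, 0.5, 33.8, 0.02),
                 width = c(1.2, 1.2, 0.4, 0.12, 0.45, 0.03),
                 weight = c(2, 1, 1, 1, 1, 0.5)),
               gamma = 0),
      B = list(name = "mackerel",
               curves = data.frame(
                 covariate = c("T_50m", "Chl_a"),
                 optimum = c(12.5, 0.8),
                 width = c(2.5, 0.6),
                 weight = c(1, 0.5)),
               gamma = 0.8)),
    coupling = "multiplicative",
    effort = list(n_vessels = 80L, monthly_budget = 150, k = 2, q = 1.5,
                  sigma = 0.1, floor = 0.05, haul_rate = 2),
    model = list(ntree = 1000L, mtry = 4L, min_node = 5L),
    validation = list(iterations = 100L, train_fraction = 0.8),
    combiner = "geometric_mean",
    seed = as.integer(seed))
}

#' Read and validate a YAML run configuration
#'
#' Missing fields fall back to \code{\link{defaultRunConfig}} values;
#' malformed fields raise an error naming the field.
#'
#' @param path Path to a YAML file, or a named list to validate in place.
#' @return A validated RunConfig list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- defaultRunConfig(seed = cfg$seed %||% 1L)
  cfg <- utils::modifyList(base, cfg)
  for (sp in names(cfg$species))
    if (is.list(cfg$species[[sp]]$curves) && !is.data.frame(cfg$species[[sp]]$curves))
      cfg$species[[sp]]$curves <- as.data.frame(cfg$species[[sp]]$curves)
  validateRunConfig(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRunConfig
#' @param config A RunConfig list.
#' @export
validateRunConfig <- function(config) {
  fail <- function(field, why) stop(sprintf("config field '%s' invalid: %s", field, why))
  g <- config$grid
  for (f in c("lat_min", "lat_max", "lon_min", "lon_max", "res"))
    if (!is.numeric(g[[f]]) || length(g[[f]]) != 1L) fail(paste0("grid.", f), "must be a numeric scalar")
  if (g$res <= 0) fail("grid.res", "must be > 0")
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    fail("seed", "must be a single integer (no wall-clock seeding)")
  if (!all(monthNumber(config$months) %in% 6:11))
    fail("months", "must lie within June..November")
  if (length(intersect(config$train_years, config$predict_years)) &&
      !isTRUE(config$allow_overlap))
    fail("predict_years", "overlaps train_years (set allow_overlap: true to permit)")
  for (sp in c("A", "B")) {
    s <- config$species[[sp]]
    if (is.null(s)) fail(paste0("species.", sp), "missing")
    if (!is.data.frame(s$curves)) fail(paste0("species.", sp, ".curves"), "must be a table")
    if (!is.numeric(s$gamma)) fail(paste0("species.", sp, ".gamma"), "must be numeric")
  }
  v <- config$validation
  if (v$train_fraction <= 0 || v$train_fraction >= 1)
    fail("validation.train_fraction", "must lie strictly in (0, 1)")
  if (!config$combiner %in% c("geometric_mean", "min", "product"))
    fail("combiner", "must be geometric_mean, min or product")
  config
}

## config -> domain objects
.cfgGrid <- function(config) {
  g <- config$grid
  GridSpec(g$lat_min, g$lat_max, g$lon_min, g$lon_max, g$res)
}
.cfgResponse <- function(config, which) {
  s <- config$species[[which]]
  SpeciesResponse(s$curves, s$gamma)
}
.cfgEffort <- function(config) {
  e <- config$effort
  EffortModel(e$n_vessels, e$monthly_budget, e$k, e$q, e$sigma, e$floor,
              e$haul_rate)
}
.cfgModelSpec <- function(config, seed) {
  m <- config$model
  ModelSpec(covariateNames(), m$ntree, m$mtry, m$min_node, seed)
}

## deterministic md5 of a config (serialized to canonical JSON)
.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.writeManifest <- function(stage, config, files, outDir) {
  files <- sort(files)
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(names(hashes))
  man <- list(stage = stage, config_hash = .configHash(config),
              run_id = substr(.configHash(config), 1, 12),
              seed = config$seed, files = hashes)
  path <- file.path(outDir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

.checkOverwrite <- function(paths, force) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !force)
    stop("output file(s) already exist (use force = TRUE): ",
         paste(basename(hit), collapse = ", "))
}

#' Simulation stage: environment, truth surfaces and logbook
#'
#' Generates the synthetic environment over the union of training and
#' prediction years, the two species' coupled truth surfaces, and the
#' fishery logbook, then writes \code{logbook.csv}, \code{env_long.csv},
#' \code{truth_long.csv} and a manifest with md5 hashes.
#'
#' @param config A RunConfig (see \code{\link{defaultRunConfig}}).
#' @param outDir Output directory (created if missing).
#' @param force Overwrite existing outputs (default FALSE).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
runSimulate <- function(config, outDir, force = FALSE) {
  config <- validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outDir, c("logbook.csv", "env_long.csv", "truth_long.csv"))
  .checkOverwrite(paths, force)
  grid <- .cfgGrid(config)
  years <- sort(union(config$train_years, config$predict_years))
  env <- generateEnvironment(grid, years, config$months,
                             seed = deriveSeed(config$seed, "generator"))
  respA <- .cfgResponse(config, "A"); respB <- .cfgResponse(config, "B")
  truths <- trueSuitability(env, respA, respB,
                            speciesA = config$species$A$name,
                            speciesB = config$species$B$name,
                            coupling = config$coupling)
  logbook <- simulateFishery(truths, .cfgEffort(config), grid,
                             seed = deriveSeed(config$seed, "fishery"))
  writeLogbook(logbook, paths[1])
  write.csv(envToLong(env), paths[2], row.names = FALSE, quote = FALSE)
  write.csv(surfaceToLong(c(truths$A, truths$B)), paths[3],
            row.names = FALSE, quote = FALSE)
  manifest <- .writeManifest("simulate", config, paths, outDir)
  message(sprintf("simulate: %d records, %d env layers -> %s",
                  nrow(logbook), ncol(env), outDir))
  invisible(list(env = env, truths = truths, logbook = logbook,
                 files = c(paths, manifest)))
}

#' Gridding stage: logbook + environment to cell samples
#'
#' @inheritParams runSimulate
#' @return Invisibly, the cell-sample table and file paths.
#' @export
runGrid <- function(config, outDir, force = FALSE) {
  config <- validateRunConfig(config)
  grid <- .cfgGrid(config)
  logbook <- readLogbook(file.path(outDir, "logbook.csv"))
  env <- envFromLong(read.csv(file.path(outDir, "env_long.csv")), grid)
  path <- file.path(outDir, "cell_samples.csv")
  .checkOverwrite(path, force)
  samples <- buildCellSamples(logbook, env)
  write.csv(samples, path, row.names = FALSE, quote = FALSE)
  manifest <- .writeManifest("grid", config, path, outDir)
  message(sprintf("grid: %d cell samples (%d complete) -> %s",
                  nrow(samples), sum(samples$complete), basename(path)))
  invisible(list(samples = samples, env = env, files = c(path, manifest)))
}

## empirical surface: hsi_emp at fished cells, NA elsewhere
.empiricalSurface <- function(samples, grid, species, year, month) {
  sel <- samples$species == species & samples$year == year & samples$month == month
  vals <- rep(NA_real_, nCells(grid))
  vals[samples$cell[sel]] <- samples$hsi_emp[sel]
  HSISurface(grid, vals, species, "empirical", year, month)
}

#' Model-fitting stage: ssSDM, regional surfaces, icSDM, ic surfaces
#'
#' Enforces the stage order of the workflow: single-species models are fit
#' on the training years, predicted regionally (training layers feed the
#' biotic feature, prediction layers feed the final surfaces), then the
#' interspecific-competition models are fit with the competitor's regional
#' suitability as an added covariate and predicted over the prediction
#' window. Requesting the ic stage alone without existing ss artifacts is
#' an error.
#'
#' @inheritParams runSimulate
#' @param stages Character subset of \code{c("ss", "ic")}, in order.
#' @return Invisibly, models, surfaces and file paths.
#' @export
runFit <- function(config, outDir, force = FALSE, stages = c("ss", "ic")) {
  config <- validateRunConfig(config)
  grid <- .cfgGrid(config)
  samplesPath <- file.path(outDir, "cell_samples.csv")
  if (!file.exists(samplesPath))
    stop("cell_samples.csv not found in ", outDir, "; run the grid stage first")
  samples <- read.csv(samplesPath, stringsAsFactors = FALSE)
  attr(samples, "grid") <- grid
  months <- monthNumber(config$months)
  spA <- config$species$A$name; spB <- config$species$B$name
  ssPaths <- file.path(outDir, sprintf("model_ss_%s", c(spA, spB)))
  if (identical(stages, "ic") && !all(file.exists(paste0(ssPaths, ".rds"))))
    stop("ic stage requested but ss model artifacts are missing; fit ss first")
  train <- samples[samples$year %in% config$train_years & samples$complete, ]
  surfaces <- list(); models <- list()
  if ("ss" %in% stages) {
    for (sp in c(A = spA, B = spB)) {
      spec <- .cfgModelSpec(config, deriveSeed(config$seed, paste0("trees-ss-", sp)))
      models[[paste0("ss_", sp)]] <- fitSSSDM(train[train$species == sp, ], spec)
      saveSDM(models[[paste0("ss_", sp)]],
              file.path(outDir, sprintf("model_ss_%s", sp)))
    }
  } else {
    for (sp in c(spA, spB))
      models[[paste0("ss_", sp)]] <- loadSDM(file.path(outDir, sprintf("model_ss_%s", sp)))
  }
  env <- envFromLong(read.csv(file.path(outDir, "env_long.csv")), grid)
  allYears <- sort(union(config$train_years, config$predict_years))
  regional <- list()
  for (sp in c(spA, spB)) {
    regional[[sp]] <- list()
    for (yr in allYears) for (mo in months) {
      s <- predictRegional(models[[paste0("ss_", sp)]], env, yr, mo)
      regional[[sp]][[sprintf("%d-%02d", yr, mo)]] <- s
    }
  }
  icSurf <- list()
  if ("ic" %in% stages) {
    for (pair in list(c(spA, spB), c(spB, spA))) {
      focal <- pair[1]; other <- pair[2]
      aug <- buildBioticFeature(train[train$species == focal, ], regional[[other]])
      spec <- icModelSpec(.cfgModelSpec(config,
                deriveSeed(config$seed, paste0("trees-ic-", focal))))
      m <- fitICSDM(aug, spec)
      models[[paste0("ic_", focal)]] <- m
      saveSDM(m, file.path(outDir, sprintf("model_ic_%s", focal)))
      icSurf[[focal]] <- list()
      for (yr in config$predict_years) for (mo in months) {
        key <- sprintf("%d-%02d", yr, mo)
        icSurf[[focal]][[key]] <- predictICSDM(m, env, regional[[other]][[key]], yr, mo)
      }
    }
  }
  empir <- list()
  sampHSI <- empiricalHSI(samples)
  for (sp in c(spA, spB))
    for (yr in config$predict_years) for (mo in months)
      empir[[length(empir) + 1L]] <- .empiricalSurface(sampHSI, grid, sp, yr, mo)
  allSurf <- c(unlist(lapply(regional, unname)), unlist(lapply(icSurf, unname)), empir)
  surfPath <- file.path(outDir, "surfaces.csv")
  write.csv(surfaceToLong(allSurf), surfPath, row.names = FALSE, quote = FALSE)
  files <- c(surfPath, list.files(outDir, "^model_.*\\.(rds|json)$", full.names = TRUE))
  manifest <- .writeManifest("fit", config, files, outDir)
  message(sprintf("fit: %d models, %d surfaces -> %s",
                  length(models), length(allSurf), basename(surfPath)))
  invisible(list(models = models, regional = regional, ic = icSurf,
                 files = c(files, manifest)))
}

#' Validation stage: repeated holdout and effort concentration
#'
#' @inheritParams runSimulate
#' @return Invisibly, the per-species \linkS4class{ValidationReport}s.
#' @export
runValidate <- function(config, outDir, force = FALSE) {
  config <- validateRunConfig(config)
  grid <- .cfgGrid(config)
  samples <- read.csv(file.path(outDir, "cell_samples.csv"), stringsAsFactors = FALSE)
  attr(samples, "grid") <- grid
  surf <- surfaceFromLong(read.csv(file.path(outDir, "surfaces.csv"),
                                   stringsAsFactors = FALSE), grid)
  logbook <- readLogbook(file.path(outDir, "logbook.csv"))
  spA <- config$species$A$name; spB <- config$species$B$name
  roleOf <- function(s) surfaceRole(s)
  reports <- list()
  for (pair in list(c(spA, spB), c(spB, spA))) {
    focal <- pair[1]; other <- pair[2]
    reg <- Filter(function(s) speciesName(s) == other && roleOf(s) == "regional_ss", surf)
    train <- samples[samples$species == focal &
                     samples$year %in% config$train_years & samples$complete, ]
    aug <- buildBioticFeature(train, reg)
    ssSpec <- .cfgModelSpec(config, deriveSeed(config$seed, paste0("val-", focal)))
    rep_ <- validateSDMs(aug, ssSpec, icModelSpec(ssSpec),
                         iterations = config$validation$iterations,
                         trainFraction = config$validation$train_fraction,
                         seed = deriveSeed(config$seed, paste0("splits-", focal)))
    eff <- list()
    for (yr in config$predict_years) {
      for (mo in monthNumber(config$months)) {
        ic <- Filter(function(s) speciesName(s) == focal && roleOf(s) == "ic" &&
                       s@year == yr && s@month == mo, surf)
        if (!length(ic)) next
        eb <- effortByCell(logbook, grid, species = focal, year = yr, month = mo)
        if (!nrow(eb)) next
        eff[[length(eff) + 1L]] <- data.frame(
          species = focal, year = yr, month = mo,
          fraction = effortConcentration(ic[[1]], eb),
          top_class_fraction = highEffortTopClass(ic[[1]], eb))
      }
    }
    rep_@effort <- if (length(eff)) do.call(rbind, eff) else data.frame()
    reports[[focal]] <- rep_
    writeValidationReport(rep_, file.path(outDir, sprintf("validation_%s", focal)))
  }
  files <- list.files(outDir, "^validation_.*\\.(json|csv)$", full.names = TRUE)
  manifest <- .writeManifest("validate", config, files, outDir)
  invisible(reports)
}

#' Analysis stage: habitat classes, cohabitation, monthly correlation
#'
#' @inheritParams runSimulate
#' @return Invisibly, class maps, cohabitation surfaces and the
#'   \linkS4class{CorrelationReport}.
#' @export
runAnalyze <- function(config, outDir, force = FALSE) {
  config <- validateRunConfig(config)
  grid <- .cfgGrid(config)
  surf <- surfaceFromLong(read.csv(file.path(outDir, "surfaces.csv"),
                                   stringsAsFactors = FALSE), grid)
  spA <- config$species$A$name; spB <- config$species$B$name
  icA <- Filter(function(s) speciesName(s) == spA && surfaceRole(s) == "ic", surf)
  icB <- Filter(function(s) speciesName(s) == spB && surfaceRole(s) == "ic", surf)
  if (!length(icA) || !length(icB))
    stop("no ic surfaces found in surfaces.csv; run the fit stage first")
  byMonth <- function(x) x[order(vapply(x, function(s) s@month, integer(1)))]
  icA <- byMonth(icA); icB <- byMonth(icB)
  maps <- lapply(c(icA, icB), classifyHSI)
  area <- optimalAreaSeries(maps)
  coh <- mapply(function(a, b) cohabitationSurface(a, b, rule = config$combiner),
                icA, icB, SIMPLIFY = FALSE)
  corr <- monthlyCorrelationReport(icA, icB)
  write.csv(area, file.path(outDir, "optimal_area.csv"), row.names = FALSE, quote = FALSE)
  clsLong <- do.call(rbind, lapply(maps, function(m) {
    cc <- cellCenters(m@grid)
    data.frame(year = m@year, month = m@month, species = m@species,
               lat = cc$lat, lon = cc$lon, class = m@classes)
  }))
  write.csv(clsLong, file.path(outDir, "class_maps.csv"), row.names = FALSE, quote = FALSE)
  write.csv(surfaceToLong(coh), file.path(outDir, "cohabitation.csv"),
            row.names = FALSE, quote = FALSE)
  writeCorrelationReport(corr, file.path(outDir, "correlation"))
  files <- file.path(outDir, c("optimal_area.csv", "class_maps.csv",
                               "cohabitation.csv", "correlation_cross.csv",
                               "correlation_withinA.csv", "correlation_withinB.csv",
                               "correlation.json"))
  manifest <- .writeManifest("analyze", config, files, outDir)
  invisible(list(maps = maps, cohabitation = coh, correlation = corr,
                 area = area, files = c(files, manifest)))
}

#' Run the full workflow: simulate, grid, fit, validate, analyze
#'
#' @inheritParams runSimulate
#' @return Invisibly, a list with each stage's outputs.
#' @export
runPipeline <- function(config, outDir, force = FALSE) {
  sim <- runSimulate(config, outDir, force)
  grd <- runGrid(config, outDir, force)
  fit <- runFit(config, outDir, force)
  val <- runValidate(config, outDir, force)
  ana <- runAnalyze(config, outDir, force)
  invisible(list(simulate = sim, grid = grd, fit = fit,
                 validate = val, analyze = ana))
}
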