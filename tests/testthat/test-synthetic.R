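test_that("generateEnvironment is deterministic, validates input, and builds all covariates", {
  g <- tinyGrid()
  e1 <- generateEnvironment(g, 2020:2021, c("June", "July"), seed = 9)
  e2 <- generateEnvironment(g, 2020:2021, c("June", "July"), seed = 9)
  expect_identical(SummarizedExperiment::assays(e1), SummarizedExperiment::assays(e2))
  e3 <- generateEnvironment(g, 2020:2021, c("June", "July"), seed = 10)
  expect_false(identical(SummarizedExperiment::assay(e1, "T_0m"),
                         SummarizedExperiment::assay(e3, "T_0m")))
  expect_setequal(SummarizedExperiment::assayNames(e1), covariateNames())
  expect_error(generateEnvironment(g, 2020, "Juny", seed = 1), "unknown month")
  expect_error(generateEnvironment(g, 2020, 5, seed = 1), "June..November")
  expect_error(generateEnvironment(g, c(2020, 2020), 6, seed = 1), "duplicate")
})

test_that("temperature decreases with depth on average and SSTA/ONI broadcast as month scalars", {
  g <- GridSpec()
  env <- generateEnvironment(g, 2020, 6:11, seed = 3)
  for (l in 1:6) {
    t0 <- SummarizedExperiment::assay(env, "T_0m")[, l]
    t200 <- SummarizedExperiment::assay(env, "T_200m")[, l]
    # configured lapse 0.045 degC/m -> 9 degC mean contrast, noise sd ~2
    expect_gt(mean(t0) - mean(t200), 0)
    oni <- SummarizedExperiment::assay(env, "ONI")[, l]
    expect_equal(length(unique(oni)), 1L)
    ssta <- SummarizedExperiment::assay(env, "SSTA")[, l]
    expect_equal(length(unique(ssta)), 1L)
  }
})

test_that("EKE is zero for constant currents and latitudinal gradients are present", {
  g <- tinyGrid()
  env <- tinyEnv(g)  # U and V spatially varying
  # hand-build a stack with constant U, V: anomalies vanish
  assays <- SummarizedExperiment::assays(tinyEnv(g))
  assays$U[] <- 0; assays$V[] <- 0
  assays$EKE[] <- 0.5 * ((assays$U - mean(assays$U))^2 +
                         (assays$V - mean(assays$V))^2)
  expect_true(all(assays$EKE == 0))
  # generated stacks satisfy the same identity between U, V and EKE
  env <- generateEnvironment(GridSpec(), 2020, 6, seed = 5)
  u <- SummarizedExperiment::assay(env, "U")[, 1]
  v <- SummarizedExperiment::assay(env, "V")[, 1]
  eke <- SummarizedExperiment::assay(env, "EKE")[, 1]
  expect_equal(eke, 0.5 * ((u - mean(u))^2 + (v - mean(v))^2), tolerance = 1e-12)
  # T_0m cools toward the north
  t0 <- SummarizedExperiment::assay(env, "T_0m")[, 1]
  lat <- SummarizedExperiment::rowData(env)$lat
  expect_lt(mean(t0[lat > 42]), mean(t0[lat < 37]))
})

test_that("base suitability hits 1 at a single-covariate optimum and zero coupling decouples species", {
  g <- tinyGrid()
  env <- tinyEnv(g)
  x <- SummarizedExperiment::assay(env, "T_0m")[1, 1]
  respA <- SpeciesResponse(data.frame(covariate = "T_0m", optimum = x,
                                      width = 1, weight = 1), gamma = 0)
  # optimum everywhere would give 1; at least the optimum cell must
  flat <- SpeciesResponse(data.frame(covariate = "SSTA", optimum = 0.5,
                                     width = 2, weight = 1), gamma = 0)
  # SSTA is constant per layer: set optimum to the layer value -> suit == 1
  oniVal <- 0.3  # tinyEnv holds SSTA constant at 0.3
  atOpt <- SpeciesResponse(data.frame(covariate = "SSTA", optimum = oniVal,
                                      width = 2, weight = 1), gamma = 0)
  tr <- trueSuitability(env, atOpt, respA)
  expect_equal(hsiValues(tr$A[[1]]), rep(1, nCells(g)))
  # with both gammas zero, changing resp_B leaves surface A untouched
  respB2 <- SpeciesResponse(data.frame(covariate = "SSS", optimum = 34,
                                       width = 1, weight = 1), gamma = 0)
  trA1 <- trueSuitability(env, respA, respB2)
  trA2 <- trueSuitability(env, respA, atOpt)
  expect_identical(hsiValues(trA1$A[[1]]), hsiValues(trA2$A[[1]]))
})

test_that("positive coupling raises the cross-species correlation, monotonically in gamma", {
  g <- GridSpec()
  env <- generateEnvironment(g, 2020, 6, seed = 21)
  resp <- defaultResponses()
  rAt <- function(gamma) {
    tr <- trueSuitability(env, resp$A,
                          SpeciesResponse(defaultRunConfig(1)$species$B$curves, gamma))
    cor(hsiValues(tr$A[[1]]), hsiValues(tr$B[[1]]))
  }
  r <- vapply(c(0, 0.4, 0.8), rAt, numeric(1))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})

test_that("coupling errors are explicit: missing covariate and all-zero surfaces", {
  g <- tinyGrid()
  env <- tinyEnv(g)
  bad <- SpeciesResponse(data.frame(covariate = "T_300m", optimum = 5,
                                    width = 1, weight = 1), gamma = 0)
  ok <- SpeciesResponse(data.frame(covariate = "T_0m", optimum = 2,
                                   width = 1, weight = 1), gamma = 0)
  expect_error(trueSuitability(env, bad, ok), "absent from the environment")
  # gamma < -1 can annihilate a surface entirely; must be flagged
  hi <- SpeciesResponse(data.frame(covariate = "SSTA", optimum = 0.5,
                                   width = 10, weight = 1), gamma = 0)
  killer <- SpeciesResponse(data.frame(covariate = "SSTA", optimum = 0.5,
                                       width = 10, weight = 1), gamma = -50)
  expect_error(trueSuitability(tinyEnv(g, oni = 0.5), hi, killer), "all-zero")
})

test_that("sampleLogbook conserves the budget, respects noise-free catch, and concentrates under large k", {
  g <- tinyGrid()
  truth <- constantSurface(0.5, g)
  em <- EffortModel(nVessels = 5L, monthlyBudget = 40, k = 1, q = 1,
                    sigma = 0, floor = 0)
  lb <- sampleLogbook(truth, em, g, seed = 2)
  expect_equal(sum(lb$effort_days), 40)
  expect_equal(lb$catch_t, 0.5 * lb$effort_days)  # sigma 0, q 1, truth 0.5
  expect_true(all(lb$lat >= 34 & lb$lat <= 35 & lb$lon >= 144 & lb$lon <= 145))
  # peaked surface + huge k: all effort lands in the argmax cell
  vals <- rep(0.3, nCells(g)); vals[7] <- 0.9
  peak <- HSISurface(g, vals, "A", "truth", 2020L, 6L)
  em2 <- EffortModel(nVessels = 5L, monthlyBudget = 30, k = 50, q = 1,
                     sigma = 0, floor = 0)
  lb2 <- sampleLogbook(peak, em2, g, seed = 3)
  expect_equal(unique(assignCell(lb2$lat, lb2$lon, g)$cell), 7L)
  expect_error(sampleLogbook(constantSurface(0.1, g),
                             EffortModel(floor = 0.5), g, 1),
               "empty feasible region")
})

test_that("logbooks are seed-reproducible and effort tracks suitability ranks", {
  g <- GridSpec()
  env <- generateEnvironment(g, 2020, 6:11, seed = 77)
  resp <- defaultResponses()
  tr <- trueSuitability(env, resp$A, resp$B)
  em <- EffortModel(monthlyBudget = 600)
  lb1 <- simulateFishery(tr, em, g, seed = 5)
  lb2 <- simulateFishery(tr, em, g, seed = 5)
  expect_identical(lb1, lb2)
  lb3 <- simulateFishery(tr, em, g, seed = 6)
  expect_false(identical(lb1, lb3))
  # Spearman correlation between cell effort and truth is positive (k > 0)
  effB <- effortByCell(lb1, g, species = "B", month = 6)
  truthB <- hsiValues(tr$B[["2020-06"]])[effB$cell]
  expect_gte(nrow(effB), 50)
  expect_gt(cor(effB$effort_days, truthB, method = "spearman"), 0)
})

test_that("logbook records carry the full field set with valid ranges", {
  g <- tinyGrid()
  lb <- sampleLogbook(constantSurface(0.7, g), EffortModel(), g, seed = 11)
  expect_setequal(names(lb), c("date", "lat", "lon", "species", "catch_t",
                               "hauls", "effort_days", "vessel_id",
                               "vessel_length_m"))
  expect_false(anyNA(as.Date(lb$date)))
  expect_true(all(lb$catch_t >= 0))
  expect_true(all(lb$effort_days >= 1))
  expect_true(all(lb$vessel_id >= 1 & lb$vessel_id <= 80))
})
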