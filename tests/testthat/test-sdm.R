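## shared fixture: one generated environment + samples, reused across blocks
sdmFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- GridSpec()
    env <- generateEnvironment(g, 2019:2020, 6:11, seed = 31)
    resp <- defaultResponses()
    tr <- trueSuitability(env, resp$A, resp$B, "A", "B")
    lb <- simulateFishery(tr, EffortModel(monthlyBudget = 250), g, seed = 32)
    cs <- buildCellSamples(lb, env)
    cache <<- list(g = g, env = env, tr = tr, cs = cs)
    cache
  }
})

test_that("fitSSSDM refuses degenerate inputs and honors the constant override", {
  fx <- sdmFixture()
  csA <- fx$cs[fx$cs$species == "A", ]
  expect_error(fitSSSDM(csA[1:10, ], ModelSpec(seed = 1)), "at least 30")
  const <- csA
  const$hsi_emp <- 0.7
  expect_error(fitSSSDM(const, ModelSpec(seed = 1)), "constant response")
  m <- fitSSSDM(const, ModelSpec(ntree = 20, seed = 1), allowConstant = TRUE)
  p <- predictRegional(m, fx$env, 2020, 6)
  expect_equal(unique(stats::na.omit(hsiValues(p))), 0.7)
  bad <- csA
  bad$hsi_emp[1] <- 1.4
  expect_error(fitSSSDM(bad, ModelSpec(seed = 1)), "lie in \\[0, 1\\]")
})

test_that("fits are deterministic under a fixed seed and respond to seed changes", {
  fx <- sdmFixture()
  csA <- fx$cs[fx$cs$species == "A", ]
  m1 <- fitSSSDM(csA, ModelSpec(ntree = 50, seed = 7))
  m2 <- fitSSSDM(csA, ModelSpec(ntree = 50, seed = 7))
  expect_identical(m1@importance, m2@importance)
  s1 <- predictRegional(m1, fx$env, 2020, 7)
  s2 <- predictRegional(m2, fx$env, 2020, 7)
  expect_identical(hsiValues(s1), hsiValues(s2))
  m3 <- fitSSSDM(csA, ModelSpec(ntree = 50, seed = 8))
  expect_false(identical(m1@importance, m3@importance))
})

test_that("a model on a deterministic single-covariate signal recovers it", {
  # response is a step function of T_0m: high suitability below 14 degrees
  fx <- sdmFixture()
  csA <- fx$cs[fx$cs$species == "A" & fx$cs$complete, ]
  csA$hsi_emp <- ifelse(csA$T_0m < 14, 0.9, 0.1)
  n <- nrow(csA)
  idx <- seq_len(floor(0.8 * n))
  m <- fitSSSDM(csA[idx, ], ModelSpec(ntree = 100, seed = 3))
  test <- csA[-idx, ]
  pred <- vapply(seq_len(nrow(test)), function(r) {
    s <- predictRegional(m, fx$env, test$year[r], test$month[r])
    hsiValues(s)[test$cell[r]]
  }, numeric(1))
  expect_gte(holdoutR2(test$hsi_emp, pred), 0.9)
  imp <- sort(m@importance, decreasing = TRUE)
  expect_true(names(imp)[1] %in% c("T_0m", "T_50m", "T_100m", "T_150m", "T_200m"))
})

test_that("regional predictions stay inside the training response range and propagate masks", {
  fx <- sdmFixture()
  csA <- fx$cs[fx$cs$species == "A", ]
  m <- fitSSSDM(csA, ModelSpec(ntree = 50, seed = 7))
  s <- predictRegional(m, fx$env, 2020, 8)
  v <- hsiValues(s)
  expect_false(anyNA(v))
  expect_true(all(v >= m@responseRange[1] - 1e-9 & v <= m@responseRange[2] + 1e-9))
  expect_equal(surfaceRole(s), "regional_ss")
  # masked environment cells yield masked predictions
  mask <- rep(FALSE, nCells(fx$g)); mask[1:10] <- TRUE
  envM <- generateEnvironment(fx$g, 2020, 6, seed = 31, landMask = mask)
  sM <- predictRegional(m, envM, 2020, 6)
  expect_true(all(is.na(hsiValues(sM)[1:10])))
  expect_false(anyNA(hsiValues(sM)[-(1:10)]))
})

test_that("batched regional prediction equals a per-cell loop oracle on a toy grid", {
  fx <- sdmFixture()
  g <- tinyGrid()
  envT <- generateEnvironment(g, 2020, 6, seed = 41)
  m <- fitSSSDM(fx$cs[fx$cs$species == "A", ], ModelSpec(ntree = 30, seed = 7))
  batch <- hsiValues(predictRegional(m, envT, 2020, 6))
  feat <- envLayer(envT, 2020, 6)
  loop <- vapply(seq_len(nCells(g)), function(cell) {
    row <- as.data.frame(feat[cell, , drop = FALSE])
    predict(m@forest, data = row, num.threads = 1)$predictions
  }, numeric(1))
  expect_equal(batch, loop, tolerance = 1e-12)
})

test_that("buildBioticFeature augments, mirrors under swap, and polices roles", {
  fx <- sdmFixture()
  g <- fx$g
  csA <- fx$cs[fx$cs$species == "A", ]
  const <- HSISurface(g, rep(0.4, nCells(g)), "B", "regional_ss", 2019L, 6L)
  one <- csA[csA$year == 2019 & csA$month == 6, ]
  aug <- buildBioticFeature(one, const)
  expect_true(all(aug$hsi_other == 0.4))
  # role guard: an ic surface cannot be injected (circular coupling)
  icS <- HSISurface(g, rep(0.4, nCells(g)), "B", "ic", 2019L, 6L)
  expect_error(buildBioticFeature(one, icS), "regional_ss")
  # missing layer
  expect_error(buildBioticFeature(csA, const), "no regional surface")
  # 3-row toy join equals a hand-built expectation
  vals <- seq(0, 1, length.out = nCells(g))
  sB <- HSISurface(g, vals, "B", "regional_ss", 2019L, 6L)
  toy <- one[1:3, ]
  augT <- buildBioticFeature(toy, sB)
  expect_equal(augT$hsi_other, vals[toy$cell])
  # swapping focal and donor mirrors the construction
  csB <- fx$cs[fx$cs$species == "B" & fx$cs$year == 2019 & fx$cs$month == 6, ]
  sA <- HSISurface(g, vals, "A", "regional_ss", 2019L, 6L)
  augB <- buildBioticFeature(csB, sA)
  expect_equal(augB$hsi_other, vals[csB$cell])
})

test_that("dropping hsi_other from an ic fit reproduces the single-species fit exactly", {
  fx <- sdmFixture()
  csB <- fx$cs[fx$cs$species == "B", ]
  csB$hsi_other <- runif(nrow(csB))
  spec <- ModelSpec(ntree = 40, seed = 9)
  mSS <- fitSSSDM(csB, spec)
  mIC <- fitICSDM(csB, spec)     # same covariates: reduction case
  expect_identical(mSS@importance, mIC@importance)
  expect_equal(mIC@stage, "ic")
  pSS <- predictRegional(mSS, fx$env, 2020, 9)
  feat <- envLayer(fx$env, 2020, 9)
  pIC <- predict(mIC@forest, data = as.data.frame(feat[, spec@covariates]),
                 num.threads = 1)$predictions
  expect_equal(hsiValues(pSS), pIC, tolerance = 1e-12)
})

test_that("biotic covariate importance reflects the generator coupling", {
  # with a strong coupling the competitor surface outranks the median
  # covariate; decoupled it falls low. One seed per case keeps this fast;
  # the acceptance suite covers replication.
  # niches chosen with near-zero baseline habitat correlation (A rides the
  # noise-driven SSH/EKE fields, B the thermal gradient) so that at gamma 0
  # the competitor surface is genuinely uninformative for B
  runCase <- function(gammaB, seed) {
    g <- GridSpec()
    env <- generateEnvironment(g, 2019:2020, 6:11, deriveSeed(seed, "generator"))
    respA <- SpeciesResponse(data.frame(
      covariate = c("SSH", "EKE"), optimum = c(0.5, 0.02),
      width = c(0.08, 0.02), weight = c(1, 1)), 0)
    respB <- SpeciesResponse(data.frame(
      covariate = c("T_50m", "Chl_a"), optimum = c(12.5, 0.8),
      width = c(2.5, 0.6), weight = c(1, 0.5)), gammaB)
    tr <- trueSuitability(env, respA, respB, "A", "B")
    lb <- simulateFishery(tr, EffortModel(), g, deriveSeed(seed, "fishery"))
    cs <- buildCellSamples(lb, env)
    mA <- fitSSSDM(cs[cs$species == "A", ], ModelSpec(ntree = 100, seed = 1))
    cd <- as.data.frame(SummarizedExperiment::colData(env))
    reg <- lapply(seq_len(nrow(cd)),
                  function(l) predictRegional(mA, env, cd$year[l], cd$month[l]))
    aug <- buildBioticFeature(cs[cs$species == "B", ], reg)
    m <- fitICSDM(aug, icModelSpec(ModelSpec(ntree = 100, seed = 2)))
    rank <- rank(m@importance)[["hsi_other"]] / length(m@importance)
    rank
  }
  expect_gt(runCase(0.8, 51), 0.5)   # above the median covariate
  expect_lt(runCase(0, 52), 0.35)
})

test_that("predictICSDM checks roles and layer identity and propagates both masks", {
  fx <- sdmFixture()
  g <- fx$g
  csB <- fx$cs[fx$cs$species == "B", ]
  mA <- fitSSSDM(fx$cs[fx$cs$species == "A", ], ModelSpec(ntree = 30, seed = 7))
  cd <- as.data.frame(SummarizedExperiment::colData(fx$env))
  reg <- lapply(seq_len(nrow(cd)),
                function(l) predictRegional(mA, fx$env, cd$year[l], cd$month[l]))
  aug <- buildBioticFeature(csB, reg)
  mIC <- fitICSDM(aug, icModelSpec(ModelSpec(ntree = 30, seed = 8)))
  sOther <- reg[[which(cd$year == 2020 & cd$month == 6)]]
  sIC <- predictICSDM(mIC, fx$env, sOther, 2020, 6)
  expect_equal(surfaceRole(sIC), "ic")
  expect_true(all(hsiValues(sIC) >= 0 & hsiValues(sIC) <= 1, na.rm = TRUE))
  expect_error(predictICSDM(mIC, fx$env, sOther, 2020, 7), "mismatch")
  expect_error(predictICSDM(mA, fx$env, sOther, 2020, 6), "stage")
  # masked competitor cells yield masked output
  vv <- hsiValues(sOther); vv[5] <- NA
  sHole <- HSISurface(g, vv, "A", "regional_ss", 2020L, 6L)
  sIC2 <- predictICSDM(mIC, fx$env, sHole, 2020, 6)
  expect_true(is.na(hsiValues(sIC2)[5]))
  # constant competitor surface: prediction equals ss-style prediction
  # with one constant column appended
  sConst <- HSISurface(g, rep(0.4, nCells(g)), "A", "regional_ss", 2020L, 6L)
  sIC3 <- predictICSDM(mIC, fx$env, sConst, 2020, 6)
  feat <- cbind(envLayer(fx$env, 2020, 6), hsi_other = 0.4)
  direct <- predict(mIC@forest, data = as.data.frame(feat[, mIC@spec@covariates]),
                    num.threads = 1)$predictions
  expect_equal(hsiValues(sIC3), pmin(pmax(direct, 0), 1), tolerance = 1e-12)
})

test_that("model serialization round-trips with a JSON sidecar", {
  fx <- sdmFixture()
  m <- fitSSSDM(fx$cs[fx$cs$species == "A", ], ModelSpec(ntree = 20, seed = 7))
  stem <- file.path(tempdir(), "sdm-roundtrip")
  side <- saveSDM(m, stem)
  expect_true(file.exists(paste0(stem, ".rds")))
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$ntree, 20L)
  expect_equal(js$stage, "ss")
  m2 <- loadSDM(stem)
  expect_identical(m2@importance, m@importance)
  unlink(paste0(stem, c(".rds", ".json")))
})
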