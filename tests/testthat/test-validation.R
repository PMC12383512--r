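## synthetic samples table with a known signal, no fishery machinery needed
makeSamples <- function(n = 200, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * 13), n, 13, dimnames = list(NULL, covariateNames()))
  y <- pmin(pmax(0.7 * x[, "T_0m"] + 0.15 + rnorm(n, 0, 0.05), 0), 1)
  cbind(data.frame(species = "A", month = 6L, year = 2020L,
                   cell = seq_len(n), hsi_emp = y), as.data.frame(x))
}

test_that("a perfect predictor scores R2 = 1 and the train-mean predictor about 0", {
  s <- makeSamples(300)
  perfect <- repeatedHoldout(s, ModelSpec(seed = 1), iterations = 20, seed = 5,
    fitFunction = function(train, spec, is) train,
    predictFunction = function(obj, test) test$hsi_emp)
  expect_equal(as.numeric(perfect), rep(1, 20))
  meanPred <- repeatedHoldout(s, ModelSpec(seed = 1), iterations = 100, seed = 5,
    fitFunction = function(train, spec, is) mean(train$hsi_emp),
    predictFunction = function(obj, test) rep(obj, nrow(test)))
  expect_true(all(meanPred <= 1))
  # expected R2 of the train-mean predictor is ~ 0 (slightly negative)
  expect_lt(abs(mean(meanPred)), 0.05)
  expect_lt(mean(meanPred), 0.01)
})

test_that("holdout iterations are reproducible from (seed, iteration)", {
  s <- makeSamples(120)
  one <- repeatedHoldout(s, ModelSpec(ntree = 20, seed = 1), iterations = 1, seed = 42)
  two <- repeatedHoldout(s, ModelSpec(ntree = 20, seed = 1), iterations = 1, seed = 42)
  expect_identical(as.numeric(one), as.numeric(two))
  more <- repeatedHoldout(s, ModelSpec(ntree = 20, seed = 1), iterations = 3, seed = 42)
  expect_equal(as.numeric(more)[1], as.numeric(one))  # iteration i depends on (seed, i) only
  expect_error(repeatedHoldout(s, ModelSpec(seed = 1), trainFraction = 1.2),
               "strictly between")
  expect_error(repeatedHoldout(s[1:5, ], ModelSpec(seed = 1)), "at least 10")
})

test_that("degenerate test strata are recorded as NA and counted", {
  s <- makeSamples(40)
  s$hsi_emp <- 0.5   # constant response everywhere -> every split degenerate
  suppressMessages(
    r2 <- repeatedHoldout(s, ModelSpec(ntree = 5, seed = 1), iterations = 8, seed = 2,
      fitFunction = function(train, spec, is) NULL,
      predictFunction = function(obj, test) rep(0.5, nrow(test))))
  expect_true(all(is.na(r2)))
  expect_equal(attr(r2, "na_count"), 8L)
})

test_that("compareModels handles ties, shifts, and pairing the way a signed-rank test should", {
  r2 <- runif(100, 0.2, 0.6)
  tie <- compareModels(r2, r2)
  expect_equal(tie$delta_r2, 0)
  expect_equal(tie$p_value, 1)
  shift <- compareModels(r2, r2 + 0.1)
  expect_equal(shift$delta_r2, 0.1)
  # all 100 differences positive: signed-rank p is far below 1e-4
  expect_lt(shift$p_value, 1e-4)
  expect_equal(shift$stars, "****")
  # shuffling the pairing changes p but not the mean difference
  shuf <- compareModels(r2, sample(r2 + 0.1))
  expect_equal(shuf$delta_r2, 0.1, tolerance = 1e-12)
  expect_error(compareModels(r2, r2[1:50]), "equal length")
})

test_that("significance stars follow the conventional ladder", {
  expect_equal(significanceStars(c(0.5, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
})

test_that("effortConcentration computes filtered effort shares with explicit errors", {
  g <- tinyGrid()
  s <- HSISurface(g, c(0.7, 0.5, rep(0.1, 14)), "A", "ic", 2021L, 6L)
  eff <- data.frame(cell = c(1L, 2L), effort_days = c(30, 10))
  expect_equal(effortConcentration(s, eff), 0.75)
  allHigh <- HSISurface(g, rep(0.9, 16), "A", "ic", 2021L, 6L)
  expect_equal(effortConcentration(allHigh, eff), 1.0)
  expect_error(effortConcentration(s, data.frame(cell = 1L, effort_days = 0)),
               "zero total effort")
  expect_error(effortConcentration(s, data.frame(cell = 1L, effort_days = -1)),
               ">= 0")
})

test_that("effortConcentration equals a brute-force filter-and-sum oracle and is monotone in the threshold", {
  g <- GridSpec(34, 36.5, 144, 145.25, 0.25)   # 10 x 5 = 50 cells
  set.seed(61)
  hsi <- runif(50)
  eff <- data.frame(cell = 1:50, effort_days = rpois(50, 20))
  s <- HSISurface(g, hsi, "A", "ic", 2021L, 6L)
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    # naive loop oracle
    num <- 0; den <- 0
    for (r in 1:50) {
      den <- den + eff$effort_days[r]
      if (hsi[r] >= thr) num <- num + eff$effort_days[r]
    }
    expect_identical(effortConcentration(s, eff, thr), num / den)
  }
  fr <- vapply(seq(0, 1, 0.1), function(t) effortConcentration(s, eff, t), numeric(1))
  expect_true(all(diff(fr) <= 0))   # monotone non-increasing in threshold
})

test_that("effort concentrated as truth^2 beats the areal fraction of optimal cells", {
  g <- GridSpec()
  env <- generateEnvironment(g, 2021, 6, seed = 71)
  resp <- defaultResponses()
  tr <- trueSuitability(env, resp$A, resp$B)
  truth <- tr$B[[1]]
  em <- EffortModel(monthlyBudget = 2000, k = 2, floor = 0, sigma = 0)
  lb <- sampleLogbook(truth, em, g, seed = 72)
  eff <- effortByCell(lb, g)
  conc <- effortConcentration(truth, eff, 0.6)
  areal <- mean(hsiValues(truth) >= 0.6)
  expect_gt(conc, areal)
})

test_that("highEffortTopClass reports the share of high-effort cells in the top occupied class", {
  g <- tinyGrid()
  s <- HSISurface(g, c(0.95, 0.9, 0.7, rep(0.3, 13)), "A", "ic", 2021L, 6L)
  eff <- data.frame(cell = 1:3, effort_days = c(50, 45, 60))
  # top occupied class is 5; cells 1-2 are in it, cell 3 is not
  expect_equal(highEffortTopClass(s, eff, minEffort = 40), 2 / 3)
  expect_true(is.na(suppressMessages(highEffortTopClass(s, eff, minEffort = 100))))
})

test_that("validateSDMs produces a coherent per-month report", {
  set.seed(91)
  n <- 240
  x <- matrix(runif(n * 13), n, 13, dimnames = list(NULL, covariateNames()))
  s <- cbind(data.frame(species = "B", month = rep(6:7, each = n / 2),
                        year = 2020L, cell = seq_len(n),
                        hsi_emp = pmin(pmax(x[, 1] * 0.8 + rnorm(n, 0, 0.1), 0), 1),
                        hsi_other = runif(n)),
             as.data.frame(x))
  rep_ <- validateSDMs(s, ModelSpec(ntree = 15, seed = 1), iterations = 10, seed = 3)
  expect_s4_class(rep_, "ValidationReport")
  expect_equal(nrow(rep_@r2), 20L)             # 2 months x 10 iterations
  expect_equal(sort(unique(rep_@summary$month)), c(6L, 7L))
  expect_true(all(rep_@r2$r2_ss <= 1, na.rm = TRUE))
  expect_error(validateSDMs(s[, setdiff(names(s), "hsi_other")],
                            ModelSpec(seed = 1)), "hsi_other")
})
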