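## per-iteration substream: depends only on (seed, i)
.iterSeed <- function(seed, i) as.integer((as.double(seed) * 10007 + i) %% 2147483647)

#' Repeated 80/20 holdout R-squared
#'
#' Draws \code{iterations} fresh random train/test splits; each iteration
#' fits on the training part and reports \eqn{R^2 = 1 - SSE/SST} on the
#' test part. The split and fit of iteration i are reproducible from
#' (seed, i) alone, so two models evaluated with the same seed on the same
#' rows see identical splits (paired iterations). Iterations whose test
#' stratum has zero response variance are recorded as NA and counted.
#'
#' @param samples Model-ready cell samples (rows flagged incomplete are
#'   dropped).
#' @param spec A \linkS4class{ModelSpec}.
#' @param iterations Number of repetitions (default 100).
#' @param trainFraction Training share in (0,1), default 0.8.
#' @param seed Integer seed.
#' @param fitFunction,predictFunction Optional overrides for the model:
#'   \code{fitFunction(train, spec, iterSeed)} returning an object that
#'   \code{predictFunction(object, test)} turns into predictions. Defaults
#'   fit the package's tree ensemble.
#' @return Numeric vector of length \code{iterations} (attribute
#'   \code{na_count} gives the number of degenerate iterations).
#' @export
repeatedHoldout <- function(samples, spec, iterations = 100L,
                            trainFraction = 0.8, seed = 1L,
                            fitFunction = NULL, predictFunction = NULL) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  if ("complete" %in% names(samples)) samples <- samples[samples$complete, ]
  keep <- stats::complete.cases(samples[, c(spec@covariates, spec@response)])
  samples <- samples[keep, ]
  n <- nrow(samples)
  if (n < 10L) stop("need at least 10 complete rows for holdout validation")
  if (is.null(fitFunction))
    fitFunction <- function(train, spec, iterSeed) {
      s2 <- ModelSpec(spec@covariates, spec@ntree, spec@mtry, spec@minNode,
                      iterSeed, spec@response)
      .fitSDM(train, s2, "ss", minRows = 5L, allowConstant = TRUE)
    }
  if (is.null(predictFunction))
    predictFunction <- function(object, test)
      .predictCells(object, as.matrix(test[, object@spec@covariates, drop = FALSE]))
  r2 <- rep(NA_real_, iterations)
  ntrain <- max(1L, floor(trainFraction * n))
  for (i in seq_len(iterations)) {
    is_ <- .iterSeed(seed, i)
    set.seed(is_)
    idx <- sample.int(n, ntrain)
    train <- samples[idx, ]
    test <- samples[-idx, ]
    yte <- test[[spec@response]]
    if (length(yte) < 2L || stats::sd(yte) == 0) next
    obj <- fitFunction(train, spec, is_)
    r2[i] <- holdoutR2(yte, predictFunction(obj, test))
  }
  nna <- sum(is.na(r2))
  if (nna) message(sprintf("repeatedHoldout: %d of %d iterations degenerate (zero test variance)",
                           nna, iterations))
  structure(r2, na_count = nna)
}

#' Compare paired holdout R-squared vectors of two models
#'
#' Summarizes the gain of the interspecific-competition model over the
#' single-species model across split-matched iterations: mean difference,
#' two-sided paired Wilcoxon signed-rank p-value, and significance stars
#' (\code{****} p < 0.0001, \code{***} < 0.001, \code{**} < 0.01,
#' \code{*} < 0.05). With all differences zero the p-value is defined as 1.
#' The replicate R-squared values share training data across iterations, so
#' the p-value is descriptive, not an independent-sample test.
#'
#' @param r2_ss,r2_ic Equal-length numeric vectors from
#'   \code{\link{repeatedHoldout}} runs sharing one seed.
#' @return List with \code{delta_r2} (mean of ic - ss), \code{p_value},
#'   \code{stars}, \code{n} (complete pairs).
#' @export
compareModels <- function(r2_ss, r2_ic) {
  if (length(r2_ss) != length(r2_ic))
    stop("R2 vectors must have equal length (split-matched iterations)")
  ok <- !is.na(r2_ss) & !is.na(r2_ic)
  d <- r2_ic[ok] - r2_ss[ok]
  if (!length(d)) stop("no complete iteration pairs")
  delta <- mean(d)
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  list(delta_r2 = delta, p_value = p, stars = significanceStars(p),
       n = length(d))
}

#' Paired per-month validation of ssSDM vs icSDM
#'
#' For each month, runs split-matched repeated holdouts for the
#' single-species spec and the biotic-augmented spec on the same rows, and
#' assembles a \linkS4class{ValidationReport}.
#'
#' @param samples Augmented cell samples of the focal species (must carry
#'   \code{hsi_other}).
#' @param ssSpec,icSpec \linkS4class{ModelSpec} for the two stages
#'   (\code{icSpec} defaults to \code{icModelSpec(ssSpec)}).
#' @param months Months to validate; default all present.
#' @param iterations,trainFraction,seed As \code{\link{repeatedHoldout}};
#'   each month uses a substream seed derived from \code{seed} and the
#'   month.
#' @param perMonth Validate within months (default TRUE) or pooled.
#' @return A \linkS4class{ValidationReport}.
#' @export
validateSDMs <- function(samples, ssSpec = ModelSpec(),
                         icSpec = icModelSpec(ssSpec), months = NULL,
                         iterations = 100L, trainFraction = 0.8, seed = 1L,
                         perMonth = TRUE) {
  if (!"hsi_other" %in% names(samples))
    stop("samples lack the biotic feature 'hsi_other'; run buildBioticFeature()")
  if (is.null(months)) months <- sort(unique(samples$month))
  months <- monthNumber(months)
  if (!perMonth) months <- NA_integer_
  r2 <- list(); summ <- list()
  for (mo in months) {
    sub <- if (is.na(mo)) samples else samples[samples$month == mo, ]
    ms <- deriveSeed(seed, paste0("holdout-", mo))
    v_ss <- repeatedHoldout(sub, ssSpec, iterations, trainFraction, ms)
    v_ic <- repeatedHoldout(sub, icSpec, iterations, trainFraction, ms)
    cmp <- compareModels(v_ss, v_ic)
    r2[[length(r2) + 1L]] <- data.frame(month = mo, iteration = seq_len(iterations),
                                        r2_ss = as.numeric(v_ss),
                                        r2_ic = as.numeric(v_ic))
    summ[[length(summ) + 1L]] <- data.frame(
      month = mo, mean_r2_ss = mean(v_ss, na.rm = TRUE),
      mean_r2_ic = mean(v_ic, na.rm = TRUE), delta_r2 = cmp$delta_r2,
      p_value = cmp$p_value, stars = cmp$stars)
  }
  new("ValidationReport", iterations = as.integer(iterations),
      r2 = do.call(rbind, r2), summary = do.call(rbind, summ),
      effort = data.frame())
}

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d holdout iterations per month\n", object@iterations))
  s <- object@summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("  month %2s: R2 ss %.3f -> ic %.3f, delta %.3f (p %.3g %s)\n",
                s$month[r], s$mean_r2_ss[r], s$mean_r2_ic[r], s$delta_r2[r],
                s$p_value[r], s$stars[r]))
  if (nrow(object@effort)) {
    cat("  effort concentration:\n")
    print(object@effort, row.names = FALSE)
  }
})

#' Fraction of fishing effort inside high-suitability habitat
#'
#' \code{effortConcentration}: share of total effort falling in cells whose
#' HSI meets the threshold (default 0.6, the optimal-habitat cutoff).
#' \code{highEffortTopClass}: companion statistic, the share of high-effort
#' cells (default >= 40 days) whose habitat class equals the highest class
#' occupied on the surface.
#'
#' @param surface An \linkS4class{HSISurface} covering the effort cells.
#' @param effortByCell data.frame with columns \code{cell},
#'   \code{effort_days} (nonnegative).
#' @param threshold HSI cutoff, default 0.6.
#' @return Numeric fraction in [0, 1].
#' @export
effortConcentration <- function(surface, effortByCell, threshold = 0.6) {
  stopifnot(all(c("cell", "effort_days") %in% names(effortByCell)))
  if (any(effortByCell$effort_days < 0)) stop("effort must be >= 0")
  tot <- sum(effortByCell$effort_days)
  if (tot <= 0) stop("zero total effort: concentration undefined")
  hsi <- surface@values[effortByCell$cell]
  if (anyNA(hsi)) stop("surface is masked at some effort cells")
  sum(effortByCell$effort_days[hsi >= threshold]) / tot
}

#' @rdname effortConcentration
#' @param minEffort Effort-days cutoff defining high-effort cells
#'   (default 40).
#' @export
highEffortTopClass <- function(surface, effortByCell, minEffort = 40) {
  cls <- classifyHSI(surface)
  top <- max(cls@classes, na.rm = TRUE)
  hi <- effortByCell$cell[effortByCell$effort_days >= minEffort]
  if (!length(hi)) {
    message("no cells reach the high-effort cutoff of ", minEffort, " days")
    return(NA_real_)
  }
  mean(cls@classes[hi] == top, na.rm = TRUE)
}

#' Per-cell effort totals from a logbook
#'
#' @param records Logbook data.frame.
#' @param grid A \linkS4class{GridSpec}.
#' @param species Optional species filter.
#' @param year,month Optional period filter.
#' @return data.frame with columns \code{cell}, \code{effort_days}.
#' @export
effortByCell <- function(records, grid, species = NULL, year = NULL, month = NULL) {
  d <- as.Date(records$date, format = "%Y-%m-%d")
  if (!is.null(species)) {
    keep <- records$species == species
    records <- records[keep, ]; d <- d[keep]
  }
  if (!is.null(year)) {
    keep <- as.integer(format(d, "%Y")) == year
    records <- records[keep, ]; d <- d[keep]
  }
  if (!is.null(month)) {
    keep <- as.integer(format(d, "%m")) == monthNumber(month)
    records <- records[keep, ]
  }
  if (!nrow(records)) return(data.frame(cell = integer(), effort_days = numeric()))
  cell <- assignCell(records$lat, records$lon, grid)$cell
  agg <- stats::aggregate(list(effort_days = records$effort_days),
                          by = list(cell = cell), FUN = sum)
  agg[order(agg$cell), ]
}
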