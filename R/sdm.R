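#' Construct a ModelSpec
#'
#' Defaults follow the study configuration: an ensemble of 1000 regression
#' trees with 4 candidate covariates per split, minimum leaf size 5, and
#' the empirical HSI as response.
#'
#' @param covariates Feature columns; default the 13 environmental
#'   covariates.
#' @param ntree,mtry,minNode,seed Integers (see class docs).
#' @param response Response column name, default \code{"hsi_emp"}.
#' @return A \linkS4class{ModelSpec}.
#' @export
ModelSpec <- function(covariates = covariateNames(), ntree = 1000L, mtry = 4L,
                      minNode = 5L, seed = 1L, response = "hsi_emp") {
  new("ModelSpec", covariates = covariates, ntree = as.integer(ntree),
      mtry = as.integer(mtry), minNode = as.integer(minNode),
      seed = as.integer(seed), response = response)
}

#' @describeIn ModelSpec the same spec with the biotic covariate
#'   \code{hsi_other} appended (mtry unchanged).
#' @param spec A \linkS4class{ModelSpec}.
#' @export
icModelSpec <- function(spec) {
  if ("hsi_other" %in% spec@covariates) return(spec)
  ModelSpec(c(spec@covariates, "hsi_other"), spec@ntree, spec@mtry,
            spec@minNode, spec@seed, spec@response)
}

## shared fitting path for both stages; bagged regression trees with a
## random covariate subspace per split, deterministic under (seed, 1 thread)
.fitSDM <- function(samples, spec, stage, minRows = 30L, allowConstant = FALSE) {
  if ("complete" %in% names(samples)) samples <- samples[samples$complete, ]
  miss <- setdiff(c(spec@covariates, spec@response), names(samples))
  if (length(miss)) stop("samples lack column(s): ", paste(miss, collapse = ", "))
  samples <- samples[stats::complete.cases(samples[, c(spec@covariates, spec@response)]), ]
  if (nrow(samples) < minRows)
    stop(sprintf("need at least %d complete rows, have %d", minRows, nrow(samples)))
  y <- samples[[spec@response]]
  if (min(y) < 0 || max(y) > 1) stop("response must lie in [0, 1]")
  if (!allowConstant && stats::sd(y) == 0)
    stop("constant response: the model cannot be fit (override with allowConstant = TRUE)")
  x <- samples[, spec@covariates, drop = FALSE]
  fit <- ranger::ranger(x = x, y = y, num.trees = spec@ntree, mtry = spec@mtry,
                        min.node.size = spec@minNode, seed = spec@seed,
                        num.threads = 1, importance = "impurity",
                        oob.error = TRUE)
  sp <- unique(samples$species)
  new("FittedSDM", forest = fit, spec = spec,
      species = if (length(sp) == 1L) sp else "mixed",
      stage = stage, responseRange = range(y),
      importance = fit$variable.importance,
      oobR2 = fit$r.squared,
      years = sort(unique(as.integer(samples$year))),
      months = sort(unique(as.integer(samples$month))))
}

#' Fit a single-species suitability model (ssSDM)
#'
#' Bagged regression-tree ensemble on the environmental covariates, grown
#' on bootstrap resamples with \code{mtry} candidate covariates per split;
#' deterministic under a fixed seed. Rows flagged incomplete are excluded.
#'
#' @param samples Model-ready cell samples for one species (see
#'   \code{\link{buildCellSamples}}).
#' @param spec A \linkS4class{ModelSpec}.
#' @param minRows Minimum complete rows required (default 30).
#' @param allowConstant Permit a constant response (degenerate override);
#'   default FALSE.
#' @return A \linkS4class{FittedSDM} with stage \code{"ss"}.
#' @export
fitSSSDM <- function(samples, spec = ModelSpec(), minRows = 30L,
                     allowConstant = FALSE) {
  .fitSDM(samples, spec, "ss", minRows, allowConstant)
}

#' Fit an interspecific-competition model (icSDM)
#'
#' Identical estimator to \code{\link{fitSSSDM}} but intended for samples
#' augmented with the competitor's predicted regional suitability
#' (column \code{hsi_other}; see \code{\link{buildBioticFeature}}) and a
#' spec listing it (\code{\link{icModelSpec}}). \code{mtry} is left at its
#' single-species value. Dropping \code{hsi_other} from the spec reduces
#' the fit to the single-species model exactly.
#'
#' @inheritParams fitSSSDM
#' @return A \linkS4class{FittedSDM} with stage \code{"ic"}.
#' @export
fitICSDM <- function(samples, spec, minRows = 30L, allowConstant = FALSE) {
  .fitSDM(samples, spec, "ic", minRows, allowConstant)
}

## newdata -> per-cell predictions for unmasked rows of a feature matrix
.predictCells <- function(model, feat) {
  ok <- stats::complete.cases(feat)
  vals <- rep(NA_real_, nrow(feat))
  if (any(ok)) {
    p <- predict(model@forest, data = as.data.frame(feat[ok, , drop = FALSE]),
                 num.threads = 1)$predictions
    vals[ok] <- .clip01(p)  # tree means of a [0,1] response; clip is a guard
  }
  vals
}

#' Predict a regional suitability surface from a single-species model
#'
#' Evaluates the fitted model at every unmasked grid cell of one
#' (year, month) environment layer; masked cells propagate missing.
#'
#' @param model A \linkS4class{FittedSDM} (stage \code{"ss"}).
#' @param env An \linkS4class{EnvStack} covering the model covariates.
#' @param year,month Layer to predict.
#' @return An \linkS4class{HSISurface} with role \code{"regional_ss"}.
#' @export
predictRegional <- function(model, env, year, month) {
  month <- monthNumber(month)
  feat <- envLayer(env, year, month)
  miss <- setdiff(model@spec@covariates, colnames(feat))
  if (length(miss)) stop("environment lacks model covariate(s): ",
                         paste(miss, collapse = ", "))
  vals <- .predictCells(model, feat[, model@spec@covariates, drop = FALSE])
  HSISurface(gridSpec(env), vals, model@species, "regional_ss", year, month)
}

#' Augment one species' samples with the competitor's predicted suitability
#'
#' Adds a column \code{hsi_other}: species B's regional single-species
#' prediction looked up at species A's (cell, year, month). Only surfaces
#' with role \code{"regional_ss"} are accepted, which prevents accidental
#' circular ic-to-ic coupling. Rows over masked surface cells are flagged
#' incomplete.
#'
#' @param samples Cell samples of the focal species.
#' @param surfaces A single \linkS4class{HSISurface} or a list of them
#'   (role \code{"regional_ss"}), jointly covering every sample layer.
#' @return \code{samples} with \code{hsi_other} appended and
#'   \code{complete} updated.
#' @export
buildBioticFeature <- function(samples, surfaces) {
  if (is(surfaces, "HSISurface")) surfaces <- list(surfaces)
  for (s in surfaces)
    if (surfaceRole(s) != "regional_ss")
      stop("biotic surfaces must have role 'regional_ss', got '", surfaceRole(s), "'")
  key <- vapply(surfaces, function(s) sprintf("%d-%02d", s@year, s@month), "")
  names(surfaces) <- key
  want <- sprintf("%d-%02d", samples$year, samples$month)
  missing_layers <- setdiff(unique(want), key)
  if (length(missing_layers))
    stop("no regional surface for layer(s): ", paste(missing_layers, collapse = ", "))
  samples$hsi_other <- vapply(seq_len(nrow(samples)), function(r)
    surfaces[[want[r]]]@values[samples$cell[r]], numeric(1))
  if ("complete" %in% names(samples))
    samples$complete <- samples$complete & !is.na(samples$hsi_other)
  samples
}

#' Predict an interspecific-competition suitability surface
#'
#' Per-cell prediction from the environment covariates plus the
#' competitor's regional surface; missing wherever either source is
#' masked.
#'
#' @param model A \linkS4class{FittedSDM} with stage \code{"ic"}.
#' @param env An \linkS4class{EnvStack}.
#' @param surfaceOther Competitor's \linkS4class{HSISurface}, role
#'   \code{"regional_ss"}, same (year, month).
#' @param year,month Layer to predict.
#' @return An \linkS4class{HSISurface} with role \code{"ic"}.
#' @export
predictICSDM <- function(model, env, surfaceOther, year, month) {
  month <- monthNumber(month)
  if (model@stage != "ic") stop("model stage must be 'ic'")
  if (surfaceRole(surfaceOther) != "regional_ss")
    stop("surfaceOther must have role 'regional_ss'")
  if (surfaceOther@year != year || surfaceOther@month != month)
    stop(sprintf("(year, month) mismatch: surface is %d-%02d, requested %d-%02d",
                 surfaceOther@year, surfaceOther@month, year, month))
  feat <- envLayer(env, year, month)
  feat <- cbind(feat, hsi_other = surfaceOther@values)
  miss <- setdiff(model@spec@covariates, colnames(feat))
  if (length(miss)) stop("inputs lack model covariate(s): ",
                         paste(miss, collapse = ", "))
  vals <- .predictCells(model, feat[, model@spec@covariates, drop = FALSE])
  HSISurface(gridSpec(env), vals, model@species, "ic", year, month)
}

setMethod("show", "FittedSDM", function(object) {
  cat(sprintf("FittedSDM '%s' stage=%s: %d trees, mtry %d, %d covariates; OOB R2 %.3f\n",
              object@species, object@stage, object@spec@ntree, object@spec@mtry,
              length(object@spec@covariates), object@oobR2))
  cat("  training window:", paste(object@years, collapse = ","),
      "months", paste(object@months, collapse = ","), "\n")
})

#' Serialize a fitted model with a JSON provenance sidecar
#'
#' Writes the model to \code{<path>.rds} and a JSON sidecar
#' \code{<path>.json} recording spec, seed, covariates and training window.
#'
#' @param model A \linkS4class{FittedSDM}.
#' @param path Output path stem (no extension).
#' @return Invisibly, the sidecar list.
#' @export
saveSDM <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  sidecar <- list(format_version = 1L, species = model@species,
                  stage = model@stage,
                  covariates = model@spec@covariates,
                  ntree = model@spec@ntree, mtry = model@spec@mtry,
                  minNode = model@spec@minNode, seed = model@spec@seed,
                  response = model@spec@response,
                  years = model@years, months = model@months,
                  oob_r2 = round(model@oobR2, 6))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' @rdname saveSDM
#' @export
loadSDM <- function(path) readRDS(paste0(path, ".rds"))

#' Partial-response curve of a fitted model
#'
#' Classic partial dependence: the model's mean prediction over the
#' background rows with one covariate forced to each value of a grid.
#' Useful for checking that a fitted model recovers a known unimodal
#' response (the curve's peak should sit near the species' optimum).
#'
#' @param model A \linkS4class{FittedSDM}.
#' @param samples Background rows (typically the training table).
#' @param covariate Covariate name.
#' @param values Grid of covariate values; default 50 points over the
#'   background range.
#' @return data.frame with columns \code{value}, \code{response}.
#' @export
partialDependence <- function(model, samples, covariate, values = NULL) {
  if (!covariate %in% model@spec@covariates)
    stop("'", covariate, "' is not a model covariate")
  if ("complete" %in% names(samples)) samples <- samples[samples$complete, ]
  bg <- samples[stats::complete.cases(samples[, model@spec@covariates, drop = FALSE]),
                model@spec@covariates, drop = FALSE]
  if (is.null(values))
    values <- seq(min(bg[[covariate]]), max(bg[[covariate]]), length.out = 50)
  resp <- vapply(values, function(v) {
    bg[[covariate]] <- v
    mean(predict(model@forest, data = bg, num.threads = 1)$predictions)
  }, numeric(1))
  data.frame(value = values, response = resp)
}
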