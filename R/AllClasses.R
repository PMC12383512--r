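#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor cor.test median predict quantile rbinom rlnorm rmultinom
#'   rnorm runif sd setNames wilcox.test rpois complete.cases
#' @importFrom utils head read.csv write.csv
NULL

## Fixed covariate vocabulary: five temperature depths, surface fields,
## currents, eddy kinetic energy, and two basin-scale monthly climate scalars.
.COVARIATES <- c("T_0m", "T_50m", "T_100m", "T_150m", "T_200m",
                 "SSH", "SSS", "Chl_a", "U", "V", "EKE", "SSTA", "ONI")

.ROLES <- c("truth", "empirical", "regional_ss", "ic", "cohabitation")

.MONTH_NAMES <- c(June = 6L, July = 7L, August = 8L, September = 9L,
                  October = 10L, November = 11L)

#' Names of the thirteen environmental covariates
#'
#' Temperature at 0/50/100/150/200 m, sea surface height (SSH), salinity
#' (SSS), chlorophyll-a, zonal and meridional current components (U, V),
#' eddy kinetic energy (EKE), and the two basin-scale monthly scalars SSTA
#' and ONI.
#'
#' @return Character vector of length 13.
#' @export
covariateNames <- function() .COVARIATES

#' GridSpec: a regular latitude/longitude lattice
#'
#' Describes the analysis lattice: bounds in decimal degrees and a cell
#' resolution that must divide both spans exactly (to a 1e-9 tolerance).
#' Cells are half-open \code{[low, high)} in both axes, indexed 0-based from
#' the south-west corner; points on the top/right boundary belong to the
#' last cell.
#'
#' @slot latMin,latMax,lonMin,lonMax Numeric bounds, decimal degrees.
#' @slot res Numeric cell size in degrees (default 0.25).
#' @export
setClass("GridSpec",
  representation(latMin = "numeric", latMax = "numeric",
                 lonMin = "numeric", lonMax = "numeric", res = "numeric"),
  prototype(latMin = 34, latMax = 45, lonMin = 144, lonMax = 163, res = 0.25))

setValidity("GridSpec", function(object) {
  msg <- character()
  for (s in c("latMin", "latMax", "lonMin", "lonMax", "res"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(msg)) return(msg)
  if (object@res <= 0) msg <- c(msg, "'res' must be > 0")
  if (object@latMax <= object@latMin) msg <- c(msg, "latMax must exceed latMin")
  if (object@lonMax <= object@lonMin) msg <- c(msg, "lonMax must exceed lonMin")
  if (length(msg)) return(msg)
  for (span in c(object@latMax - object@latMin, object@lonMax - object@lonMin)) {
    k <- span / object@res
    if (abs(k - round(k)) > 1e-9)
      msg <- c(msg, "grid span must be an integer multiple of 'res' (tol 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' EnvStack: gridded monthly environmental covariates
#'
#' A \linkS4class{SummarizedExperiment} whose rows are grid cells and whose
#' columns are (year, month) layers; each of the thirteen covariates is one
#' assay (cells x layers matrix). \code{rowData} carries the 0-based cell
#' indices \code{i}, \code{j}, cell-centre \code{lat}/\code{lon} and the
#' land \code{mask}; \code{colData} carries \code{year} and \code{month};
#' the \linkS4class{GridSpec} lives in \code{metadata(x)$grid}.
#'
#' @export
setClass("EnvStack", contains = "SummarizedExperiment")

setValidity("EnvStack", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!identical(sort(an), sort(.COVARIATES)))
    msg <- c(msg, "assays must be exactly the 13 named covariates")
  if (!all(c("i", "j", "lat", "lon", "mask") %in%
           colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData must carry i, j, lat, lon, mask")
  if (!all(c("year", "month") %in%
           colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must carry year, month")
  g <- S4Vectors::metadata(object)$grid
  if (!is(g, "GridSpec")) {
    msg <- c(msg, "metadata(x)$grid must be a GridSpec")
  } else if (nrow(object) != nCells(g)) {
    msg <- c(msg, "row count must equal the number of grid cells")
  }
  if (length(msg)) msg else TRUE
})

#' HSISurface: a per-cell habitat suitability field
#'
#' One suitability value in [0,1] per grid cell (NA where masked) for one
#' species, month and year, tagged with the surface's role in the workflow:
#' \code{"truth"} (generator ground truth), \code{"empirical"} (normalized
#' CPUE at fished cells), \code{"regional_ss"} (single-species model
#' predicted over the whole region), \code{"ic"} (interspecific-competition
#' model prediction) or \code{"cohabitation"} (combined two-species
#' surface).
#'
#' @slot grid A \linkS4class{GridSpec}.
#' @slot values Numeric vector, one value per cell; NA marks masked cells.
#' @slot species,role Character scalars.
#' @slot year,month Integer scalars.
#' @export
setClass("HSISurface",
  representation(grid = "GridSpec", values = "numeric", species = "character",
                 role = "character", year = "integer", month = "integer"))

setValidity("HSISurface", function(object) {
  msg <- character()
  if (length(object@values) != nCells(object@grid))
    msg <- c(msg, "values length must equal the number of grid cells")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    msg <- c(msg, "unmasked suitability values must lie in [0, 1]")
  if (!object@role %in% .ROLES)
    msg <- c(msg, sprintf("role must be one of: %s", paste(.ROLES, collapse = ", ")))
  if (length(object@month) != 1L || !object@month %in% 1:12)
    msg <- c(msg, "month must be a single integer in 1..12")
  if (length(msg)) msg else TRUE
})

#' SpeciesResponse: a species' environmental niche and coupling
#'
#' Unimodal (Gaussian) response curves per covariate plus a signed coupling
#' coefficient gamma linking this species' suitability to the other
#' species' suitability. Base suitability is the weight-normalized
#' geometric mean of the per-covariate responses.
#'
#' @slot curves data.frame with columns \code{covariate}, \code{optimum},
#'   \code{width}, \code{weight}; widths > 0, weights >= 0, at least one
#'   weight > 0.
#' @slot gamma Finite numeric scalar; 0 means no interspecific coupling.
#' @export
setClass("SpeciesResponse",
  representation(curves = "data.frame", gamma = "numeric"))

setValidity("SpeciesResponse", function(object) {
  msg <- character()
  cv <- object@curves
  need <- c("covariate", "optimum", "width", "weight")
  if (!all(need %in% names(cv)))
    return("curves needs columns covariate, optimum, width, weight")
  if (nrow(cv) == 0L) msg <- c(msg, "at least one response curve required")
  if (any(cv$width <= 0)) msg <- c(msg, "tolerance widths must be > 0")
  if (any(cv$weight < 0)) msg <- c(msg, "weights must be >= 0")
  if (nrow(cv) && !any(cv$weight > 0)) msg <- c(msg, "at least one weight must be > 0")
  if (length(object@gamma) != 1L || !is.finite(object@gamma))
    msg <- c(msg, "gamma must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' EffortModel: the fishery observation process
#'
#' Controls how simulated fishing effort is allocated over the suitability
#' surface and how catches are generated: expected cell effort is
#' proportional to suitability^k above a detection floor, the monthly
#' effort budget (vessel-days) is integerized by a multinomial draw, and
#' catch per record is q x effort x suitability x lognormal noise.
#'
#' @slot nVessels Integer number of vessels in the fleet.
#' @slot monthlyBudget Total effort days allocated per month (> 0).
#' @slot k Concentration exponent (>= 0); larger values concentrate effort.
#' @slot q Catchability, tons per day at suitability 1 (> 0).
#' @slot sigma Lognormal catch-noise dispersion (>= 0).
#' @slot floor Minimum suitability a cell needs to be fished.
#' @slot haulRate Hauls per effort day (format fidelity only).
#' @export
setClass("EffortModel",
  representation(nVessels = "integer", monthlyBudget = "numeric", k = "numeric",
                 q = "numeric", sigma = "numeric", floor = "numeric",
                 haulRate = "numeric"))

setValidity("EffortModel", function(object) {
  msg <- character()
  if (object@nVessels < 1L) msg <- c(msg, "nVessels must be >= 1")
  if (object@monthlyBudget <= 0) msg <- c(msg, "monthlyBudget must be > 0")
  if (object@k < 0) msg <- c(msg, "k must be >= 0")
  if (object@q <= 0) msg <- c(msg, "q must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@floor < 0 || object@floor >= 1) msg <- c(msg, "floor must lie in [0, 1)")
  if (object@haulRate <= 0) msg <- c(msg, "haulRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: configuration of one suitability model
#'
#' @slot covariates Character vector of feature columns used by the model.
#' @slot ntree Number of trees in the ensemble (default 1000).
#' @slot mtry Candidate covariates tried per split (default 4).
#' @slot minNode Minimum leaf size (default 5).
#' @slot seed Integer seed making the fit deterministic.
#' @slot response Name of the response column (default \code{"hsi_emp"}).
#' @export
setClass("ModelSpec",
  representation(covariates = "character", ntree = "integer", mtry = "integer",
                 minNode = "integer", seed = "integer", response = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (length(object@covariates) < 1L) msg <- c(msg, "at least one covariate required")
  if (object@ntree < 1L) msg <- c(msg, "ntree must be >= 1")
  if (object@mtry < 1L || object@mtry > length(object@covariates))
    msg <- c(msg, "mtry must lie in 1..length(covariates)")
  if (object@minNode < 1L) msg <- c(msg, "minNode must be >= 1")
  if (length(msg)) msg else TRUE
})

#' FittedSDM: a trained suitability model
#'
#' Wraps the trained tree ensemble together with its configuration and
#' provenance: species, stage (\code{"ss"} single-species or \code{"ic"}
#' interspecific-competition), the training window, the training-response
#' range (tree-mean predictions are bounded by it) and impurity importance
#' scores.
#'
#' @slot forest The trained ensemble (a \code{ranger} object).
#' @slot spec The \linkS4class{ModelSpec} used.
#' @slot species,stage Character scalars.
#' @slot responseRange Numeric length-2: range of the training response.
#' @slot importance Named non-negative numeric importance scores.
#' @slot oobR2 Out-of-bag R-squared of the fit.
#' @slot years,months Integer vectors: the training window.
#' @export
setClass("FittedSDM",
  representation(forest = "ANY", spec = "ModelSpec", species = "character",
                 stage = "character", responseRange = "numeric",
                 importance = "numeric", oobR2 = "numeric",
                 years = "integer", months = "integer"))

setValidity("FittedSDM", function(object) {
  msg <- character()
  if (!object@stage %in% c("ss", "ic")) msg <- c(msg, "stage must be 'ss' or 'ic'")
  if (length(object@responseRange) != 2L)
    msg <- c(msg, "responseRange must have length 2")
  if (any(object@importance < 0)) msg <- c(msg, "importance scores must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ValidationReport: repeated-holdout comparison of ssSDM vs icSDM
#'
#' @slot iterations Number of 80/20 holdout repetitions per month.
#' @slot r2 Long data.frame: month, iteration, r2_ss, r2_ic (NA where a test
#'   stratum had zero response variance).
#' @slot summary Per-month data.frame: mean R2 of each model, mean delta R2,
#'   paired Wilcoxon p-value and significance stars.
#' @slot effort Per-species effort-concentration statistics (may be empty).
#' @export
setClass("ValidationReport",
  representation(iterations = "integer", r2 = "data.frame",
                 summary = "data.frame", effort = "data.frame"))

setValidity("ValidationReport", function(object) {
  msg <- character()
  if (!all(c("month", "iteration", "r2_ss", "r2_ic") %in% names(object@r2)))
    msg <- c(msg, "r2 needs columns month, iteration, r2_ss, r2_ic")
  r2v <- c(object@r2$r2_ss, object@r2$r2_ic)
  if (any(r2v > 1 + 1e-12, na.rm = TRUE)) msg <- c(msg, "R2 cannot exceed 1")
  if (nrow(object@effort)) {
    fr <- object@effort$fraction
    if (any(fr < 0 | fr > 1, na.rm = TRUE))
      msg <- c(msg, "effort fractions must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HabitatClassMap: five-class partition of a suitability surface
#'
#' Classes use the fixed boundaries 0, 0.2, 0.4, 0.6, 0.8, 1: every bin is
#' half-open except the last, which is closed at 1. Cells with HSI >= 0.6
#' (classes 4-5) form the optimal-habitat mask.
#'
#' @slot grid A \linkS4class{GridSpec}.
#' @slot classes Integer vector, one class 1..5 per cell, NA where masked.
#' @slot counts Integer length-5 cell counts per class.
#' @slot optimalMask Logical per-cell mask of HSI >= 0.6.
#' @slot species,role Character provenance tags.
#' @slot year,month Integer provenance tags.
#' @export
setClass("HabitatClassMap",
  representation(grid = "GridSpec", classes = "integer", counts = "integer",
                 optimalMask = "logical", species = "character",
                 role = "character", year = "integer", month = "integer"))

setValidity("HabitatClassMap", function(object) {
  msg <- character()
  if (length(object@classes) != nCells(object@grid))
    msg <- c(msg, "classes length must equal the number of grid cells")
  cl <- object@classes[!is.na(object@classes)]
  if (length(cl) && (min(cl) < 1L || max(cl) > 5L))
    msg <- c(msg, "classes must lie in 1..5")
  if (length(object@counts) != 5L) msg <- c(msg, "counts must have length 5")
  if (sum(object@counts) != sum(!is.na(object@classes)))
    msg <- c(msg, "class counts must sum to the number of unmasked cells")
  if (length(msg)) msg else TRUE
})

#' CorrelationReport: monthly habitat-correlation structure
#'
#' @slot months Integer months covered (June-November).
#' @slot cross data.frame month, r, p, n: cross-species Pearson correlation.
#' @slot withinA,withinB Month-by-month Pearson matrices within each species.
#' @slot speciesA,speciesB Character species tags.
#' @export
setClass("CorrelationReport",
  representation(months = "integer", cross = "data.frame",
                 withinA = "matrix", withinB = "matrix",
                 speciesA = "character", speciesB = "character"))

setValidity("CorrelationReport", function(object) {
  msg <- character()
  rr <- object@cross$r
  if (any(abs(rr) > 1 + 1e-12, na.rm = TRUE)) msg <- c(msg, "r must lie in [-1, 1]")
  for (nm in c("withinA", "withinB")) {
    m <- slot(object, nm)
    if (nrow(m) && !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      msg <- c(msg, sprintf("%s must be symmetric", nm))
    if (nrow(m) && any(abs(diag(m)[!is.na(diag(m))] - 1) > 1e-8))
      msg <- c(msg, sprintf("%s must have unit diagonal", nm))
  }
  if (length(msg)) msg else TRUE
})
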