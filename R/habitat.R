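.CLASS_BREAKS <- c(0, 0.2, 0.4, 0.6, 0.8, 1)

#' Classify a suitability surface into the five habitat classes
#'
#' Fixed boundaries 0, 0.2, 0.4, 0.6, 0.8, 1; every bin is half-open
#' \code{[a, b)} except the last, which is closed (\code{0.8 <= HSI <= 1}).
#' Cells with HSI >= 0.6 (classes 4 and 5) form the optimal-habitat mask.
#'
#' @param surface An \linkS4class{HSISurface} with values in [0, 1].
#' @return A \linkS4class{HabitatClassMap}.
#' @examples
#' g <- GridSpec(34, 34.5, 144, 144.5, 0.25)
#' s <- HSISurface(g, c(0.1, 0.6, 0.8, 1.0), "A", "truth", 2021L, 6L)
#' classifyHSI(s)@classes   # 1 4 5 5
#' @export
classifyHSI <- function(surface) {
  v <- surface@values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("surface values outside [0, 1]; upstream must guarantee the range")
  cls <- rep(NA_integer_, length(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], .CLASS_BREAKS[-c(1, 6)]) + 1L  # 1.0 joins class 5
  counts <- tabulate(cls, nbins = 5L)
  new("HabitatClassMap", grid = surface@grid, classes = cls,
      counts = as.integer(counts), optimalMask = !is.na(cls) & cls >= 4L,
      species = surface@species, role = surface@role,
      year = surface@year, month = surface@month)
}

setMethod("show", "HabitatClassMap", function(object) {
  cat(sprintf("HabitatClassMap '%s' (%s) %d-%02d: counts %s; optimal cells %d\n",
              object@species, object@role, object@year, object@month,
              paste(object@counts, collapse = "/"), sum(object@optimalMask)))
})

#' Combine two species' surfaces into a cohabitation surface
#'
#' Cellwise combination of the two interspecific-competition surfaces into
#' a jointly-favorable habitat field. Default rule is the geometric mean
#' (symmetric, [0,1]-preserving, zero iff either species finds the cell
#' unsuitable); \code{"min"} and \code{"product"} are alternatives, ordered
#' \code{product <= min <= geometric_mean} cellwise. The mask of the result
#' is the union of the input masks; the rule used is recorded in the
#' species tag.
#'
#' @param surfA,surfB \linkS4class{HSISurface} objects of role \code{"ic"}
#'   on the same grid, (year, month).
#' @param rule \code{"geometric_mean"} (default), \code{"min"} or
#'   \code{"product"}.
#' @return An \linkS4class{HSISurface} with role \code{"cohabitation"}.
#' @export
cohabitationSurface <- function(surfA, surfB,
                                rule = c("geometric_mean", "min", "product")) {
  rule <- match.arg(rule)
  for (s in list(surfA, surfB))
    if (!surfaceRole(s) %in% c("ic", "truth", "regional_ss"))
      stop("cohabitation expects model surfaces (role 'ic'), got '",
           surfaceRole(s), "'")
  if (surfaceRole(surfA) != surfaceRole(surfB))
    stop("role mismatch between the two surfaces")
  if (!.sameGrid(surfA@grid, surfB@grid) || surfA@year != surfB@year ||
      surfA@month != surfB@month)
    stop("surfaces must share grid, year and month")
  a <- surfA@values; b <- surfB@values
  v <- switch(rule,
              geometric_mean = sqrt(a * b),
              min = pmin(a, b),
              product = a * b)
  v[is.na(a) | is.na(b)] <- NA_real_
  out <- HSISurface(surfA@grid, v,
                    sprintf("%s+%s[%s]", surfA@species, surfB@species, rule),
                    "cohabitation", surfA@year, surfA@month)
  out
}

#' Pearson correlation between two suitability surfaces
#'
#' Computed over jointly unmasked cells only (pairwise-complete, no
#' imputation), with the two-sided p-value from the t transform.
#'
#' @param surfX,surfY \linkS4class{HSISurface} objects on the same grid.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
correlateSurfaces <- function(surfX, surfY) {
  if (!.sameGrid(surfX@grid, surfY@grid)) stop("surfaces are on different grids")
  ok <- !is.na(surfX@values) & !is.na(surfY@values)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 jointly unmasked cells")
  x <- surfX@values[ok]; y <- surfY@values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a surface: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Monthly correlation structure of two species' habitat surfaces
#'
#' Cross-species Pearson r per month, plus the within-species
#' month-by-month correlation matrices (symmetric, unit diagonal). Months
#' present in only one species are reported as missing, never imputed. The
#' month with the highest cross-species correlation is flagged in the
#' report.
#'
#' @param surfacesA,surfacesB Lists of \linkS4class{HSISurface}, one per
#'   month, same species within a list.
#' @return A \linkS4class{CorrelationReport}.
#' @export
monthlyCorrelationReport <- function(surfacesA, surfacesB) {
  monthsA <- vapply(surfacesA, function(s) s@month, integer(1))
  monthsB <- vapply(surfacesB, function(s) s@month, integer(1))
  months <- sort(union(monthsA, monthsB))
  cross <- data.frame(month = months, r = NA_real_, p = NA_real_, n = NA_integer_)
  for (k in seq_along(months)) {
    ia <- match(months[k], monthsA); ib <- match(months[k], monthsB)
    if (is.na(ia) || is.na(ib)) next
    cs <- correlateSurfaces(surfacesA[[ia]], surfacesB[[ib]])
    cross$r[k] <- cs$r; cross$p[k] <- cs$p; cross$n[k] <- cs$n
  }
  within <- function(surfs, mos) {
    m <- matrix(NA_real_, length(months), length(months),
                dimnames = list(months, months))
    for (a in seq_along(months)) for (b in seq_len(a)) {
      ia <- match(months[a], mos); ib <- match(months[b], mos)
      if (is.na(ia) || is.na(ib)) next
      m[a, b] <- m[b, a] <- if (a == b) 1 else
        correlateSurfaces(surfs[[ia]], surfs[[ib]])$r
    }
    m
  }
  new("CorrelationReport", months = as.integer(months), cross = cross,
      withinA = within(surfacesA, monthsA), withinB = within(surfacesB, monthsB),
      speciesA = surfacesA[[1]]@species, speciesB = surfacesB[[1]]@species)
}

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport: %s vs %s\n", object@speciesA, object@speciesB))
  cr <- object@cross
  best <- cr$month[which.max(cr$r)]
  for (k in seq_len(nrow(cr)))
    cat(sprintf("  month %2d: r = %s (p %s, n %s)%s\n", cr$month[k],
                formatC(cr$r[k], digits = 3, format = "f"),
                formatC(cr$p[k], digits = 2, format = "g"), cr$n[k],
                if (identical(cr$month[k], best)) "  <- highest" else ""))
})

#' Optimal-habitat area per month
#'
#' For each class map: count of optimal (class 4-5) cells, their fraction
#' of unmasked area, and the latitude/longitude bounding box of the
#' optimal mask.
#'
#' @param classMaps List of \linkS4class{HabitatClassMap} sharing a grid.
#' @return data.frame with one row per map: \code{year, month, species,
#'   optimal_cells, unmasked_cells, optimal_fraction, lat_min, lat_max,
#'   lon_min, lon_max}.
#' @export
optimalAreaSeries <- function(classMaps) {
  if (is(classMaps, "HabitatClassMap")) classMaps <- list(classMaps)
  g <- classMaps[[1]]@grid
  for (m in classMaps)
    if (!.sameGrid(m@grid, g)) stop("class maps must share one grid")
  cc <- cellCenters(g)
  do.call(rbind, lapply(classMaps, function(m) {
    opt <- m@optimalMask
    box <- if (any(opt)) {
      c(min(cc$lat[opt]) - g@res / 2, max(cc$lat[opt]) + g@res / 2,
        min(cc$lon[opt]) - g@res / 2, max(cc$lon[opt]) + g@res / 2)
    } else rep(NA_real_, 4)
    data.frame(year = m@year, month = m@month, species = m@species,
               optimal_cells = sum(opt), unmasked_cells = sum(!is.na(m@classes)),
               optimal_fraction = sum(opt) / max(1L, sum(!is.na(m@classes))),
               lat_min = box[1], lat_max = box[2],
               lon_min = box[3], lon_max = box[4])
  }))
}
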