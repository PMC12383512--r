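#' Construct an HSISurface
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param values Numeric vector of per-cell suitability in [0,1] (NA where
#'   masked), in linear cell-id order.
#' @param species Species tag.
#' @param role One of \code{"truth"}, \code{"empirical"},
#'   \code{"regional_ss"}, \code{"ic"}, \code{"cohabitation"}.
#' @param year,month Integer provenance tags.
#' @return An \linkS4class{HSISurface}.
#' @export
HSISurface <- function(grid, values, species, role, year, month) {
  new("HSISurface", grid = grid, values = as.numeric(values),
      species = species, role = role,
      year = as.integer(year), month = as.integer(month))
}

#' @rdname hsiValues
#' @export
setGeneric("hsiValues", function(x) standardGeneric("hsiValues"))

#' Per-cell suitability values of a surface
#'
#' @param x An \linkS4class{HSISurface}.
#' @return Numeric vector in linear cell-id order; NA marks masked cells.
#' @name hsiValues
#' @export
setMethod("hsiValues", "HSISurface", function(x) x@values)

#' @rdname surfaceRole
#' @export
setGeneric("surfaceRole", function(x) standardGeneric("surfaceRole"))

#' Role tag of a surface
#' @param x An \linkS4class{HSISurface}.
#' @name surfaceRole
#' @export
setMethod("surfaceRole", "HSISurface", function(x) x@role)

#' @rdname speciesName
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' Species tag of a surface or model
#' @param x An \linkS4class{HSISurface} or \linkS4class{FittedSDM}.
#' @name speciesName
#' @export
setMethod("speciesName", "HSISurface", function(x) x@species)

#' @rdname speciesName
#' @export
setMethod("speciesName", "FittedSDM", function(x) x@species)

setMethod("show", "HSISurface", function(object) {
  v <- object@values
  cat(sprintf("HSISurface '%s' role=%s %d-%02d: %d cells (%d masked), range [%.3f, %.3f]\n",
              object@species, object@role, object@year, object@month,
              length(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

#' Convert surfaces to/from long-format tables
#'
#' The long CSV dialect carries one row per cell:
#' \code{year,month,lat,lon,species,role,hsi}.
#'
#' @param x An \linkS4class{HSISurface} or a list of them.
#' @return data.frame in the long dialect (masked cells have NA hsi).
#' @export
surfaceToLong <- function(x) {
  if (is(x, "HSISurface")) x <- list(x)
  do.call(rbind, lapply(x, function(s) {
    cc <- cellCenters(s@grid)
    data.frame(year = s@year, month = s@month, lat = cc$lat, lon = cc$lon,
               species = s@species, role = s@role, hsi = s@values)
  }))
}

#' @rdname surfaceToLong
#' @param df Long-format data.frame as produced by \code{surfaceToLong}.
#' @param grid The \linkS4class{GridSpec} the table was exported from.
#' @return \code{surfaceFromLong}: a list of \linkS4class{HSISurface}.
#' @export
surfaceFromLong <- function(df, grid) {
  keys <- unique(df[, c("year", "month", "species", "role")])
  lapply(seq_len(nrow(keys)), function(r) {
    k <- keys[r, ]
    sub <- df[df$year == k$year & df$month == k$month &
              df$species == k$species & df$role == k$role, ]
    cell <- assignCell(sub$lat, sub$lon, grid)$cell
    vals <- rep(NA_real_, nCells(grid))
    vals[cell] <- sub$hsi
    HSISurface(grid, vals, k$species, k$role, k$year, k$month)
  })
}
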