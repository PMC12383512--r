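#' Construct a GridSpec
#'
#' @param latMin,latMax,lonMin,lonMax Grid bounds in decimal degrees.
#'   Defaults cover the Northwest Pacific study window 34-45 N, 144-163 E.
#' @param res Cell resolution in degrees; default 0.25.
#' @return A \linkS4class{GridSpec}.
#' @examples
#' g <- GridSpec()
#' nCells(g)
#' @export
GridSpec <- function(latMin = 34, latMax = 45, lonMin = 144, lonMax = 163,
                     res = 0.25) {
  new("GridSpec", latMin = latMin, latMax = latMax,
      lonMin = lonMin, lonMax = lonMax, res = res)
}

#' @describeIn GridSpec number of latitude rows
#' @param grid A \linkS4class{GridSpec}.
#' @export
nLat <- function(grid) as.integer(round((grid@latMax - grid@latMin) / grid@res))

#' @describeIn GridSpec number of longitude columns
#' @export
nLon <- function(grid) as.integer(round((grid@lonMax - grid@lonMin) / grid@res))

#' @describeIn GridSpec total number of cells
#' @export
nCells <- function(grid) nLat(grid) * nLon(grid)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %g-%g N x %g-%g E at %g deg (%d x %d = %d cells)\n",
              object@latMin, object@latMax, object@lonMin, object@lonMax,
              object@res, nLat(object), nLon(object), nCells(object)))
})

## linear cell id from 0-based (i, j); row-major with latitude rows
.cellId <- function(i, j, grid) i * nLon(grid) + j + 1L

#' Cell-centre coordinate table
#'
#' One row per grid cell in linear-id order: 0-based indices \code{i}
#' (latitude row from the south) and \code{j} (longitude column from the
#' west), and the cell-centre coordinates.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @return data.frame with columns \code{cell}, \code{i}, \code{j},
#'   \code{lat}, \code{lon}.
#' @export
cellCenters <- function(grid) {
  ni <- nLat(grid); nj <- nLon(grid)
  i <- rep(seq_len(ni) - 1L, each = nj)
  j <- rep(seq_len(nj) - 1L, times = ni)
  data.frame(cell = .cellId(i, j, grid), i = i, j = j,
             lat = grid@latMin + (i + 0.5) * grid@res,
             lon = grid@lonMin + (j + 0.5) * grid@res)
}

#' Assign points to grid cells
#'
#' Maps coordinates to 0-based cell indices using half-open cells
#' \code{[low, high)} in both axes; points exactly on the northern or
#' eastern boundary fall in the last row/column. Points outside the grid
#' bounds are an error, never silently clamped.
#'
#' @param lat,lon Numeric vectors of equal length, decimal degrees.
#' @param grid A \linkS4class{GridSpec}.
#' @return data.frame with columns \code{i}, \code{j}, \code{cell}.
#' @examples
#' assignCell(34.0, 144.0, GridSpec())   # origin cell (0, 0)
#' assignCell(45.0, 163.0, GridSpec())   # boundary point -> last cell
#' @export
assignCell <- function(lat, lon, grid) {
  stopifnot(length(lat) == length(lon))
  bad <- lat < grid@latMin | lat > grid@latMax |
         lon < grid@lonMin | lon > grid@lonMax | !is.finite(lat) | !is.finite(lon)
  if (any(bad))
    stop(sprintf("%d point(s) outside grid bounds [%g, %g] x [%g, %g]; first: (%g, %g)",
                 sum(bad), grid@latMin, grid@latMax, grid@lonMin, grid@lonMax,
                 lat[which(bad)[1]], lon[which(bad)[1]]))
  i <- pmin(as.integer(floor((lat - grid@latMin) / grid@res)), nLat(grid) - 1L)
  j <- pmin(as.integer(floor((lon - grid@lonMin) / grid@res)), nLon(grid) - 1L)
  data.frame(i = i, j = j, cell = .cellId(i, j, grid))
}

#' @rdname gridSpec
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Extract the GridSpec of a gridded object
#'
#' @param x An \linkS4class{EnvStack}, \linkS4class{HSISurface} or
#'   \linkS4class{HabitatClassMap}.
#' @return The \linkS4class{GridSpec}.
#' @name gridSpec
#' @export
setMethod("gridSpec", "EnvStack", function(x) S4Vectors::metadata(x)$grid)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "HSISurface", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "HabitatClassMap", function(x) x@grid)

.sameGrid <- function(a, b) {
  isTRUE(all.equal(c(a@latMin, a@latMax, a@lonMin, a@lonMax, a@res),
                   c(b@latMin, b@latMax, b@lonMin, b@lonMax, b@res),
                   tolerance = 1e-9))
}
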