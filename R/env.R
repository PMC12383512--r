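#' Construct an EnvStack from per-covariate matrices
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param assays Named list of 13 numeric matrices (cells x layers), names
#'   exactly \code{covariateNames()}.
#' @param years,months Integer vectors, one entry per layer (column).
#' @param mask Logical per-cell land mask (TRUE = masked); default none.
#' @return An \linkS4class{EnvStack}.
#' @export
EnvStack <- function(grid, assays, years, months, mask = NULL) {
  cc <- cellCenters(grid)
  if (is.null(mask)) mask <- rep(FALSE, nCells(grid))
  rd <- S4Vectors::DataFrame(i = cc$i, j = cc$j, lat = cc$lat, lon = cc$lon,
                             mask = mask)
  cd <- S4Vectors::DataFrame(year = as.integer(years), month = as.integer(months))
  colnames(cd) <- c("year", "month")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd,
    metadata = list(grid = grid))
  colnames(se) <- sprintf("%d-%02d", as.integer(years), as.integer(months))
  new("EnvStack", se)
}

#' Layer lookup: column index of a (year, month) in an EnvStack
#' @param env An \linkS4class{EnvStack}.
#' @param year,month Integers.
#' @return Integer column index.
#' @keywords internal
.layerIndex <- function(env, year, month) {
  cd <- SummarizedExperiment::colData(env)
  idx <- which(cd$year == year & cd$month == month)
  if (length(idx) != 1L)
    stop(sprintf("environment stack has no unique layer for %d-%02d", year, month))
  idx
}

#' Extract the covariate matrix for one (year, month) layer
#'
#' @param env An \linkS4class{EnvStack}.
#' @param year,month Integers identifying the layer.
#' @return Numeric matrix (cells x 13 covariates); masked cells are NA.
#' @export
envLayer <- function(env, year, month) {
  idx <- .layerIndex(env, year, month)
  m <- vapply(covariateNames(),
              function(v) SummarizedExperiment::assay(env, v)[, idx],
              numeric(nrow(env)))
  m[SummarizedExperiment::rowData(env)$mask, ] <- NA_real_
  m
}

#' @rdname envToLong
#' @export
envMask <- function(env) SummarizedExperiment::rowData(env)$mask

#' Convert an EnvStack to/from the long CSV dialect
#'
#' The dialect is \code{year,month,lat,lon,var,value}, one row per
#' (cell, layer, covariate); masked cells are omitted.
#'
#' @param env An \linkS4class{EnvStack}.
#' @return data.frame in the long dialect.
#' @export
envToLong <- function(env) {
  cd <- SummarizedExperiment::colData(env)
  rd <- SummarizedExperiment::rowData(env)
  keep <- !rd$mask
  out <- lapply(covariateNames(), function(v) {
    a <- SummarizedExperiment::assay(env, v)[keep, , drop = FALSE]
    data.frame(year = rep(cd$year, each = sum(keep)),
               month = rep(cd$month, each = sum(keep)),
               lat = rep(rd$lat[keep], times = ncol(a)),
               lon = rep(rd$lon[keep], times = ncol(a)),
               var = v, value = as.vector(a))
  })
  do.call(rbind, out)
}

#' @rdname envToLong
#' @param df Long-format data.frame.
#' @param grid The \linkS4class{GridSpec} of the exported stack.
#' @return \code{envFromLong}: an \linkS4class{EnvStack}; cells absent from
#'   the table are masked.
#' @export
envFromLong <- function(df, grid) {
  stopifnot(all(c("year", "month", "lat", "lon", "var", "value") %in% names(df)))
  bad <- setdiff(unique(df$var), covariateNames())
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  layers <- unique(df[, c("year", "month")])
  layers <- layers[order(layers$year, layers$month), ]
  nc <- nCells(grid)
  cell <- assignCell(df$lat, df$lon, grid)$cell
  lay <- match(paste(df$year, df$month), paste(layers$year, layers$month))
  seen <- rep(FALSE, nc)
  assays <- lapply(covariateNames(), function(v) {
    m <- matrix(NA_real_, nc, nrow(layers))
    sel <- df$var == v
    m[cbind(cell[sel], lay[sel])] <- df$value[sel]
    seen[unique(cell[sel])] <<- TRUE
    m
  })
  names(assays) <- covariateNames()
  EnvStack(grid, assays, layers$year, layers$month, mask = !seen)
}

setMethod("show", "EnvStack", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("EnvStack: %d cells x %d layers (%s) x 13 covariates; %d masked cells\n",
              nrow(object), ncol(object),
              paste(range(cd$year), collapse = "-"),
              sum(SummarizedExperiment::rowData(object)$mask)))
})
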