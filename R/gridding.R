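#' Aggregate logbook records to cell-month samples
#'
#' Sums catch, effort and hauls within (species, cell, year, month) and
#' recomputes CPUE as the ratio of sums (tons per effort day), never the
#' mean of per-record ratios. Rows with negative catch or effort are
#' rejected row-wise with a warning listing their line numbers. The result
#' carries the grid as an attribute plus per-month sample counts and the
#' per-month count of cells where both species occur
#' (\code{attr(x, "monthlyCounts")}, \code{attr(x, "overlap")}).
#'
#' @param records Logbook data.frame with columns \code{date, lat, lon,
#'   species, catch_t, effort_days} (and optionally \code{hauls}).
#' @param grid A \linkS4class{GridSpec}.
#' @return data.frame of cell samples, one row per
#'   (species, cell, year, month).
#' @export
aggregateRecords <- function(records, grid) {
  need <- c("date", "lat", "lon", "species", "catch_t", "effort_days")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("logbook lacks column(s): ", paste(miss, collapse = ", "))
  if (!"hauls" %in% names(records)) records$hauls <- NA_integer_
  d <- as.Date(records$date, format = "%Y-%m-%d")
  if (anyNA(d)) stop("unparseable date(s) at line(s): ",
                     paste(head(which(is.na(d)), 5), collapse = ", "))
  bad <- which(records$catch_t < 0 | records$effort_days < 0)
  if (length(bad)) {
    warning(sprintf("rejected %d record(s) with negative catch/effort at line(s): %s",
                    length(bad), paste(head(bad, 10), collapse = ", ")))
    records <- records[-bad, ]
    d <- d[-bad]
  }
  if (!nrow(records)) stop("no valid records to aggregate")
  cell <- assignCell(records$lat, records$lon, grid)$cell
  key <- data.frame(species = records$species, cell = cell,
                    year = as.integer(format(d, "%Y")),
                    month = as.integer(format(d, "%m")))
  agg <- stats::aggregate(
    cbind(catch_t = records$catch_t, effort_days = records$effort_days,
          hauls = records$hauls),
    by = key, FUN = sum)
  agg <- agg[order(agg$species, agg$year, agg$month, agg$cell), ]
  cc <- cellCenters(grid)
  m <- match(agg$cell, cc$cell)
  out <- data.frame(species = agg$species, cell = agg$cell,
                    i = cc$i[m], j = cc$j[m], lat = cc$lat[m], lon = cc$lon[m],
                    year = agg$year, month = agg$month,
                    catch_t = agg$catch_t, effort_days = agg$effort_days,
                    hauls = agg$hauls,
                    cpue = agg$catch_t / agg$effort_days)
  rownames(out) <- NULL
  counts <- stats::aggregate(list(n = out$cell),
                             by = out[, c("species", "year", "month")], FUN = length)
  sp <- unique(out$species)
  overlap <- NULL
  if (length(sp) == 2L) {
    ym <- unique(out[, c("year", "month")])
    overlap <- do.call(rbind, lapply(seq_len(nrow(ym)), function(r) {
      sub <- out[out$year == ym$year[r] & out$month == ym$month[r], ]
      data.frame(year = ym$year[r], month = ym$month[r],
                 overlap = length(intersect(sub$cell[sub$species == sp[1]],
                                            sub$cell[sub$species == sp[2]])))
    }))
  } else {
    ym <- unique(out[, c("year", "month")])
    overlap <- data.frame(year = ym$year, month = ym$month, overlap = 0L)
  }
  attr(out, "grid") <- grid
  attr(out, "monthlyCounts") <- counts
  attr(out, "overlap") <- overlap
  out
}

#' Join environmental covariates onto cell samples
#'
#' Exact (cell, year, month) join of the thirteen covariates. Rows falling
#' on masked environment cells (or on layers absent from the stack) are
#' flagged \code{complete = FALSE} and are excluded from model fitting
#' downstream; their count is reported via message.
#'
#' @param samples Cell-sample data.frame from \code{\link{aggregateRecords}}.
#' @param env An \linkS4class{EnvStack} on the same grid (grid mismatch is
#'   fatal).
#' @return \code{samples} with 13 covariate columns and a logical
#'   \code{complete} column appended.
#' @export
matchEnvironment <- function(samples, env) {
  g <- attr(samples, "grid")
  if (is.null(g)) stop("samples carry no grid attribute; use aggregateRecords()")
  if (!.sameGrid(g, gridSpec(env)))
    stop("grid mismatch between samples and environment stack")
  cd <- SummarizedExperiment::colData(env)
  lay <- match(paste(samples$year, samples$month), paste(cd$year, cd$month))
  covs <- matrix(NA_real_, nrow(samples), length(covariateNames()),
                 dimnames = list(NULL, covariateNames()))
  for (v in covariateNames()) {
    a <- SummarizedExperiment::assay(env, v)
    ok <- !is.na(lay)
    covs[ok, v] <- a[cbind(samples$cell[ok], lay[ok])]
  }
  masked <- envMask(env)[samples$cell]
  covs[masked, ] <- NA_real_
  res <- cbind(samples, as.data.frame(covs))
  res$complete <- stats::complete.cases(covs)
  n_inc <- sum(!res$complete)
  if (n_inc) message(sprintf("matchEnvironment: %d of %d rows incomplete (masked or missing layer)",
                             n_inc, nrow(res)))
  for (a in c("grid", "monthlyCounts", "overlap")) attr(res, a) <- attr(samples, a)
  res
}

#' Empirical habitat suitability index from CPUE
#'
#' Min-max normalizes CPUE within each (species, month) stratum, pooled
#' over the years present, so the cell with the stratum's maximum CPUE gets
#' HSI 1 and the minimum gets 0. A degenerate stratum (all CPUE equal) gets
#' HSI 0.5 for all its rows, with a warning.
#'
#' @param samples Cell-sample data.frame with a \code{cpue} column.
#' @return \code{samples} with an \code{hsi_emp} column in [0,1] appended.
#' @export
empiricalHSI <- function(samples) {
  stopifnot("cpue" %in% names(samples))
  hsi <- rep(NA_real_, nrow(samples))
  strata <- unique(samples[, c("species", "month")])
  for (r in seq_len(nrow(strata))) {
    sel <- samples$species == strata$species[r] & samples$month == strata$month[r]
    x <- samples$cpue[sel]
    rng <- range(x)
    if (diff(rng) == 0) {
      warning(sprintf("degenerate CPUE stratum (%s, month %d): all values equal; HSI set to 0.5",
                      strata$species[r], strata$month[r]))
      hsi[sel] <- 0.5
    } else {
      hsi[sel] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  samples$hsi_emp <- hsi
  samples
}

#' Full gridding stage: records + environment to model-ready samples
#'
#' Chains \code{\link{aggregateRecords}}, \code{\link{matchEnvironment}}
#' and \code{\link{empiricalHSI}}.
#'
#' @param records Logbook data.frame.
#' @param env An \linkS4class{EnvStack}.
#' @return Model-ready cell-sample data.frame.
#' @export
buildCellSamples <- function(records, env) {
  empiricalHSI(matchEnvironment(aggregateRecords(records, gridSpec(env)), env))
}
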