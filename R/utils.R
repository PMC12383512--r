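## small internal helpers

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Normalize month input
#'
#' Accepts month numbers (6..11) or English names ("June".."November") and
#' returns integers; unknown names are an error.
#' @param months Integer or character vector.
#' @return Integer vector.
#' @export
monthNumber <- function(months) {
  if (is.numeric(months)) return(as.integer(months))
  idx <- match(months, names(.MONTH_NAMES))
  if (anyNA(idx))
    stop("unknown month name(s): ",
         paste(months[is.na(idx)], collapse = ", "),
         " (expected June..November)")
  unname(.MONTH_NAMES[idx])
}

#' Derive a reproducible substream seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams so stages can be re-run independently yet reproducibly.
#' The derivation is a fixed integer hash of (root, label), kept within
#' 32-bit range.
#'
#' @param root Integer root seed.
#' @param label Character substream label, e.g. "generator", "splits".
#' @return Integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(root, label) {
  h <- as.double(root) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

## Smooth random field on an ni x nj lattice: coarse white noise bilinearly
## interpolated to the full lattice. 'scale' is the coarse knot spacing in
## cells; larger => smoother.
.smoothField <- function(ni, nj, scale = 8, sd = 1) {
  ki <- max(2L, ceiling(ni / scale) + 1L)
  kj <- max(2L, ceiling(nj / scale) + 1L)
  knots <- matrix(rnorm(ki * kj, 0, sd), ki, kj)
  gi <- seq(1, ki, length.out = ni)
  gj <- seq(1, kj, length.out = nj)
  i0 <- pmin(floor(gi), ki - 1L); fi <- gi - i0
  j0 <- pmin(floor(gj), kj - 1L); fj <- gj - j0
  a <- knots[cbind(rep(i0, nj), rep(j0, each = ni))]
  b <- knots[cbind(rep(i0 + 1, nj), rep(j0, each = ni))]
  cc <- knots[cbind(rep(i0, nj), rep(j0 + 1, each = ni))]
  d <- knots[cbind(rep(i0 + 1, nj), rep(j0 + 1, each = ni))]
  wfi <- rep(fi, nj); wfj <- rep(fj, each = ni)
  v <- a * (1 - wfi) * (1 - wfj) + b * wfi * (1 - wfj) +
       cc * (1 - wfi) * wfj + d * wfi * wfj
  matrix(v, ni, nj)  # [i, j] = [lat row, lon col]
}

## matrix [i, j] -> vector in linear cell-id order (i-major, j fastest)
.fieldToVector <- function(m) as.vector(t(m))

#' Holdout R-squared
#'
#' \eqn{R^2 = 1 - SSE/SST} of predictions against observations, with SST
#' about the observed mean. Returns NA (with attribute) when the
#' observations have zero variance.
#' @param obs,pred Numeric vectors of equal length.
#' @return Numeric scalar (possibly negative; never above 1), or NA.
#' @export
holdoutR2 <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Significance stars for p-values
#'
#' Standard ladder: **** p < 0.0001, *** p < 0.001, ** p < 0.01,
#' * p < 0.05, "ns" otherwise.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 5e-2, "*", "ns")))))
}
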