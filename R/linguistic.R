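#' Default bank of linguistic membership functions
#'
#' Five triangular membership functions on the weight-magnitude axis \[0, 1\],
#' one per linguistic level (`very_low`, `low`, `medium`, `high`,
#' `very_high`), with peaks evenly spaced at 0.1, 0.3, ..., 0.9 and a common
#' half-width of 0.25. The outermost triangles extend past the axis and are
#' truncated to \[0, 1\] when evaluated, so `very_low`/`very_high` are
#' shoulder-like rather than symmetric.
#'
#' @param peaks Named numeric vector of peak positions, one per level; names
#'   define the admissible linguistic terms.
#' @param halfwidth Common half-width of the triangles.
#' @return A data.frame of class `"mf_bank"` with columns `level`, `left`,
#'   `peak`, `right`.
#' @export
mf_bank <- function(peaks = c(very_low = 0.1, low = 0.3, medium = 0.5,
                              high = 0.7, very_high = 0.9),
                    halfwidth = 0.25) {
  if (is.null(names(peaks)) || any(!nzchar(names(peaks))))
    stop("`peaks` must be a named vector", call. = FALSE)
  if (halfwidth <= 0) stop("`halfwidth` must be positive", call. = FALSE)
  bank <- data.frame(
    level = names(peaks),
    left = unname(peaks) - halfwidth,
    peak = unname(peaks),
    right = unname(peaks) + halfwidth,
    stringsAsFactors = FALSE
  )
  class(bank) <- c("mf_bank", class(bank))
  bank
}

# Triangular membership, vectorised over x. Zero outside [left, right];
# truncation to [0, 1] happens implicitly because curves are tabulated on a
# grid confined to the unit interval.
mf_membership <- function(x, left, peak, right) {
  up <- if (peak > left) (x - left) / (peak - left) else as.numeric(x >= peak)
  dn <- if (right > peak) (right - x) / (right - peak) else as.numeric(x <= peak)
  pmax(0, pmin(up, dn, 1))
}

#' SUM aggregation of linguistic terms
#'
#' Pointwise sum of the membership functions of the given terms, tabulated on
#' a fixed grid over \[0, 1\]. The sum is deliberately not renormalised or
#' clipped by default: the centroid is scale-invariant, and clipping at 1
#' would discard the multiplicity of agreeing opinions. A bounded-sum mode is
#' available via `clip`.
#'
#' @param terms Character vector of linguistic terms (levels of `bank`).
#' @param bank An [mf_bank()].
#' @param step Grid step on \[0, 1\].
#' @param clip If `TRUE`, the aggregated curve is capped at 1 (bounded sum).
#' @return A list of class `"membership_curve"` with components `x` (grid)
#'   and `mu` (aggregated membership values).
#' @export
mf_aggregate <- function(terms, bank = mf_bank(), step = 1e-4, clip = FALSE) {
  if (length(terms) == 0L)
    stop("`terms` must contain at least one linguistic term", call. = FALSE)
  terms <- as.character(terms)
  unknown <- setdiff(terms, bank$level)
  if (length(unknown))
    stop("unknown linguistic term(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  x <- seq(0, 1, by = step)
  mu <- numeric(length(x))
  for (tm in terms) {
    row <- bank[bank$level == tm, ]
    mu <- mu + mf_membership(x, row$left, row$peak, row$right)
  }
  if (clip) mu <- pmin(mu, 1)
  structure(list(x = x, mu = mu), class = "membership_curve")
}

#' Centroid defuzzification
#'
#' Collapses a tabulated membership curve to its centre of mass,
#' \eqn{\int x \mu(x) dx / \int \mu(x) dx}, by trapezoidal integration on the
#' curve's grid.
#'
#' @param curve A `"membership_curve"` (or any list with numeric `x`, `mu`).
#' @return The centroid, a scalar in \[0, 1\].
#' @export
mf_centroid <- function(curve) {
  x <- curve$x
  mu <- curve$mu
  if (length(x) != length(mu) || length(x) < 2L)
    stop("malformed membership curve", call. = FALSE)
  if (any(mu < 0))
    stop("membership values must be non-negative", call. = FALSE)
  area <- pracma::trapz(x, mu)
  if (area <= 0)
    stop("cannot defuzzify an identically zero membership curve", call. = FALSE)
  pracma::trapz(x, x * mu) / area
}

#' Build a signed weight matrix from expert opinions
#'
#' Converts multi-expert linguistic causal judgments into the signed numeric
#' weight matrix of an FCM. For every (source, target) pair with at least one
#' opinion, the magnitude is the centroid of the SUM-aggregated membership
#' functions of *all* experts' terms for that pair (magnitudes are aggregated
#' sign-free), and the sign is decided by majority vote across experts. Pairs
#' with no opinion get weight zero; an exact sign tie is a consensus failure
#' and raises an error rather than guessing.
#'
#' @param opinions A data.frame with columns `source`, `target`, `sign`
#'   (+1/-1), `term` (a level of `bank`) and `expert` (identifier). One row
#'   per expert judgment; the same expert may not judge the same pair twice.
#' @param concept_ids Character vector of all concept ids, fixing matrix
#'   order.
#' @param bank An [mf_bank()].
#' @param step Grid step passed to [mf_aggregate()].
#' @param clip Passed to [mf_aggregate()].
#' @return A square signed weight matrix with `dimnames = concept_ids`.
#' @export
weights_from_opinions <- function(opinions, concept_ids, bank = mf_bank(),
                                  step = 1e-4, clip = FALSE) {
  req <- c("source", "target", "sign", "term", "expert")
  missing_cols <- setdiff(req, names(opinions))
  if (length(missing_cols))
    stop("`opinions` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- length(concept_ids)
  W <- matrix(0, n, n, dimnames = list(concept_ids, concept_ids))
  if (nrow(opinions) == 0L) return(W)

  bad <- !(opinions$source %in% concept_ids) | !(opinions$target %in% concept_ids)
  if (any(bad))
    stop("opinion refers to unknown concept id(s): ",
         paste(unique(c(opinions$source[bad], opinions$target[bad])),
               collapse = ", "), call. = FALSE)
  if (any(opinions$source == opinions$target))
    stop("self-referential opinions (source == target) are not allowed",
         call. = FALSE)
  if (!all(opinions$sign %in% c(-1, 1)))
    stop("`sign` must be +1 or -1", call. = FALSE)
  key <- paste(opinions$source, opinions$target, opinions$expert, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate opinion: the same expert judged the same pair twice",
         call. = FALSE)

  pair <- paste(opinions$source, opinions$target, sep = "\r")
  for (p in unique(pair)) {
    rows <- opinions[pair == p, , drop = FALSE]
    vote <- sum(rows$sign)
    if (vote == 0)
      stop("tied sign vote for edge ", rows$source[1], " -> ", rows$target[1],
           ": expert consensus required", call. = FALSE)
    mag <- mf_centroid(mf_aggregate(rows$term, bank, step = step, clip = clip))
    W[rows$source[1], rows$target[1]] <- sign(vote) * mag
  }
  W
}
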