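#' Piecewise-constant recombination map
#'
#' Builds a recombination map over a single chromosome of length `L` bp,
#' tiled by segments with constant rates in cM/Mb.  Internally the map is a
#' piecewise-linear cumulative position in Morgans; 1 cM/Mb equals
#' 1e-8 Morgans per bp.  Coordinates are 0-based, half-open.
#'
#' @param rates_cM_Mb Numeric vector of per-segment recombination rates
#'   (cM/Mb), all `>= 0`.
#' @param L Chromosome length in bp.
#' @param starts_bp Optional sorted segment start positions (first must be
#'   0).  Defaults to equal-length segments.
#' @return An object of class `recomb_map`: a list with anchor positions
#'   (`bp`), cumulative Morgans (`morgans`), `L` and the per-segment rates.
#' @examples
#' m <- recomb_map(1, 1e6)        # uniform 1 cM/Mb over 1 Mb
#' map_length(m)                  # 0.01 Morgans
#' @export
recomb_map <- function(rates_cM_Mb, L, starts_bp = NULL) {
  stopifnot(is.numeric(rates_cM_Mb), length(rates_cM_Mb) >= 1,
            all(rates_cM_Mb >= 0), is.numeric(L), L > 0)
  k <- length(rates_cM_Mb)
  if (is.null(starts_bp)) starts_bp <- floor(seq(0, L, length.out = k + 1))[-(k + 1)]
  stopifnot(length(starts_bp) == k, starts_bp[1] == 0,
            !is.unsorted(starts_bp, strictly = TRUE), all(starts_bp < L))
  edges <- c(starts_bp, L)
  seg_m <- diff(edges) * rates_cM_Mb * 1e-8   # cM/Mb -> Morgans/bp
  structure(
    list(bp = edges, morgans = c(0, cumsum(seg_m)),
         rates_cM_Mb = rates_cM_Mb, L = L),
    class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("<recomb_map> %d segment(s), L = %s bp, total map = %.4g cM\n",
              length(x$rates_cM_Mb), format(x$L, big.mark = ","),
              100 * map_length(x)))
  invisible(x)
}

#' Total genetic length of a map, in Morgans
#' @param map A `recomb_map`.
#' @export
map_length <- function(map) {
  stopifnot(inherits(map, "recomb_map"))
  map$morgans[length(map$morgans)]
}

#' Cumulative map position (Morgans) at given bp coordinates
#'
#' Linear interpolation between anchors; queries outside `[0, L]` are
#' clamped.
#' @param map A `recomb_map`.
#' @param bp Numeric vector of physical positions.
#' @export
map_position <- function(map, bp) {
  stopifnot(inherits(map, "recomb_map"))
  bp <- pmin(pmax(bp, 0), map$L)
  approx(map$bp, map$morgans, xout = bp, rule = 2, ties = "ordered")$y
}

#' Invert a cumulative map: bp coordinate at given Morgan positions
#'
#' Within zero-rate (flat) stretches the leftmost bp is returned.
#' @param map A `recomb_map`.
#' @param morgans Numeric vector of cumulative map positions.
#' @export
map_to_bp <- function(map, morgans) {
  stopifnot(inherits(map, "recomb_map"))
  morgans <- pmin(pmax(morgans, 0), map_length(map))
  vapply(morgans, function(mm) {
    k <- findInterval(mm, map$morgans, rightmost.closed = TRUE)
    k <- max(1L, min(k, length(map$bp) - 1L))
    span <- map$morgans[k + 1] - map$morgans[k]
    if (span <= 0) return(map$bp[k])
    map$bp[k] + (mm - map$morgans[k]) / span * (map$bp[k + 1] - map$bp[k])
  }, numeric(1))
}

#' Haldane map function: Morgans to recombination fraction
#'
#' `c = (1 - exp(-2 d)) / 2`, exact for crossovers without interference
#' (Poisson-distributed on the map scale), which is the crossover model the
#' simulator uses.
#' @param d Map distance(s) in Morgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_c <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d))
}
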