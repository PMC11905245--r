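#' MLC bank positions at a control point
#'
#' A pair of opposed leaf banks. Coordinates follow IEC 61217 MLCX: the
#' left bank (bank A) carries the negative-going leaf edges, the right bank
#' (bank B) the positive-going ones, so the opening of pair \eqn{n} is
#' `right[n] - left[n]` and must be nonnegative. Openings in
#' `[-tolerance, 0)` are snapped to closed; a more negative opening is an
#' error.
#'
#' @param left numeric vector of bank-A leaf edge coordinates (mm), one per
#'   leaf pair.
#' @param right numeric vector of bank-B leaf edge coordinates (mm), same
#'   length as `left`.
#' @param leaf_width leaf-pair width (mm) along the direction orthogonal to
#'   leaf travel. Fixed at 5 mm for the MLC modelled here.
#' @param tolerance snap tolerance (mm) for numerically negative openings.
#' @return an object of class `mlc_positions`.
#' @examples
#' m <- mlc_positions(left = c(-10, -12, -10), right = c(10, 12, 10))
#' openings(m)
#' @export
mlc_positions <- function(left, right, leaf_width = 5, tolerance = 1e-3) {
  stop_if(!is.numeric(left) || !is.numeric(right),
          "leaf bank positions must be numeric")
  stop_if(length(left) != length(right),
          "left and right banks must have the same number of leaves")
  stop_if(length(left) < 1L, "an MLC needs at least one leaf pair")
  stop_if(!is_number(leaf_width) || leaf_width <= 0,
          "leaf_width must be a positive number")
  stop_if(anyNA(left) || anyNA(right), "leaf positions must not contain NA")
  gap <- right - left
  snap <- gap < 0 & gap >= -tolerance
  if (any(snap)) right[snap] <- left[snap]
  bad <- which(right - left < 0)
  stop_if(length(bad) > 0,
          "negative opening (right < left) at leaf pair(s) ",
          paste(bad, collapse = ", "))
  structure(
    list(left = as.numeric(left), right = as.numeric(right),
         leaf_width = leaf_width),
    class = "mlc_positions"
  )
}

#' @export
print.mlc_positions <- function(x, ...) {
  cat(sprintf("<mlc_positions> %d leaf pairs, t = %g mm, %d open\n",
              length(x$left), x$leaf_width, sum(openings(x) > 0)))
  invisible(x)
}

#' Per-pair openings of an MLC snapshot
#'
#' @param mlc an [mlc_positions] object.
#' @return numeric vector `right - left` (mm), one value per leaf pair.
#' @export
openings <- function(mlc) {
  stopifnot(inherits(mlc, "mlc_positions"))
  mlc$right - mlc$left
}

# logical vector: pairs counted as dosimetrically open
open_pairs <- function(mlc, closed_gap = 0.5) {
  openings(mlc) > closed_gap
}

# perimeter of the union of a vertical stack of axis-aligned rectangles,
# one per open leaf pair (height t, x-interval [l, r]).  Closed form: each
# open row contributes 2t of vertical edge; horizontal exposure at each
# interface is len_r + len_{r+1} - 2 * overlap.  Corner contacts and
# disjoint rows fall out as separate components automatically.
stack_perimeter <- function(l, r, t) {
  m <- length(l)
  if (m == 0L) return(0)
  len <- r - l
  per <- 2 * t * m + len[1] + len[m]
  if (m > 1L) {
    ov <- pmax(0, pmin(r[-m], r[-1]) - pmax(l[-m], l[-1]))
    per <- per + sum(len[-m] + len[-1] - 2 * ov)
  }
  per
}

#' Aperture geometry at a single control point
#'
#' Computes the aperture area \eqn{AA}, perimeter \eqn{AP} and irregularity
#' \eqn{AI = AP^2 / (4 \pi AA)} of the MLC opening. The area is the
#' leaf-pair sum \eqn{AA = \sum_k t (x2_k - x1_k)} over open pairs; the
#' perimeter is the total boundary length of the union of the open
#' leaf-pair rectangles (a rectilinear polygon, possibly with several
#' connected components, whose perimeters are summed). Pairs with opening
#' at or below `closed_gap` are treated as parked-closed and excluded.
#'
#' `AI` is undefined (NA) for a fully closed aperture and is bounded below
#' by \eqn{4/\pi}, attained by a square, for any rectilinear aperture.
#'
#' @param mlc an [mlc_positions] object.
#' @param closed_gap openings at or below this value (mm) count as closed.
#' @return a list of class `aperture_geometry` with elements `area` (mm^2),
#'   `perimeter` (mm), `irregularity` (unitless) and `open_pair_count`.
#' @examples
#' sq <- mlc_positions(left = rep(-10, 4), right = rep(10, 4))
#' g <- aperture_geometry_cp(sq)   # 20 x 20 mm square
#' g$irregularity * pi / 4         # 1: square attains the bound
#' @export
aperture_geometry_cp <- function(mlc, closed_gap = 0.5) {
  stopifnot(inherits(mlc, "mlc_positions"))
  t <- mlc$leaf_width
  op <- open_pairs(mlc, closed_gap)
  area <- sum(t * (mlc$right[op] - mlc$left[op]))
  if (!any(op)) {
    res <- list(area = 0, perimeter = 0, irregularity = NA_real_,
                open_pair_count = 0L)
    class(res) <- "aperture_geometry"
    return(res)
  }
  # perimeter: split open pairs into maximal runs of consecutive rows;
  # rows in different runs never touch (separated by a closed pair)
  idx <- which(op)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  per <- sum(vapply(runs, function(i)
    stack_perimeter(mlc$left[i], mlc$right[i], t), numeric(1)))
  res <- list(area = area, perimeter = per,
              irregularity = per^2 / (4 * pi * area),
              open_pair_count = length(idx))
  class(res) <- "aperture_geometry"
  res
}

#' @export
print.aperture_geometry <- function(x, ...) {
  cat(sprintf(
    "<aperture_geometry> AA = %.2f mm^2, AP = %.2f mm, AI = %s (%d open pairs)\n",
    x$area, x$perimeter,
    if (is.na(x$irregularity)) "undef" else sprintf("%.4f", x$irregularity),
    x$open_pair_count))
  invisible(x)
}

# area (mm^2) of the union of a list of apertures (mlc_positions with equal
# pair counts): per leaf pair, the union of open x-intervals across the
# list, times the leaf width.  Exact interval-union arithmetic.
aperture_union_area <- function(mlcs, closed_gap = 0.5) {
  stopifnot(length(mlcs) >= 1L)
  n <- length(mlcs[[1]]$left)
  t <- mlcs[[1]]$leaf_width
  total <- 0
  for (pair in seq_len(n)) {
    l <- vapply(mlcs, function(m) m$left[pair], numeric(1))
    r <- vapply(mlcs, function(m) m$right[pair], numeric(1))
    keep <- (r - l) > closed_gap
    if (!any(keep)) next
    total <- total + t * interval_union_length(l[keep], r[keep])
  }
  total
}

# total length of the union of intervals [l_i, r_i]
interval_union_length <- function(l, r) {
  o <- order(l)
  l <- l[o]; r <- r[o]
  tot <- 0
  cur_l <- l[1]; cur_r <- r[1]
  for (i in seq_along(l)[-1]) {
    if (l[i] > cur_r) {
      tot <- tot + (cur_r - cur_l)
      cur_l <- l[i]; cur_r <- r[i]
    } else if (r[i] > cur_r) {
      cur_r <- r[i]
    }
  }
  tot + (cur_r - cur_l)
}
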