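#' Cumulative dose-volume histogram of a structure
#'
#' Bins the doses of the voxels inside the mask and accumulates from the
#' top: `volume_cc[k]` is the structure volume receiving at least
#' `dose_gy[k]`. The curve starts at the full structure volume at dose 0
#' and is nonincreasing. The raw-voxel mean dose is stored alongside (mean
#' dose is never taken from the binned curve, which would inherit
#' bin-width bias).
#'
#' @param dose a [dose_grid].
#' @param mask a [structure_mask] congruent with `dose`.
#' @param bin_gy bin width in Gy (default 0.01).
#' @return an object of class `dvh`: list with `dose_gy` (bin edges),
#'   `volume_cc` (volume at or above each edge), `structure`, `mean_gy`,
#'   `max_gy`, `min_gy`, `bin_gy`, `volume_total_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_gy = 0.01) {
  stop_if(!inherits(dose, "dose_grid"), "dose must be a dose_grid")
  stop_if(!inherits(mask, "structure_mask"), "mask must be a structure_mask")
  stop_if(!identical(dim(mask$mask), dim(dose$values)),
          "mask and dose grids are not congruent")
  stop_if(!is_number(bin_gy) || bin_gy <= 0, "bin_gy must be positive")
  doses <- dose$values[mask$mask]
  stop_if(length(doses) == 0L, "empty structure: ", mask$name)
  vv <- voxel_volume_cc(dose)
  edges <- seq(0, (floor(max(doses) / bin_gy) + 1) * bin_gy, by = bin_gy)
  # findInterval: voxel with dose d falls in bin i where edges[i] <= d;
  # volume at-or-above edge k counts bins k..end
  counts <- tabulate(findInterval(doses, edges), nbins = length(edges))
  vol_above <- rev(cumsum(rev(counts))) * vv
  structure(
    list(dose_gy = edges, volume_cc = vol_above, structure = mask$name,
         mean_gy = mean(doses), max_gy = max(doses), min_gy = min(doses),
         bin_gy = bin_gy, volume_total_cc = length(doses) * vv),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "<dvh> %s: %.2f cc, mean %.2f Gy, max %.2f Gy (bin %g Gy)\n",
    x$structure, x$volume_total_cc, x$mean_gy, x$max_gy, x$bin_gy))
  invisible(x)
}

#' @export
as.data.frame.dvh <- function(x, ...) {
  data.frame(dose_gy = x$dose_gy, volume_cc = x$volume_cc,
             volume_pct = 100 * x$volume_cc / x$volume_total_cc)
}

#' @export
plot.dvh <- function(x, relative = TRUE, add = FALSE, ...) {
  y <- if (relative) 100 * x$volume_cc / x$volume_total_cc else x$volume_cc
  if (add) {
    graphics::lines(x$dose_gy, y, ...)
  } else {
    graphics::plot(x$dose_gy, y, type = "l", xlab = "Dose (Gy)",
                   ylab = if (relative) "Volume (%)" else "Volume (cc)",
                   main = x$structure, ...)
  }
  invisible(x)
}

#' Query a cumulative DVH
#'
#' Extracts the standard scalar summaries:
#' \describe{
#'   \item{`"D<x>%"`}{minimum dose received by the hottest x% of the
#'     structure, e.g. `"D2%"`, `"D95%"`.}
#'   \item{`"D<v>cc"`}{minimum dose received by the hottest v cc, e.g.
#'     `"D0.03cc"`.}
#'   \item{`"V<d>Gy"`}{volume (cc) receiving at least d Gy.}
#'   \item{`"Dmean"`}{raw-voxel mean dose (stored at DVH construction).}
#' }
#' Dose queries resolve to the highest bin edge still covering the
#' requested volume (ties toward the higher-dose edge), so they are exact
#' for plateaued (step) dose distributions and accurate to one bin width
#' in general; volume queries interpolate linearly between edges.
#'
#' @param dvh a [dvh].
#' @param query a query string (see details), or several.
#' @return named numeric vector, Gy for D queries and cc for V queries.
#' @examples
#' \dontrun{dvh_query(d, c("D2%", "D98%", "D50%", "D0.03cc", "Dmean"))}
#' @export
dvh_query <- function(dvh, query) {
  stopifnot(inherits(dvh, "dvh"))
  out <- vapply(query, function(q) dvh_query_one(dvh, q), numeric(1))
  stats::setNames(out, query)
}

dvh_query_one <- function(dvh, q) {
  if (grepl("^[Dd]mean$", q)) return(dvh$mean_gy)
  m <- regmatches(q, regexec("^[Dd]([0-9.]+)%$", q))[[1]]
  if (length(m) == 2L)
    return(d_at_volume(dvh, as.numeric(m[2]) / 100 * dvh$volume_total_cc))
  m <- regmatches(q, regexec("^[Dd]([0-9.]+)cc$", q))[[1]]
  if (length(m) == 2L) return(d_at_volume(dvh, as.numeric(m[2])))
  m <- regmatches(q, regexec("^[Vv]([0-9.]+)[Gg]y$", q))[[1]]
  if (length(m) == 2L) return(v_at_dose(dvh, as.numeric(m[2])))
  stop("unrecognized DVH query: ", q, call. = FALSE)
}

#' Dose covering a given absolute volume
#'
#' The highest dose `d` such that at least `volume_cc` of the structure
#' receives `d` or more, resolved on the DVH bin grid (ties toward the
#' higher-dose edge).
#'
#' @param dvh a [dvh].
#' @param volume_cc requested volume in cc (0 < volume <= structure
#'   volume).
#' @return dose in Gy.
#' @export
d_at_volume <- function(dvh, volume_cc) {
  stopifnot(inherits(dvh, "dvh"))
  stop_if(!is_number(volume_cc) || volume_cc <= 0,
          "volume_cc must be positive")
  stop_if(volume_cc > dvh$volume_total_cc + 1e-9,
          sprintf("requested volume %.3f cc exceeds structure volume %.3f cc",
                  volume_cc, dvh$volume_total_cc))
  k <- which(dvh$volume_cc >= volume_cc - 1e-12)
  dvh$dose_gy[max(k)]
}

#' Volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative curve between bin edges.
#'
#' @param dvh a [dvh].
#' @param dose_gy dose threshold in Gy.
#' @return volume in cc.
#' @export
v_at_dose <- function(dvh, dose_gy) {
  stopifnot(inherits(dvh, "dvh"))
  if (dose_gy <= 0) return(dvh$volume_total_cc)
  if (dose_gy >= max(dvh$dose_gy)) {
    return(if (dose_gy > max(dvh$dose_gy)) 0 else
      dvh$volume_cc[length(dvh$volume_cc)])
  }
  stats::approx(dvh$dose_gy, dvh$volume_cc, xout = dose_gy,
                method = "linear", ties = "ordered")$y
}

#' Rescale a dose grid so the prescription covers 95% of the PTV
#'
#' Applies the plan normalization rule: the dose is scaled by
#' `rx / D_cov%(PTV)` so that 100% of the prescription dose covers
#' `coverage`% of the PTV. The coverage dose is computed from the raw
#' voxel doses (order statistic), so the post-condition
#' `D_cov%(PTV) == rx` holds exactly on the voxel grid.
#'
#' @param dose a [dose_grid].
#' @param ptv the PTV [structure_mask].
#' @param rx prescription dose in Gy.
#' @param coverage covered fraction of the PTV, percent (default 95).
#' @return the rescaled [dose_grid], with attribute `scale`.
#' @export
normalize_to_coverage <- function(dose, ptv, rx, coverage = 95) {
  stop_if(!inherits(dose, "dose_grid"), "dose must be a dose_grid")
  stop_if(!inherits(ptv, "structure_mask"), "ptv must be a structure_mask")
  stop_if(sum(ptv$mask) == 0, "empty PTV")
  d_cov <- coverage_dose(dose$values[ptv$mask], coverage)
  stop_if(d_cov <= 0, "coverage dose is zero; cannot normalize")
  out <- dose_grid(dose$values * (rx / d_cov), dose$spacing, dose$origin)
  attr(out, "scale") <- rx / d_cov
  out
}

# largest dose d with #\{voxels >= d\} >= coverage% of the voxels
coverage_dose <- function(doses, coverage = 95) {
  n <- length(doses)
  k <- n - ceiling(coverage / 100 * n) + 1L
  sort(doses, partial = k)[k]
}

#' PTV conformity, homogeneity and gradient indices
#'
#' \deqn{CN = \frac{V_{T,ref}}{V_T} \times \frac{V_{T,ref}}{V_{ref}}}
#' where \eqn{V_T} is the PTV volume, \eqn{V_{ref}} the total volume
#' (anywhere in the grid) covered by the prescription dose and
#' \eqn{V_{T,ref}} the PTV volume covered by the prescription dose; CN
#' approaches 1 for highly conformal plans.
#' \deqn{HI = (D_{2\%} - D_{98\%}) / D_{50\%}} on the PTV; 0 for a
#' perfectly homogeneous target dose.
#' \deqn{GI = V_{50\%} / V_{100\%}} with \eqn{V_{y\%}} the total volume
#' receiving y% of the prescription; close to 1 for a steep dose
#' gradient.
#'
#' Covered volumes are exact voxel counts over the whole grid (no DVH
#' binning); the HI dose points come from the PTV DVH at `bin_gy`
#' resolution.
#'
#' @param dose a [dose_grid] (already normalized; see
#'   [normalize_to_coverage()] and the `normalize` switch).
#' @param ptv the PTV [structure_mask].
#' @param rx prescription dose in Gy.
#' @param normalize if `TRUE`, apply the 95%-coverage normalization before
#'   evaluating the indices.
#' @param bin_gy DVH bin width for the HI dose points.
#' @return named numeric vector with `CN`, `HI`, `GI` (plus `D2`, `D98`,
#'   `D50`, `V100_cc`, `V50_cc` as attributes of the computation in a list
#'   when `detail = TRUE`).
#' @param detail return the intermediate volumes/doses too.
#' @export
ptv_indices <- function(dose, ptv, rx, normalize = FALSE, bin_gy = 0.01,
                        detail = FALSE) {
  stop_if(!inherits(dose, "dose_grid"), "dose must be a dose_grid")
  stop_if(!inherits(ptv, "structure_mask"), "ptv must be a structure_mask")
  stop_if(!identical(dim(ptv$mask), dim(dose$values)),
          "PTV mask and dose grid are not congruent")
  if (normalize) dose <- normalize_to_coverage(dose, ptv, rx)
  vv <- voxel_volume_cc(dose)
  vt <- sum(ptv$mask) * vv
  stop_if(vt == 0, "empty PTV")
  covered <- dose$values >= rx
  v_ref <- sum(covered) * vv
  v_t_ref <- sum(covered & ptv$mask) * vv
  cn <- if (v_ref == 0) 0 else (v_t_ref / vt) * (v_t_ref / v_ref)
  v100 <- v_ref
  v50 <- sum(dose$values >= rx / 2) * vv
  stop_if(v100 == 0, "V100% is zero; GI undefined")
  gi <- v50 / v100
  d <- compute_dvh(dose, ptv, bin_gy = bin_gy)
  q <- dvh_query(d, c("D2%", "D98%", "D50%"))
  hi <- (q[["D2%"]] - q[["D98%"]]) / q[["D50%"]]
  out <- c(CN = cn, HI = hi, GI = gi)
  if (detail) {
    return(list(indices = out, v_t = vt, v_ref = v_ref, v_t_ref = v_t_ref,
                v50_cc = v50, d2 = q[["D2%"]], d98 = q[["D98%"]],
                d50 = q[["D50%"]]))
  }
  out
}
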