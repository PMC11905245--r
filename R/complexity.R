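# MU-weighted MLC aperture complexity metrics: the modulation complexity
# score family (LSV / AAV / MCS) and the aperture-geometry family
# (AA / AP / AI aggregated to beam and plan level with MU weights).

# single-bank LSV factor.  pos_max is the within-bank spread at this CP;
# a zero-spread bank (all leaves aligned) contributes 1 by convention so
# the modulation-free limit reaches MCS = 1.
lsv_bank <- function(pos) {
  n <- length(pos)
  if (n < 2L) return(1)
  spread <- max(pos) - min(pos)
  if (spread <= 0) return(1)
  sum(spread - abs(diff(pos))) / ((n - 1) * spread)
}

#' Leaf sequence variability at a control point
#'
#' The LSV of the aperture: for each bank,
#' \deqn{\sum_{n=1}^{N-1} (pos_{max} - |pos_n - pos_{n+1}|) /
#'   ((N-1)\, pos_{max})}
#' with \eqn{pos_{max}} the within-bank position spread at this control
#' point, and the two bank factors multiplied. A bank whose leaves are all
#' aligned (zero spread) contributes a factor of 1. Only in-field leaf
#' pairs should be supplied (see `in_field` to restrict).
#'
#' @param mlc an [mlc_positions] object.
#' @param in_field optional logical vector selecting the leaf pairs exposed
#'   in the field; default uses all pairs.
#' @return LSV in `[0, 1]`.
#' @examples
#' lsv_cp(mlc_positions(c(0, 5, 10), c(20, 25, 30)))  # 0.25
#' @export
lsv_cp <- function(mlc, in_field = NULL) {
  stopifnot(inherits(mlc, "mlc_positions"))
  l <- mlc$left; r <- mlc$right
  if (!is.null(in_field)) {
    l <- l[in_field]; r <- r[in_field]
  }
  if (length(l) < 1L) return(1)
  lsv_bank(l) * lsv_bank(r)
}

#' Per-leaf maximum openings over an arc
#'
#' For each leaf pair, the largest opening attained at any control point of
#' the arc: the denominator terms of the aperture area variability.
#'
#' @param arc a [vmat_arc].
#' @return numeric vector, one maximum opening (mm) per leaf pair.
#' @export
arc_max_openings <- function(arc) {
  stopifnot(inherits(arc, "vmat_arc"))
  op <- vapply(arc$control_points, function(cp) openings(cp$mlc),
               numeric(length(arc$control_points[[1]]$mlc$left)))
  op <- matrix(op, ncol = length(arc$control_points))
  apply(op, 1L, max)
}

#' Aperture area variability at a control point
#'
#' The summed per-leaf openings at this control point divided by the summed
#' per-leaf maximum openings over the whole arc the control point belongs
#' to. Equals 1 when every leaf pair is at its arc-maximal opening. If the
#' arc never opens (zero denominator) the value is 1 by convention and the
#' result carries attribute `degenerate = TRUE`.
#'
#' @param mlc an [mlc_positions] object.
#' @param max_openings per-leaf maximum openings over the arc, as returned
#'   by [arc_max_openings()].
#' @return AAV in `[0, 1]`.
#' @export
aav_cp <- function(mlc, max_openings) {
  stopifnot(inherits(mlc, "mlc_positions"))
  stop_if(length(max_openings) != length(mlc$left),
          "max_openings must have one value per leaf pair")
  denom <- sum(pmax(max_openings, 0))
  if (denom <= 0) return(structure(1, degenerate = TRUE))
  sum(pmax(openings(mlc), 0)) / denom
}

# LSV and AAV for every control point of an arc.  In-field leaf pairs are
# those that open beyond closed_gap at some control point of the arc;
# permanently parked pairs are excluded from the LSV banks (they carry no
# exposed leaf edge) and contribute nothing to the AAV sums.
arc_variability <- function(arc, closed_gap = 0.5) {
  maxop <- arc_max_openings(arc)
  in_field <- maxop > closed_gap
  lsv <- vapply(arc$control_points, function(cp)
    lsv_cp(cp$mlc, in_field = in_field), numeric(1))
  denom <- sum(maxop[in_field])
  aav <- vapply(arc$control_points, function(cp) {
    if (denom <= 0) return(1)
    sum(pmax(openings(cp$mlc)[in_field], 0)) / denom
  }, numeric(1))
  list(lsv = lsv, aav = aav, in_field = in_field)
}

#' Modulation complexity score of an arc
#'
#' \deqn{MCS_{arc} = \sum_{i=1}^{I-1} \frac{AAV_i + AAV_{i+1}}{2}\,
#'   \frac{LSV_i + LSV_{i+1}}{2}\, \frac{MU_{i,i+1}}{MU_{arc}}}
#'
#' @param arc a [vmat_arc].
#' @param closed_gap openings at or below this value (mm) count as closed
#'   when deciding which leaf pairs are in-field.
#' @return a list with `mcs_arc`, and per-control-point `lsv` and `aav`.
#' @export
mcs_arc <- function(arc, closed_gap = 0.5) {
  stopifnot(inherits(arc, "vmat_arc"))
  v <- arc_variability(arc, closed_gap)
  mu <- segment_mu(arc)
  i <- seq_along(mu)
  m <- sum((v$aav[i] + v$aav[i + 1]) / 2 * (v$lsv[i] + v$lsv[i + 1]) / 2 *
             mu / arc$arc_mu)
  list(mcs_arc = m, lsv = v$lsv, aav = v$aav)
}

#' Modulation complexity score of a plan
#'
#' The plan score is the unweighted mean of the per-arc scores,
#' \eqn{MCS_v = (1/K) \sum_k MCS_{arc,k}}. It approaches 0 for heavily
#' modulated plans; a value of 1 indicates no modulation (every control
#' point at maximal, uniform aperture). Note the arc average is the plain
#' \eqn{1/K} mean, not MU-weighted; some of the complexity literature
#' weights by arc MU instead.
#'
#' @param plan a [vmat_plan].
#' @param closed_gap closed-pair threshold (mm).
#' @return a list with `mcs_v`, vector `mcs_arc`, and a `per_arc` list of
#'   per-control-point LSV/AAV values.
#' @examples
#' mlc1 <- mlc_positions(c(-10, -10), c(10, 10))
#' cps <- list(control_point(0, mlc1, 0), control_point(90, mlc1, 1))
#' mcs_plan(vmat_plan(list(vmat_arc(cps, 100))))$mcs_v  # 1: no modulation
#' @export
mcs_plan <- function(plan, closed_gap = 0.5) {
  stopifnot(inherits(plan, "vmat_plan"))
  per <- lapply(plan$arcs, mcs_arc, closed_gap = closed_gap)
  m <- vapply(per, `[[`, numeric(1), "mcs_arc")
  list(mcs_v = mean(m), mcs_arc = m, per_arc = per)
}

#' Beam-level aperture metrics of an arc
#'
#' MU-weighted aggregates of the control-point aperture geometry:
#' \deqn{BA = \sum_j MU_j AA_j / MU_{arc}, \quad
#'       BI = \sum_j MU_j AI_j / MU_{arc}, \quad
#'       BM = 1 - \sum_j MU_j AA_j / (MU_{arc}\, U)}
#' where \eqn{U} is the area of the union of all apertures in the arc.
#'
#' The table formulas index apertures by control point but MU by segment.
#' With `attribution = "segment-mean"` (default) each segment takes the
#' mean area/irregularity of its two bounding control points, consistent
#' with the pairwise-average structure of the MCS arc sum; with
#' `attribution = "per-cp"` each control point receives half the MU of its
#' adjacent segments. Segments (or control points) with a fully closed
#' aperture have undefined irregularity and are excluded from the BI
#' average, whose weights are renormalized accordingly.
#'
#' @param arc a [vmat_arc].
#' @param closed_gap closed-pair threshold (mm).
#' @param attribution how segment MU maps onto control-point apertures.
#' @return a list with `ba` (mm^2), `bi`, `bm`, `u` (union area, mm^2) and
#'   `mu` (arc meterset).
#' @export
beam_metrics <- function(arc, closed_gap = 0.5,
                         attribution = c("segment-mean", "per-cp")) {
  stopifnot(inherits(arc, "vmat_arc"))
  attribution <- match.arg(attribution)
  geoms <- lapply(arc$control_points, function(cp)
    aperture_geometry_cp(cp$mlc, closed_gap))
  aa <- vapply(geoms, `[[`, numeric(1), "area")
  ai <- vapply(geoms, `[[`, numeric(1), "irregularity")
  stop_if(all(aa == 0), "degenerate beam: all apertures closed")
  mu_seg <- segment_mu(arc)
  if (attribution == "segment-mean") {
    i <- seq_along(mu_seg)
    w <- mu_seg
    aa_w <- (aa[i] + aa[i + 1]) / 2
    ai_w <- vapply(i, function(j) {
      v <- c(ai[j], ai[j + 1])
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  } else {
    ii <- seq_along(aa)
    w <- (c(0, mu_seg) + c(mu_seg, 0)) / 2
    aa_w <- aa
    ai_w <- ai
  }
  mu_arc <- arc$arc_mu
  ba <- sum(w * aa_w) / mu_arc
  def <- !is.na(ai_w)
  stop_if(!any(def & w > 0), "degenerate beam: no open MU-carrying segment")
  bi <- sum(w[def] * ai_w[def]) / sum(w[def])
  u <- aperture_union_area(lapply(arc$control_points, `[[`, "mlc"),
                           closed_gap)
  bm <- 1 - sum(w * aa_w) / (mu_arc * u)
  if (abs(bm) < 1e-9) bm <- 0  # shave float noise off the zero bound
  list(ba = ba, bi = bi, bm = bm, u = u, mu = mu_arc)
}

#' All complexity metrics of a plan
#'
#' Computes the full MU-weighted complexity profile: the modulation
#' complexity score `mcs_v` with per-arc detail, and the plan-averaged
#' area, irregularity and modulation
#' \deqn{PA = \sum_i BA_i MU_i / MU_p,\quad PI = \sum_i BI_i MU_i / MU_p,
#'       \quad PM = \sum_i BM_i MU_i / MU_p.}
#'
#' @param plan a [vmat_plan].
#' @param closed_gap closed-pair threshold (mm).
#' @param attribution see [beam_metrics()].
#' @return an object of class `plan_complexity`: a list with `mcs_v`,
#'   `total_mu`, `pa`, `pi`, `pm` and `per_arc` (per-arc `mcs_arc`, `lsv`,
#'   `aav`, `ba`, `bi`, `bm`, `u`).
#' @examples
#' mlc <- mlc_positions(rep(-20, 8), rep(20, 8))
#' cps <- list(control_point(0, mlc, 0), control_point(180, mlc, 1))
#' pc <- plan_complexity(vmat_plan(list(vmat_arc(cps, 300))))
#' c(pc$mcs_v, pc$pm)  # 1 and 0: a static aperture has no modulation
#' @export
plan_complexity <- function(plan, closed_gap = 0.5,
                            attribution = c("segment-mean", "per-cp")) {
  stopifnot(inherits(plan, "vmat_plan"))
  attribution <- match.arg(attribution)
  mcs <- mcs_plan(plan, closed_gap)
  beams <- lapply(plan$arcs, beam_metrics, closed_gap = closed_gap,
                  attribution = attribution)
  mu_i <- vapply(plan$arcs, `[[`, numeric(1), "arc_mu")
  mu_p <- sum(mu_i)
  agg <- function(field)
    sum(vapply(beams, `[[`, numeric(1), field) * mu_i) / mu_p
  per_arc <- lapply(seq_along(beams), function(k) list(
    mcs_arc = mcs$mcs_arc[k],
    lsv = mcs$per_arc[[k]]$lsv,
    aav = mcs$per_arc[[k]]$aav,
    ba = beams[[k]]$ba, bi = beams[[k]]$bi, bm = beams[[k]]$bm,
    u = beams[[k]]$u, mu = mu_i[k]
  ))
  structure(
    list(mcs_v = mcs$mcs_v, total_mu = mu_p,
         pa = agg("ba"), pi = agg("bi"), pm = agg("bm"),
         per_arc = per_arc),
    class = "plan_complexity"
  )
}

#' @export
print.plan_complexity <- function(x, ...) {
  cat("<plan_complexity>\n")
  cat(sprintf("  MCSv = %.4f   MU = %.1f\n", x$mcs_v, x$total_mu))
  cat(sprintf("  PA = %.2f mm^2 (%.2f cm^2)   PI = %.2f   PM = %.4f\n",
              x$pa, x$pa / 100, x$pi, x$pm))
  for (k in seq_along(x$per_arc)) {
    a <- x$per_arc[[k]]
    cat(sprintf(
      "  arc %d: MCS = %.4f, BA = %.1f mm^2, BI = %.2f, BM = %.4f, MU = %.1f\n",
      k, a$mcs_arc, a$ba, a$bi, a$bm, a$mu))
  }
  invisible(x)
}

#' Per-plan complexity metrics as a one-row data frame
#'
#' @param x a `plan_complexity` object.
#' @param ... unused.
#' @return a one-row data.frame with columns `MCSv`, `MU`, `PA`, `PI`,
#'   `PM` (`PA` in mm^2).
#' @export
as.data.frame.plan_complexity <- function(x, ...) {
  data.frame(MCSv = x$mcs_v, MU = x$total_mu, PA = x$pa, PI = x$pi,
             PM = x$pm)
}
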