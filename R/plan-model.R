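#' Control point of a VMAT arc
#'
#' A snapshot of machine state along an arc: gantry angle, MLC aperture,
#' cumulative meterset weight and collimator angle. Segments of delivery lie
#' between consecutive control points; the MU delivered in segment
#' \eqn{(i, i+1)} is the weight difference times the arc meterset.
#'
#' @param gantry_deg gantry angle in degrees, reduced to `[0, 360)`.
#' @param mlc an [mlc_positions] object.
#' @param cum_weight cumulative meterset weight in `[0, 1]`.
#' @param collimator_deg collimator (beam-limiting device) angle, degrees.
#' @return an object of class `control_point`.
#' @export
control_point <- function(gantry_deg, mlc, cum_weight, collimator_deg = 0) {
  stop_if(!is_number(gantry_deg), "gantry_deg must be a single number")
  stop_if(!inherits(mlc, "mlc_positions"), "mlc must be an mlc_positions object")
  stop_if(!is_number(cum_weight) || cum_weight < -1e-9 || cum_weight > 1 + 1e-9,
          "cum_weight must lie in [0, 1]")
  structure(
    list(gantry_deg = gantry_deg %% 360, mlc = mlc,
         cum_weight = min(max(cum_weight, 0), 1),
         collimator_deg = collimator_deg %% 360),
    class = "control_point"
  )
}

#' A full VMAT arc
#'
#' An ordered sequence of control points with a total arc meterset.
#' The arc increment is the sector width the optimizer used when the plan
#' was created: the gantry rotation is split into sectors of this width and
#' the leaves reverse travel direction at each internal sector boundary, so
#' a 360 degree arc with sector width `increment_deg` has
#' `360 / increment_deg` sectors and one fewer internal reversals. Both
#' counts are recorded on the object.
#'
#' @param control_points list of [control_point] objects, length >= 2, with
#'   nondecreasing cumulative weights starting at 0 and ending at 1.
#' @param arc_mu total monitor units (MU) for the arc, positive.
#' @param increment_deg arc increment (sector width) metadata, degrees;
#'   the plans modelled here use 15 or 30.
#' @param direction `"CW"` or `"CCW"` gantry rotation.
#' @return an object of class `vmat_arc`.
#' @seealso [segment_mu()], [vmat_plan()]
#' @export
vmat_arc <- function(control_points, arc_mu, increment_deg = 30,
                     direction = c("CW", "CCW")) {
  direction <- match.arg(direction)
  stop_if(!is.list(control_points) || length(control_points) < 2L,
          "an arc needs at least 2 control points")
  ok <- vapply(control_points, inherits, logical(1), "control_point")
  stop_if(!all(ok), "control_points must all be control_point objects")
  stop_if(!is_number(arc_mu) || arc_mu <= 0, "arc_mu must be positive")
  stop_if(!is_number(increment_deg) || increment_deg <= 0 ||
            increment_deg > 360,
          "increment_deg must be in (0, 360]")
  w <- vapply(control_points, `[[`, numeric(1), "cum_weight")
  bad <- which(diff(w) < -1e-9)
  stop_if(length(bad) > 0,
          "cumulative meterset weights must be nondecreasing; violated at ",
          "control point ", bad[1] + 1L)
  stop_if(abs(w[1]) > 1e-9, "first cumulative weight must be 0")
  stop_if(abs(w[length(w)] - 1) > 1e-9, "last cumulative weight must be 1")
  n_lv <- vapply(control_points, function(cp) length(cp$mlc$left), integer(1))
  stop_if(length(unique(n_lv)) != 1L,
          "all control points in an arc must have the same leaf count")
  n_sectors <- round(360 / increment_deg)
  structure(
    list(control_points = control_points, arc_mu = arc_mu,
         increment_deg = increment_deg, direction = direction,
         n_sectors = n_sectors, n_reversals = max(n_sectors - 1L, 0L)),
    class = "vmat_arc"
  )
}

#' @export
print.vmat_arc <- function(x, ...) {
  cat(sprintf(
    "<vmat_arc> %d control points, %.1f MU, increment %g deg (%s), %d sectors\n",
    length(x$control_points), x$arc_mu, x$increment_deg, x$direction,
    x$n_sectors))
  invisible(x)
}

#' A VMAT plan
#'
#' One or more arcs plus prescription metadata. The cohort design modelled
#' here uses dual full arcs per plan with arc-increment combinations
#' 30/30 (group A), 15/15 (group B) and 30/15 (group C), prescribed
#' 70 Gy in 35 fractions.
#'
#' @param arcs list of [vmat_arc] objects, length >= 1.
#' @param prescription_gy prescription dose in Gy.
#' @param fractions number of fractions.
#' @param group group label (`"A"`, `"B"`, `"C"` or `NA`).
#' @param patient_id patient identifier.
#' @return an object of class `vmat_plan`.
#' @examples
#' mlc <- mlc_positions(rep(-20, 5), rep(20, 5))
#' cps <- list(control_point(0, mlc, 0), control_point(180, mlc, 1))
#' plan <- vmat_plan(list(vmat_arc(cps, arc_mu = 300)))
#' plan_mu(plan)
#' @export
vmat_plan <- function(arcs, prescription_gy = 70, fractions = 35,
                      group = NA_character_, patient_id = NA_character_) {
  stop_if(!is.list(arcs) || length(arcs) < 1L, "a plan needs at least one arc")
  ok <- vapply(arcs, inherits, logical(1), "vmat_arc")
  stop_if(!all(ok), "arcs must all be vmat_arc objects")
  stop_if(!is_number(prescription_gy) || prescription_gy <= 0,
          "prescription_gy must be positive")
  stop_if(!is_number(fractions) || fractions < 1,
          "fractions must be a positive count")
  structure(
    list(arcs = arcs, prescription_gy = prescription_gy,
         fractions = fractions, group = as.character(group),
         patient_id = as.character(patient_id)),
    class = "vmat_plan"
  )
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("<vmat_plan> %s / group %s: %d arc(s), %.1f MU, %g Gy / %g fx\n",
              x$patient_id, x$group, length(x$arcs), plan_mu(x),
              x$prescription_gy, x$fractions))
  for (a in x$arcs) print(a)
  invisible(x)
}

#' Total plan monitor units
#'
#' @param plan a [vmat_plan].
#' @return the sum of the arc metersets (MU).
#' @export
plan_mu <- function(plan) {
  stopifnot(inherits(plan, "vmat_plan"))
  sum(vapply(plan$arcs, `[[`, numeric(1), "arc_mu"))
}

#' Per-segment monitor units of an arc
#'
#' Segment \eqn{j} lies between control points \eqn{j} and \eqn{j+1} and
#' delivers \eqn{(w_{j+1} - w_j) \times MU_{arc}}. The segment MUs sum to
#' the arc meterset exactly.
#'
#' @param arc a [vmat_arc].
#' @return numeric vector of length `I - 1` (MU per segment).
#' @examples
#' mlc <- mlc_positions(-10, 10)
#' cps <- list(control_point(0, mlc, 0), control_point(90, mlc, 0.5),
#'             control_point(180, mlc, 1))
#' segment_mu(vmat_arc(cps, arc_mu = 200))  # 100 100
#' @export
segment_mu <- function(arc) {
  stopifnot(inherits(arc, "vmat_arc"))
  w <- vapply(arc$control_points, `[[`, numeric(1), "cum_weight")
  diff(w) * arc$arc_mu
}

# gantry span of an arc in degrees, accumulated along the rotation
# direction (angles are stored reduced to [0, 360))
arc_gantry_span <- function(arc) {
  g <- vapply(arc$control_points, `[[`, numeric(1), "gantry_deg")
  step <- diff(g)
  if (arc$direction == "CW") step <- step %% 360 else step <- (-step) %% 360
  # a full arc sampled at spacing s has steps of s; a wrapped value of 0
  # only occurs for coincident consecutive angles
  sum(step)
}

#' Validate a plan against the metric-readiness invariants
#'
#' Checks every structural invariant the metric pipeline relies on: at
#' least one arc, positive MU, >= 2 control points per arc, nondecreasing
#' cumulative weights anchored at 0 and 1, nonnegative leaf openings,
#' full 360 degree gantry span per arc, and study-shaped prescription
#' metadata. Violations are reported, not raised.
#'
#' @param plan a [vmat_plan] (or any object; a non-plan is itself a
#'   violation).
#' @return an object of class `plan_validation`: a data.frame with columns
#'   `where` and `problem`. Zero rows means the plan is metric-ready.
#' @export
validate_plan <- function(plan) {
  issues <- list()
  add <- function(where, problem)
    issues[[length(issues) + 1L]] <<- data.frame(where = where,
                                                 problem = problem)
  if (!inherits(plan, "vmat_plan")) {
    add("plan", "not a vmat_plan object")
  } else {
    if (length(plan$arcs) < 1L) add("plan", "no arcs (K = 0)")
    if (plan_mu(plan) <= 0) add("plan", "total MU not positive")
    if (plan$prescription_gy <= 0) add("plan", "prescription not positive")
    for (k in seq_along(plan$arcs)) {
      arc <- plan$arcs[[k]]
      lab <- sprintf("arc %d", k)
      if (length(arc$control_points) < 2L) {
        add(lab, "fewer than 2 control points")
        next
      }
      w <- vapply(arc$control_points, `[[`, numeric(1), "cum_weight")
      if (any(diff(w) < -1e-9))
        add(lab, sprintf("non-monotone cumulative weight at CP %d",
                         which(diff(w) < -1e-9)[1] + 1L))
      if (abs(w[1]) > 1e-9) add(lab, "first cumulative weight not 0")
      if (abs(w[length(w)] - 1) > 1e-9) add(lab, "last cumulative weight not 1")
      if (arc$arc_mu <= 0) add(lab, "arc MU not positive")
      if (!arc$increment_deg %in% c(15, 30))
        add(lab, sprintf("arc increment %g outside {15, 30}",
                         arc$increment_deg))
      span <- arc_gantry_span(arc)
      if (abs(span - 360) > 1e-6)
        add(lab, sprintf("gantry span %.2f deg, not a full 360 arc", span))
      for (i in seq_along(arc$control_points)) {
        opn <- openings(arc$control_points[[i]]$mlc)
        if (any(opn < 0))
          add(sprintf("%s CP %d", lab, i), "negative opening (right < left)")
      }
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(where = character(), problem = character())
  class(out) <- c("plan_validation", "data.frame")
  out
}

#' @export
print.plan_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("plan OK: no invariant violations\n")
  } else {
    cat(sprintf("%d invariant violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  - [%s] %s\n", x$where[i], x$problem[i]))
  }
  invisible(x)
}
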