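#' Read a plan from the JSON fixture dialect
#'
#' The fixture dialect is a plain-JSON serialization of a [vmat_plan]:
#' \preformatted{
#' {"patient_id": ..., "group": ..., "prescription_gy": 70, "fractions": 35,
#'  "arcs": [{"increment_deg": 30, "direction": "CW", "arc_mu": 620,
#'            "control_points": [{"gantry_deg": 0, "cum_weight": 0,
#'                                "collimator_deg": 45,
#'                                "left_mm": [...], "right_mm": [...]}, ...]}]}
#' }
#' A machine-readable schema ships at
#' `system.file("extdata", "plan-schema.json", package = "vmatmetrics")`.
#' If `group` is absent it is inferred from the arc increments:
#' 30/30 is group A, 15/15 group B, and a mixed 30/15 combination group C.
#'
#' @param path path to a JSON fixture file.
#' @param leaf_width leaf-pair width (mm) used for the MLC snapshots.
#' @return a [vmat_plan].
#' @export
load_plan_fixture <- function(path, leaf_width = 5) {
  stop_if(!file.exists(path), "no such file: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  plan_from_fixture_list(x, leaf_width = leaf_width)
}

plan_from_fixture_list <- function(x, leaf_width = 5) {
  required <- c("prescription_gy", "fractions", "arcs")
  missing_keys <- setdiff(required, names(x))
  stop_if(length(missing_keys) > 0,
          "plan fixture is missing required key(s): ",
          paste(missing_keys, collapse = ", "))
  stop_if(length(x$arcs) == 0, "plan fixture has an empty arcs list")
  arcs <- lapply(seq_along(x$arcs), function(k) {
    a <- x$arcs[[k]]
    need <- c("increment_deg", "arc_mu", "control_points")
    miss <- setdiff(need, names(a))
    stop_if(length(miss) > 0, sprintf("arc %d missing key(s): %s", k,
                                      paste(miss, collapse = ", ")))
    stop_if(length(a$control_points) < 2L,
            sprintf("arc %d has fewer than 2 control points", k))
    cps <- lapply(seq_along(a$control_points), function(i) {
      cp <- a$control_points[[i]]
      need_cp <- c("gantry_deg", "cum_weight", "left_mm", "right_mm")
      miss_cp <- setdiff(need_cp, names(cp))
      stop_if(length(miss_cp) > 0,
              sprintf("arc %d CP %d missing key(s): %s", k, i,
                      paste(miss_cp, collapse = ", ")))
      control_point(
        gantry_deg = cp$gantry_deg,
        mlc = mlc_positions(unlist(cp$left_mm), unlist(cp$right_mm),
                            leaf_width = x$leaf_width_mm %||% leaf_width),
        cum_weight = cp$cum_weight,
        collimator_deg = cp$collimator_deg %||% 0
      )
    })
    vmat_arc(cps, arc_mu = a$arc_mu, increment_deg = a$increment_deg,
             direction = a$direction %||% "CW")
  })
  group <- x$group %||% infer_group(
    vapply(arcs, `[[`, numeric(1), "increment_deg"))
  vmat_plan(arcs, prescription_gy = x$prescription_gy,
            fractions = x$fractions, group = group,
            patient_id = x$patient_id %||% NA_character_)
}

#' Infer the arc-increment group label from per-arc increments
#'
#' @param increments numeric vector of arc increments (degrees).
#' @return `"A"` for 30/30, `"B"` for 15/15, `"C"` for a mix of 30 and 15,
#'   otherwise `NA`.
#' @export
infer_group <- function(increments) {
  s <- sort(unique(increments))
  if (identical(s, 30)) return("A")
  if (identical(s, 15)) return("B")
  if (identical(s, c(15, 30))) return("C")
  NA_character_
}

#' Write a plan to the JSON fixture dialect
#'
#' Inverse of [load_plan_fixture()]: `load_plan_fixture(write_plan_fixture(p,
#' f))` reproduces `p` up to numeric serialization (17 significant digits).
#'
#' @param plan a [vmat_plan].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_fixture <- function(plan, path) {
  stopifnot(inherits(plan, "vmat_plan"))
  x <- list(
    patient_id = plan$patient_id,
    group = plan$group,
    prescription_gy = plan$prescription_gy,
    fractions = plan$fractions,
    leaf_width_mm = plan$arcs[[1]]$control_points[[1]]$mlc$leaf_width,
    arcs = lapply(plan$arcs, function(a) list(
      increment_deg = a$increment_deg,
      direction = a$direction,
      arc_mu = a$arc_mu,
      control_points = lapply(a$control_points, function(cp) list(
        gantry_deg = cp$gantry_deg,
        cum_weight = cp$cum_weight,
        collimator_deg = cp$collimator_deg,
        left_mm = cp$mlc$left,
        right_mm = cp$mlc$right
      ))
    ))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}
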