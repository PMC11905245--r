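# Seeded synthetic cohort emulating the dual-arc head-and-neck study
# design: per patient, three paired plans (arc-increment groups A = 30/30,
# B = 15/15, C = 30/15) plus analytic dose phantoms with structure masks.
# The phantoms are analytic fields, not beam transport: the group effect
# is injected through the radial dose-falloff length outside the PTV.

#' Anatomy table of the modelled head-and-neck cohort
#'
#' Structure volumes and PTV center-to-center distances for ten
#' head-and-neck patients (hypopharynx/oropharynx/nasopharynx/larynx
#' sites): the envelope within which the cohort generator samples
#' synthetic anatomies.
#'
#' @return data.frame with one row per patient: structure volumes (cc) and
#'   center-to-center distances to the PTV (cm).
#' @export
hn_anatomy <- function() {
  f <- system.file("extdata", "hn_anatomy.csv", package = "vmatmetrics",
                   mustWork = TRUE)
  utils::read.csv(f)
}

# min/max sampling ranges derived from the anatomy table
anatomy_ranges <- function() {
  a <- hn_anatomy()
  num <- a[, setdiff(names(a), c("patient", "site"))]
  list(min = vapply(num, min, numeric(1)),
       max = vapply(num, max, numeric(1)))
}

#' Specification of a synthetic paired cohort
#'
#' Bundles every tunable of the generator. The defaults are the modelled
#' study conditions: 10 patients, three plans each (30/30, 15/15, 30/15),
#' 70 Gy in 35 fractions, 3 degree control-point spacing, 2 mm dose grid,
#' anatomies sampled within the ranges of [hn_anatomy()].
#'
#' @param n_patients number of synthetic patients.
#' @param seed integer master seed; all randomness derives from it.
#' @param groups named list of per-group arc-increment pairs (degrees).
#' @param cp_spacing control-point spacing in degrees; must divide each
#'   increment.
#' @param modulation_level leaf-sweep modulation in `[0, 1]` (0 = static
#'   aperture).
#' @param prescription_gy,fractions prescription.
#' @param n_leaf_pairs,leaf_width_mm MLC layout.
#' @param falloff_mm named per-group exponential dose-falloff length
#'   outside the PTV (mm); the smaller group-C value injects the
#'   organ-at-risk sparing effect.
#' @param homogeneity relative amplitude of the intra-PTV dose ripple
#'   (drives the homogeneity index; 0 gives a perfectly flat target dose).
#' @param falloff_sd lognormal sd of the per-plan falloff jitter.
#' @param dose_sd lognormal sd of the per-plan global output jitter.
#' @param grid_spacing_mm dose grid resolution (mm).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10, seed = 1,
                        groups = list(A = c(30, 30), B = c(15, 15),
                                      C = c(30, 15)),
                        cp_spacing = 3, modulation_level = 0.5,
                        prescription_gy = 70, fractions = 35,
                        n_leaf_pairs = 40, leaf_width_mm = 5,
                        falloff_mm = c(A = 33, B = 30, C = 23),
                        homogeneity = 0.03, falloff_sd = 0.08,
                        dose_sd = 0.03, grid_spacing_mm = 2) {
  stop_if(!is_number(n_patients) || n_patients < 1,
          "n_patients must be >= 1")
  incs <- unlist(groups)
  stop_if(!all(incs %in% c(15, 30)),
          "arc increments must be 15 or 30 degrees")
  stop_if(any(incs %% cp_spacing != 0),
          "cp_spacing must divide every arc increment")
  stop_if(!all(names(groups) %in% names(falloff_mm)),
          "falloff_mm needs one value per group")
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         groups = groups, cp_spacing = cp_spacing,
         modulation_level = modulation_level,
         prescription_gy = prescription_gy, fractions = fractions,
         n_leaf_pairs = n_leaf_pairs, leaf_width_mm = leaf_width_mm,
         falloff_mm = falloff_mm, homogeneity = homogeneity,
         falloff_sd = falloff_sd, dose_sd = dose_sd,
         grid_spacing_mm = grid_spacing_mm),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d patients, seed %d, groups %s, modulation %.2f\n",
    x$n_patients, x$seed,
    paste(sprintf("%s=%s", names(x$groups),
                  vapply(x$groups, paste, character(1), collapse = "/")),
          collapse = " "),
    x$modulation_level))
  invisible(x)
}

# triangle carrier in [-1, 1] with vertices at every multiple of the
# sector width: the synchronized leaf sweep that reverses direction at
# each internal sector boundary (S - 1 reversals over a 360 degree arc
# split into S sectors)
sweep_carrier <- function(theta_deg, increment_deg) {
  phase <- (theta_deg / increment_deg) %% 2
  1 - 2 * abs(phase - 1)
}

#' Generate one synthetic dual-arc plan
#'
#' Builds a deterministic (seeded) dual-arc plan with sector-reversal leaf
#' kinematics: within each sector of width `increments[k]` the leaves
#' sweep monotonically and reverse at internal sector boundaries. The
#' per-leaf sweep amplitude scales with `modulation_level` and with the
#' sector count (`sqrt(30 / increment)`), so smaller increments produce
#' more heavily modulated apertures, mirroring the extra degrees of
#' freedom a finer sector split gives the optimizer. At
#' `modulation_level = 0` the aperture is a static rectangle matching the
#' target projection area and the plan is modulation-free
#' (MCSv = 1, PM = 0).
#'
#' @param seed integer seed; the same seed reproduces the plan exactly.
#' @param increments length-2 vector of arc increments (degrees).
#' @param modulation_level sweep amplitude scale in `[0, 1]`.
#' @param cp_spacing control-point spacing (degrees); must divide the
#'   increments.
#' @param n_pairs,leaf_width MLC layout (pairs, mm).
#' @param target_radius_mm radius of the (spherical) target whose
#'   projection sets the base aperture.
#' @param prescription_gy,fractions,group,patient_id plan metadata.
#' @return a [vmat_plan] with two full arcs.
#' @export
generate_plan <- function(seed, increments = c(30, 15),
                          modulation_level = 0.5, cp_spacing = 3,
                          n_pairs = 40, leaf_width = 5,
                          target_radius_mm = 50, prescription_gy = 70,
                          fractions = 35, group = NA_character_,
                          patient_id = NA_character_) {
  stop_if(!all(increments %% cp_spacing == 0),
          "cp spacing does not divide the arc increment")
  stop_if(modulation_level < 0 || modulation_level > 1,
          "modulation_level must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  t <- leaf_width
  y <- (seq_len(n_pairs) - (n_pairs + 1) / 2) * t
  # base aperture: rectangle spanning the target projection in height,
  # width chosen so the area equals the circular projection pi R^2; the
  # modulation sweeps then carve leaf-by-leaf structure into it.  a zero
  # modulation level leaves the rectangle untouched at every control
  # point: the exact no-modulation limit (LSV = AAV = 1, MCS = 1)
  exposed <- abs(y) < target_radius_mm
  half_w <- ifelse(exposed, pi * target_radius_mm / 4, 0)

  arcs <- lapply(seq_along(increments), function(k) {
    inc <- increments[k]
    theta <- seq(0, 360, by = cp_spacing)
    n_cp <- length(theta)
    gantry <- if (k %% 2 == 1) theta %% 360 else (360 - theta) %% 360
    direction <- if (k %% 2 == 1) "CW" else "CCW"
    collimator <- if (k %% 2 == 1) 45 else 315

    # per-leaf, per-bank sweep amplitudes; finer sectors modulate harder
    eff <- modulation_level * sqrt(30 / inc)
    amp_l <- pmin(0.85, eff * stats::runif(n_pairs, 0.25, 0.95)) * half_w
    amp_r <- pmin(0.85, eff * stats::runif(n_pairs, 0.25, 0.95)) * half_w
    sgn_l <- sample(c(-1, 1), n_pairs, replace = TRUE)
    sgn_r <- sample(c(-1, 1), n_pairs, replace = TRUE)
    carrier <- sweep_carrier(theta, inc)

    u <- exp(modulation_level * stats::rnorm(n_cp - 1, 0, 0.6))
    w <- c(0, cumsum(u) / sum(u))
    w[n_cp] <- 1
    arc_mu <- stats::runif(1, 560, 700)

    cps <- lapply(seq_len(n_cp), function(i) {
      off_l <- amp_l * sgn_l * carrier[i]
      off_r <- amp_r * sgn_r * carrier[i]
      control_point(
        gantry_deg = gantry[i],
        mlc = mlc_positions(-half_w + off_l, half_w + off_r,
                            leaf_width = t),
        cum_weight = w[i], collimator_deg = collimator
      )
    })
    vmat_arc(cps, arc_mu = arc_mu, increment_deg = inc,
             direction = direction)
  })
  vmat_plan(arcs, prescription_gy = prescription_gy, fractions = fractions,
            group = group, patient_id = patient_id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# sample one synthetic anatomy within the cohort envelope; distances are
# resampled (then clamped) so no organ overlaps the spherical PTV
sample_anatomy <- function(seed) {
  rg <- anatomy_ranges()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(field) stats::runif(1, rg$min[[field]], rg$max[[field]])
  ptv_cc <- draw("ptv_cc")
  r_ptv <- (3 * ptv_cc * 1000 / (4 * pi))^(1 / 3)
  organs <- list(
    spinal_cord = list(vol_field = "cord_cc", dist_field = "cord_dist_cm",
                       shape = "cylinder", length_mm = 150,
                       dir = c(0, -1, 0)),
    brain_stem = list(vol_field = "brainstem_cc",
                      dist_field = "brainstem_dist_cm",
                      shape = "cylinder", length_mm = 55,
                      dir = c(0, -0.35, 0.9368) / sqrt(0.35^2 + 0.9368^2)),
    parotid_L = list(vol_field = "parotid_l_cc",
                     dist_field = "parotid_l_dist_cm", shape = "sphere",
                     dir = c(-0.93, -0.3676, 0) / sqrt(0.93^2 + 0.3676^2)),
    parotid_R = list(vol_field = "parotid_r_cc",
                     dist_field = "parotid_r_dist_cm", shape = "sphere",
                     dir = c(0.93, -0.3676, 0) / sqrt(0.93^2 + 0.3676^2))
  )
  out <- list(ptv_cc = ptv_cc, r_ptv_mm = r_ptv)
  for (nm in names(organs)) {
    o <- organs[[nm]]
    vol_cc <- draw(o$vol_field)
    radius <- if (o$shape == "sphere") (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)
      else sqrt(vol_cc * 1000 / (pi * o$length_mm))
    min_d <- r_ptv + radius + 1
    d <- draw(o$dist_field) * 10
    tries <- 0
    while (d < min_d && tries < 20) {
      d <- draw(o$dist_field) * 10
      tries <- tries + 1
    }
    if (d < min_d) d <- min_d
    out[[nm]] <- list(shape = o$shape, volume_cc = vol_cc,
                      radius_mm = radius,
                      length_mm = o$length_mm %||% NA_real_,
                      center_mm = o$dir * d, dist_mm = d)
  }
  out
}

# evaluate the analytic phantom dose (Gy) at voxel centers of a grid:
# prescription inside the PTV sphere, exponential radial falloff outside,
# multiplied by a smooth heterogeneity ripple and a global output factor
phantom_dose_values <- function(grid, r_ptv, lambda, rx, h, ripple, tau) {
  d2 <- grid_dist2(grid, c(0, 0, 0))
  r <- sqrt(d2)
  base <- ifelse(r <= r_ptv, 1, exp(-(r - r_ptv) / lambda))
  ax <- grid_axes(grid)
  gx <- sin(2 * pi * ax$x / ripple$wavelength[1] + ripple$phase[1])
  gy <- sin(2 * pi * ax$y / ripple$wavelength[2] + ripple$phase[2])
  gz <- sin(2 * pi * ax$z / ripple$wavelength[3] + ripple$phase[3])
  g <- outer(outer(gx, gy, `*`), gz, `*`)
  rx * tau * base * (1 + h * g)
}

# empty grid (zero dose) covering [lo, hi] per axis at the given spacing
empty_grid <- function(lo, hi, spacing) {
  n <- pmax(2L, ceiling((hi - lo) / spacing) + 1L)
  dose_grid(array(0, n), spacing = rep(spacing, 3), origin = lo)
}

structure_bbox <- function(st, margin) {
  c_mm <- st$center_mm
  if (st$shape == "sphere") {
    ext <- rep(st$radius_mm, 3)
  } else {
    ext <- c(st$radius_mm, st$radius_mm, st$length_mm / 2)
  }
  list(lo = c_mm - ext - margin, hi = c_mm + ext + margin)
}

mask_for_structure <- function(grid, st, name) {
  if (st$shape == "sphere") {
    sphere_mask(grid, st$center_mm, st$radius_mm, name)
  } else {
    cylinder_mask(grid, st$center_mm, st$radius_mm, st$length_mm, name)
  }
}

#' Generate the dose phantom of one synthetic plan
#'
#' Produces the analytic dose field and structure masks standing in for a
#' calculated plan dose: the spherical PTV receives the prescription with
#' a controlled heterogeneity ripple; outside the PTV the dose falls off
#' exponentially with the group's falloff length, so groups with shorter
#' falloff (group C by default) deliver lower organ-at-risk doses and a
#' lower gradient index. Per-plan noise enters through a lognormal jitter
#' of the falloff length and of the global output; the ripple phases are
#' drawn per patient (shared by the patient's three plans).
#'
#' @param anatomy a patient anatomy from the cohort generator (see
#'   [generate_cohort()]), or `NULL` to sample one from `seed`.
#' @param group group label (selects the falloff default).
#' @param spec a [cohort_spec].
#' @param seed plan-level seed for the noise draws.
#' @param patient_seed patient-level seed for the ripple draws.
#' @param mode `"full"` for one grid covering all structures (needed for
#'   conformity/gradient indices), `"structures"` for per-structure
#'   bounding-box grids (fast; enough for organ dose metrics).
#' @param structures which structures to build in `"structures"` mode.
#' @param noise if `FALSE`, suppress the per-plan jitter (falloff at the
#'   group default, unit output factor): the noiseless effect the
#'   generator injects.
#' @return an object of class `dose_phantom`: in full mode, `dose` (a
#'   [dose_grid]) and `masks` (named [structure_mask] list); in
#'   structures mode, `regions`, a named list of `list(dose, mask)`
#'   pairs. `params` carries the realized falloff, output factor and
#'   ripple.
#' @export
generate_dose_phantom <- function(anatomy = NULL, group = "A",
                                  spec = cohort_spec(), seed = 1,
                                  patient_seed = seed,
                                  mode = c("full", "structures"),
                                  structures = c("PTV", "spinal_cord",
                                                 "brain_stem", "parotid_L",
                                                 "parotid_R"),
                                  noise = TRUE) {
  mode <- match.arg(mode)
  if (is.null(anatomy)) anatomy <- sample_anatomy(patient_seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(split_seed(patient_seed, 77))
  ripple <- list(wavelength = stats::runif(3, 35, 55),
                 phase = stats::runif(3, 0, 2 * pi))

  set.seed(seed)
  lambda0 <- spec$falloff_mm[[group]]
  if (noise) {
    lambda <- lambda0 * exp(stats::rnorm(1, 0, spec$falloff_sd))
    tau <- exp(stats::rnorm(1, 0, spec$dose_sd))
  } else {
    lambda <- lambda0
    tau <- 1
  }
  rx <- spec$prescription_gy
  h <- spec$homogeneity
  sp <- spec$grid_spacing_mm
  r_ptv <- anatomy$r_ptv_mm

  fill <- function(grid) {
    dose_grid(phantom_dose_values(grid, r_ptv, lambda, rx, h, ripple, tau),
              grid$spacing, grid$origin)
  }
  params <- list(group = group, falloff_mm = lambda, output_factor = tau,
                 ripple = ripple, anatomy = anatomy, rx_gy = rx)

  if (mode == "full") {
    reach <- r_ptv + lambda * log(2) + 20
    lo <- rep(-reach, 3); hi <- rep(reach, 3)
    for (nm in setdiff(structures, "PTV")) {
      bb <- structure_bbox(anatomy[[nm]], margin = 6)
      lo <- pmin(lo, bb$lo); hi <- pmax(hi, bb$hi)
    }
    grid <- empty_grid(lo, hi, sp)
    dose <- fill(grid)
    masks <- list()
    for (nm in structures) {
      masks[[nm]] <- if (nm == "PTV")
        sphere_mask(dose, c(0, 0, 0), r_ptv, "PTV")
      else mask_for_structure(dose, anatomy[[nm]], nm)
    }
    out <- list(mode = mode, dose = dose, masks = masks, params = params)
  } else {
    regions <- list()
    for (nm in structures) {
      bb <- if (nm == "PTV") {
        list(lo = rep(-r_ptv - 2 * sp, 3), hi = rep(r_ptv + 2 * sp, 3))
      } else {
        structure_bbox(anatomy[[nm]], margin = 2 * sp)
      }
      grid <- empty_grid(bb$lo, bb$hi, sp)
      dose <- fill(grid)
      mask <- if (nm == "PTV") sphere_mask(dose, c(0, 0, 0), r_ptv, "PTV")
        else mask_for_structure(dose, anatomy[[nm]], nm)
      regions[[nm]] <- list(dose = dose, mask = mask)
    }
    out <- list(mode = mode, regions = regions, params = params)
  }
  class(out) <- "dose_phantom"
  out
}

#' @export
print.dose_phantom <- function(x, ...) {
  cat(sprintf(
    "<dose_phantom> group %s, falloff %.1f mm, output %.3f, mode %s\n",
    x$params$group, x$params$falloff_mm, x$params$output_factor, x$mode))
  invisible(x)
}

#' Generate a paired synthetic cohort
#'
#' Samples `spec$n_patients` anatomies and builds the three paired plans
#' (one per arc-increment group) for each. Dose phantoms are not stored
#' (they can be large); regenerate them deterministically with
#' [phantom_for()]. All seeds derive from `spec$seed` via a fixed
#' splitting scheme, recorded in the manifest.
#'
#' @param spec a [cohort_spec].
#' @return an object of class `vmat_cohort`: `spec` plus `patients`, each
#'   with `patient_id`, `anatomy`, `seeds` and `plans` (named by group).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- lapply(seq_len(spec$n_patients), function(p) {
    patient_seed <- split_seed(spec$seed, p)
    anatomy <- sample_anatomy(patient_seed)
    plans <- list()
    seeds <- list(patient = patient_seed, plan = list(), dose = list())
    for (gi in seq_along(spec$groups)) {
      g <- names(spec$groups)[gi]
      plan_seed <- split_seed(spec$seed, p, gi, 1)
      dose_seed <- split_seed(spec$seed, p, gi, 2)
      seeds$plan[[g]] <- plan_seed
      seeds$dose[[g]] <- dose_seed
      plans[[g]] <- generate_plan(
        seed = plan_seed, increments = spec$groups[[g]],
        modulation_level = spec$modulation_level,
        cp_spacing = spec$cp_spacing, n_pairs = spec$n_leaf_pairs,
        leaf_width = spec$leaf_width_mm,
        target_radius_mm = anatomy$r_ptv_mm,
        prescription_gy = spec$prescription_gy,
        fractions = spec$fractions, group = g,
        patient_id = sprintf("SYN%03d", p))
    }
    list(patient_id = sprintf("SYN%03d", p), anatomy = anatomy,
         seeds = seeds, plans = plans)
  })
  structure(list(spec = spec, patients = patients), class = "vmat_cohort")
}

#' @export
print.vmat_cohort <- function(x, ...) {
  cat(sprintf("<vmat_cohort> %d patients x %d groups (%d plans), seed %d\n",
              length(x$patients), length(x$spec$groups),
              length(x$patients) * length(x$spec$groups), x$spec$seed))
  invisible(x)
}

#' Regenerate the dose phantom of a cohort plan
#'
#' @param cohort a [generate_cohort()] result.
#' @param patient patient index.
#' @param group group label.
#' @param ... passed to [generate_dose_phantom()] (`mode`, `structures`,
#'   `noise`).
#' @return a `dose_phantom`.
#' @export
phantom_for <- function(cohort, patient, group, ...) {
  stopifnot(inherits(cohort, "vmat_cohort"))
  p <- cohort$patients[[patient]]
  generate_dose_phantom(anatomy = p$anatomy, group = group,
                        spec = cohort$spec,
                        seed = p$seeds$dose[[group]],
                        patient_seed = p$seeds$patient, ...)
}

#' Write a cohort manifest (YAML)
#'
#' Records the full specification and every derived seed so a cohort (and
#' all its plans and phantoms) can be regenerated exactly.
#'
#' @param cohort a [vmat_cohort].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "vmat_cohort"))
  spec <- cohort$spec
  m <- list(
    spec = list(
      n_patients = spec$n_patients, seed = spec$seed,
      groups = lapply(spec$groups, as.list),
      cp_spacing = spec$cp_spacing,
      modulation_level = spec$modulation_level,
      prescription_gy = spec$prescription_gy, fractions = spec$fractions,
      n_leaf_pairs = spec$n_leaf_pairs,
      leaf_width_mm = spec$leaf_width_mm,
      falloff_mm = as.list(spec$falloff_mm),
      homogeneity = spec$homogeneity, falloff_sd = spec$falloff_sd,
      dose_sd = spec$dose_sd, grid_spacing_mm = spec$grid_spacing_mm),
    patients = lapply(cohort$patients, function(p) list(
      patient_id = p$patient_id,
      patient_seed = p$seeds$patient,
      plan_seeds = p$seeds$plan,
      dose_seeds = p$seeds$dose,
      ptv_cc = p$anatomy$ptv_cc))
  )
  yaml::write_yaml(m, path)
  invisible(path)
}
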