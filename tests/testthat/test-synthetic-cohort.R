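# Cohort generator: plans, phantoms, determinism, injected orderings

test_that("generated plans are study-shaped, valid and deterministic", {
  plan <- generate_plan(42, c(30, 15))
  expect_equal(nrow(validate_plan(plan)), 0)
  expect_length(plan$arcs, 2)
  expect_equal(vapply(plan$arcs, `[[`, numeric(1), "increment_deg"),
               c(30, 15))
  expect_equal(plan$arcs[[1]]$n_sectors, 12)
  expect_equal(plan$arcs[[1]]$n_reversals, 11)
  expect_equal(plan$arcs[[2]]$n_sectors, 24)
  expect_equal(plan$arcs[[2]]$n_reversals, 23)
  expect_equal(plan$arcs[[1]]$control_points[[1]]$collimator_deg, 45)
  expect_equal(plan$arcs[[2]]$control_points[[1]]$collimator_deg, 315)
  expect_identical(generate_plan(42, c(30, 15)), plan)
  expect_false(identical(generate_plan(43, c(30, 15)), plan))
  expect_error(generate_plan(1, c(30, 15), cp_spacing = 4),
               "does not divide")
})

test_that("leaves reverse direction exactly at sector boundaries", {
  plan <- generate_plan(3, c(30, 30), modulation_level = 0.8)
  arc <- plan$arcs[[1]]
  # trajectory of one moving leaf edge
  traj <- vapply(arc$control_points, function(cp) cp$mlc$left[20],
                 numeric(1))
  v <- diff(traj)
  flips <- which(v[-1] * v[-length(v)] < 0)
  cp_per_sector <- 30 / 3
  # sign changes occur only at multiples of the sector width
  expect_true(all(flips %% cp_per_sector == 0))
  expect_equal(length(flips), arc$n_reversals)
})

test_that("modulation level drives MCS down monotonically on average", {
  set.seed(50)
  levels <- runif(50)
  mcs <- vapply(seq_along(levels), function(i)
    mcs_plan(generate_plan(100 + i, c(30, 30),
                           modulation_level = levels[i]))$mcs_v,
    numeric(1))
  rho <- stats::cor(levels, mcs, method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("finer arc increments yield lower MCS at equal modulation", {
  mcs_a <- vapply(1:10, function(s)
    mcs_plan(generate_plan(s, c(30, 30)))$mcs_v, numeric(1))
  mcs_b <- vapply(1:10, function(s)
    mcs_plan(generate_plan(s, c(15, 15)))$mcs_v, numeric(1))
  expect_lt(mean(mcs_b), mean(mcs_a))
})

test_that("dose phantoms hit their analytic targets", {
  spec <- cohort_spec(seed = 5)
  an <- vmatmetrics:::sample_anatomy(123)
  ph <- generate_dose_phantom(an, "A", spec, seed = 9, patient_seed = 123,
                              mode = "full", noise = FALSE)
  # noiseless gradient index close to the analytic shell ratio of the
  # exponential falloff: V50 radius = R + lambda log 2
  idx <- ptv_indices(normalize_to_coverage(ph$dose, ph$masks$PTV, 70),
                     ph$masks$PTV, 70)
  R <- an$r_ptv_mm
  lam <- spec$falloff_mm[["A"]]
  gi_expected <- ((R + lam * log(2)) / R)^3
  expect_equal(idx[["GI"]], gi_expected, tolerance = 0.06)
  expect_gt(idx[["CN"]], 0.8)
  expect_lt(idx[["HI"]], 0.12)

  # homogeneity parameter 0 gives a perfectly flat PTV dose
  spec0 <- cohort_spec(seed = 5, homogeneity = 0)
  ph0 <- generate_dose_phantom(an, "A", spec0, seed = 9,
                               patient_seed = 123, mode = "full",
                               noise = FALSE)
  idx0 <- ptv_indices(ph0$dose, ph0$masks$PTV, 70)
  expect_equal(idx0[["HI"]], 0)
})

test_that("group C spares the spinal cord for every patient", {
  spec <- cohort_spec(seed = 2, n_patients = 6)
  for (p in 1:6) {
    ps <- vmatmetrics:::split_seed(spec$seed, p)
    an <- vmatmetrics:::sample_anatomy(ps)
    d <- lapply(c("A", "C"), function(g) {
      ph <- generate_dose_phantom(an, g, spec, seed = 1, patient_seed = ps,
                                  mode = "structures",
                                  structures = c("PTV", "spinal_cord"),
                                  noise = FALSE)
      vmatmetrics:::region_dose_metrics(ph, 70)[["spinal_cord_D0.03cc_cGy"]]
    })
    expect_lt(d[[2]], d[[1]])
  }
})

test_that("cohorts are reproducible and correctly paired", {
  spec <- cohort_spec(n_patients = 3, seed = 77)
  co <- generate_cohort(spec)
  expect_length(co$patients, 3)
  for (p in co$patients) {
    expect_setequal(names(p$plans), c("A", "B", "C"))
    for (g in names(p$plans)) {
      expect_equal(p$plans[[g]]$group, g)
      expect_equal(nrow(validate_plan(p$plans[[g]])), 0)
    }
    # paired design: same anatomy, group-specific plans
    expect_equal(p$plans$A$patient_id, p$plans$C$patient_id)
  }
  co2 <- generate_cohort(spec)
  expect_identical(co, co2)

  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_manifest(co, f)
  m <- yaml::read_yaml(f)
  expect_equal(m$spec$seed, 77)
  expect_length(m$patients, 3)
  expect_equal(m$patients[[2]]$patient_seed, co$patients[[2]]$seeds$patient)
})

test_that("phantom regeneration from the cohort seeds is exact", {
  spec <- cohort_spec(n_patients = 2, seed = 31)
  co <- generate_cohort(spec)
  ph1 <- phantom_for(co, 1, "B", mode = "structures",
                     structures = c("PTV", "spinal_cord"))
  ph2 <- phantom_for(co, 1, "B", mode = "structures",
                     structures = c("PTV", "spinal_cord"))
  expect_identical(ph1, ph2)
})
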