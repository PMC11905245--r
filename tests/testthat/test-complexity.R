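# LSV / AAV / MCS and the MU-weighted aperture-area family

test_that("LSV hand-worked values and conventions hold", {
  # zero spread in both banks: the no-variability limit
  expect_equal(lsv_cp(mlc_positions(c(-7, -7, -7), c(9, 9, 9))), 1)
  # maximal adjacent jump in the left bank kills the product
  expect_equal(lsv_cp(mlc_positions(c(0, 10), c(20, 20))), 0)
  # hand evaluation of the summed form, cross-checked by the loop oracle
  m <- mlc_positions(c(0, 5, 10), c(20, 25, 30))
  expect_equal(lsv_cp(m), 0.25)
  expect_equal(lsv_cp(m), oracle_lsv(m$left, m$right))
  # a single leaf pair has no adjacent term: 1 by convention
  expect_equal(lsv_cp(mlc_positions(-5, 5)), 1)
})

test_that("AAV is the opening fraction of the arc-maximal apertures", {
  maxima <- c(10, 10)
  expect_equal(aav_cp(mlc_positions(c(-5, -5), c(0, 0)), maxima), 0.5)
  expect_equal(aav_cp(mlc_positions(c(-5, -5), c(5, 5)), maxima), 1)
  # degenerate all-closed arc
  a <- aav_cp(mlc_positions(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(as.numeric(a), 1)
  expect_true(attr(a, "degenerate"))
  # brute-force recomputation across a random arc
  for (s in 1:5) {
    arc <- random_toy_arc(s)
    o <- oracle_arc_mcs(arc)
    got <- mcs_arc(arc)
    expect_equal(got$aav, o$aav, tolerance = 1e-12)
    expect_equal(got$lsv, o$lsv, tolerance = 1e-12)
  }
})

test_that("MCS hand-worked example: per-segment pairwise averages", {
  # CP1: aligned banks (LSV 1), all pairs at their arc maxima (AAV 1)
  # CP2: left bank 0/5/10 (LSV 0.5), openings at half the maxima (AAV 0.5)
  cp1 <- list(c(0, 0, 0), c(30, 30, 30))
  cp2 <- list(c(0, 5, 10), c(20, 20, 20))
  arc <- toy_arc(list(cp1, cp2), weights = c(0, 1), arc_mu = 120)
  got <- mcs_arc(arc)
  expect_equal(got$lsv, c(1, 0.5))
  expect_equal(got$aav, c(1, 0.5))
  expect_equal(got$mcs_arc, 0.75 * 0.75)
})

test_that("plan MCS is the unweighted mean of the per-arc scores", {
  cp1 <- list(c(0, 0, 0), c(30, 30, 30))
  cp2 <- list(c(0, 5, 10), c(20, 20, 20))
  arc_mod <- toy_arc(list(cp1, cp2), weights = c(0, 1), arc_mu = 100)
  arc_flat <- toy_arc(list(cp1, cp1), weights = c(0, 1), arc_mu = 900)
  m <- mcs_plan(vmat_plan(list(arc_mod, arc_flat)))
  expect_equal(m$mcs_arc, c(0.5625, 1))
  expect_equal(m$mcs_v, mean(c(0.5625, 1)))  # 1/K mean, not MU-weighted
})

test_that("a static-aperture plan is the exact no-modulation limit", {
  plan <- generate_plan(99, c(30, 15), cp_spacing = 15,
                        modulation_level = 0)
  expect_identical(mcs_plan(plan)$mcs_v, 1)
  cx <- plan_complexity(plan)
  expect_identical(cx$pm, 0)
  expect_equal(cx$mcs_v, 1)
})

test_that("beam metrics match the direct-sum oracle and forced cases", {
  # identical aperture at every CP: BM = 0, U = AA
  arc <- toy_arc(list(list(c(-10, -10), c(10, 10)),
                      list(c(-10, -10), c(10, 10))),
                 weights = c(0, 1), arc_mu = 50)
  b <- beam_metrics(arc)
  expect_equal(b$bm, 0)
  expect_equal(b$u, 200)
  expect_equal(b$ba, 200)

  # disjoint equal-area apertures, equal MU per segment: BM = 1/2
  ap1 <- list(c(-20, -20), c(-10, -10))
  ap2 <- list(c(10, 10), c(20, 20))
  arc2 <- toy_arc(list(ap1, ap1, ap2, ap2),
                  weights = c(0, 0.25, 0.5, 1), arc_mu = 100)
  # segments: ap1 (25 MU), ap1->ap2 mean (25 MU), ap2 (50 MU)
  b2 <- beam_metrics(arc2)
  expect_equal(b2$u, 200)
  expect_equal(b2$ba, 100)
  expect_equal(b2$bm, 0.5)

  for (s in 1:8) {
    arc <- random_toy_arc(s)
    expect_equal(beam_metrics(arc)$ba, oracle_beam_area(arc),
                 tolerance = 1e-12)
  }

  closed <- toy_arc(list(list(c(0, 0), c(0, 0)), list(c(0, 0), c(0, 0))),
                    weights = c(0, 1))
  expect_error(beam_metrics(closed), "degenerate beam")
})

test_that("plan-phase metrics are MU-weighted means of beam values", {
  ap <- function(w) list(c(-w, -w), c(w, w))  # area 20 w mm^2
  arc1 <- toy_arc(list(ap(1.5), ap(1.5)), weights = c(0, 1), arc_mu = 100)
  arc2 <- toy_arc(list(ap(1.7), ap(1.7)), weights = c(0, 1), arc_mu = 100)
  cx <- plan_complexity(vmat_plan(list(arc1, arc2)))
  expect_equal(cx$pa, 32)  # mean of BA 30 and 34 at equal MU
  expect_equal(cx$total_mu, 200)
})

test_that("complexity is invariant under MU rescaling of the plan", {
  plan <- generate_plan(5, c(30, 30), cp_spacing = 15, n_pairs = 10)
  scaled <- plan
  for (k in seq_along(scaled$arcs)) {
    scaled$arcs[[k]]$arc_mu <- scaled$arcs[[k]]$arc_mu * 3.7
  }
  a <- plan_complexity(plan); b <- plan_complexity(scaled)
  expect_equal(b$pa, a$pa)
  expect_equal(b$pi, a$pi)
  expect_equal(b$pm, a$pm)
  expect_equal(b$mcs_v, a$mcs_v)
  expect_equal(b$total_mu, a$total_mu * 3.7)
})

test_that("LSV, AAV, MCS and PM stay inside their ranges", {
  set.seed(123)
  for (s in 1:10) {
    plan <- generate_plan(s, sample(list(c(30, 30), c(15, 15), c(30, 15)),
                                    1)[[1]],
                          cp_spacing = 15,
                          modulation_level = runif(1))
    m <- mcs_plan(plan)
    for (a in m$per_arc) {
      expect_true(all(a$lsv >= 0 & a$lsv <= 1))
      expect_true(all(a$aav >= 0 & a$aav <= 1))
    }
    expect_true(all(m$mcs_arc > 0 & m$mcs_arc <= 1))
    cx <- plan_complexity(plan)
    expect_true(cx$pm >= 0 && cx$pm < 1)
    expect_true(cx$pa >= 0)
  }
})
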