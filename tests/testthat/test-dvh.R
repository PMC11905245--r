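# Cumulative DVHs, queries, normalization and the PTV indices

test_that("uniform and two-level fields give the textbook DVHs", {
  g <- uniform_grid(70, n = 10, spacing = 2)   # 1000 voxels, 8 cc
  m <- structure_mask(array(TRUE, dim(g$values)), g, "PTV")
  d <- compute_dvh(g, m)
  expect_equal(d$volume_cc[1], 8)
  expect_equal(v_at_dose(d, 35), 8)
  expect_equal(v_at_dose(d, 70), 8)
  expect_equal(v_at_dose(d, 70.02), 0)
  q <- dvh_query(d, c("D2%", "D98%", "D50%", "D0.03cc", "Dmean"))
  expect_equal(unname(q), rep(70, 5))

  vals <- array(70, c(10, 10, 10)); vals[1:5, , ] <- 35
  g2 <- dose_grid(vals, 2)
  d2 <- compute_dvh(g2, m)
  expect_equal(v_at_dose(d2, 50), 4)
  expect_equal(v_at_dose(d2, 20), 8)
  expect_equal(dvh_query(d2, "D50%")[[1]], 70)

  expect_error(compute_dvh(g, structure_mask(
    array(FALSE, dim(g$values)), g, "empty")), "empty structure")
})

test_that("a volume-uniform dose ramp has its median at mid-dose", {
  n <- 20
  vals <- array(seq(0, 70, length.out = n^3), c(n, n, n))
  g <- dose_grid(vals, 2)
  m <- structure_mask(array(TRUE, dim(vals)), g, "ramp")
  d <- compute_dvh(g, m)
  expect_equal(dvh_query(d, "D50%")[[1]], 35, tolerance = 0.02)
  expect_equal(d$mean_gy, mean(vals))
})

test_that("DVH curves are monotone and conserve volume on random fields", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:10, 1)
    vals <- array(runif(n^3, 0, 75), c(n, n, n))
    g <- dose_grid(vals, sample(c(1, 2, 2.5), 1))
    m <- structure_mask(array(runif(n^3) < 0.7, c(n, n, n)), g, "s")
    if (sum(m$mask) == 0) next
    d <- compute_dvh(g, m)
    expect_true(all(diff(d$volume_cc) <= 1e-12))
    expect_equal(d$volume_cc[1], m$volume_cc)
    expect_gte(min(d$volume_cc), 0)
  }
})

test_that("DVH queries agree with the voxel-sort oracle", {
  set.seed(77)
  bin <- 0.01
  for (i in 1:30) {
    n <- sample(6:10, 1)
    vals <- array(runif(n^3, 0, 73), c(n, n, n))
    g <- dose_grid(vals, 2)
    m <- structure_mask(array(runif(n^3) < 0.8, c(n, n, n)), g, "s")
    doses <- vals[m$mask]
    vv <- 8 / 1000
    d <- compute_dvh(g, m, bin_gy = bin)
    for (pct in c(2, 50, 95, 98)) {
      v <- pct / 100 * d$volume_total_cc
      expect_lt(abs(d_at_volume(d, v) -
                      oracle_d_at_volume(doses, vv, v)), bin * 1.01)
    }
    # at bin edges the cumulative curve is an exact voxel count
    for (dose in c(10, 35.55, 60)) {
      expect_equal(v_at_dose(d, dose),
                   oracle_v_at_dose(doses, vv, dose),
                   tolerance = vv * sum(abs(doses - dose) < bin) + 1e-9)
    }
  }
})

test_that("queries converge to the oracle as the bin width shrinks", {
  set.seed(5)
  vals <- array(runif(1000, 0, 70), c(10, 10, 10))
  g <- dose_grid(vals, 2)
  m <- structure_mask(array(TRUE, dim(vals)), g, "s")
  truth <- oracle_d_at_volume(vals[m$mask], 8e-3, 0.5 * 8)
  for (bin in c(0.1, 0.01)) {
    d <- compute_dvh(g, m, bin_gy = bin)
    expect_equal(d_at_volume(d, 0.5 * 8), truth, tolerance = bin * 1.01)
  }
})

test_that("query parsing rejects nonsense and over-volume requests", {
  g <- uniform_grid(70, 5)
  m <- structure_mask(array(TRUE, dim(g$values)), g, "s")
  d <- compute_dvh(g, m)
  expect_error(dvh_query(d, "Q5%"), "unrecognized")
  expect_error(d_at_volume(d, 2 * d$volume_total_cc), "exceeds")
})

test_that("coverage normalization hits D95 = prescription exactly", {
  # uniform PTV at 66.5 Gy scales by 70/66.5
  g <- uniform_grid(66.5, 10)
  m <- structure_mask(array(TRUE, dim(g$values)), g, "PTV")
  out <- normalize_to_coverage(g, m, 70)
  expect_equal(attr(out, "scale"), 70 / 66.5)
  expect_equal(max(out$values), 70)
  # idempotence
  out2 <- normalize_to_coverage(out, m, 70)
  expect_equal(attr(out2, "scale"), 1)

  # heterogeneous field: re-query oracle confirms the post-condition
  set.seed(9)
  vals <- array(runif(8000, 50, 80), c(20, 20, 20))
  g3 <- dose_grid(vals, 2)
  m3 <- sphere_mask(g3, c(20, 20, 20), 15, "PTV")
  out3 <- normalize_to_coverage(g3, m3, 70)
  d95 <- vmatmetrics:::coverage_dose(out3$values[m3$mask], 95)
  expect_equal(d95, 70, tolerance = 1e-12)
  covered <- mean(out3$values[m3$mask] >= 70)
  expect_gte(covered, 0.95)

  expect_error(normalize_to_coverage(
    dose_grid(array(0, c(3, 3, 3)), 2),
    structure_mask(array(TRUE, c(3, 3, 3)),
                   dose_grid(array(0, c(3, 3, 3)), 2), "PTV"), 70),
    "coverage dose is zero")
})

test_that("PTV indices reproduce their defining limits and forced case", {
  # prescription isodose exactly the PTV: CN = 1
  n <- 40
  g0 <- dose_grid(array(0, c(n, n, n)), 2, origin = c(-39, -39, -39))
  ptv <- sphere_mask(g0, c(0, 0, 0), 25, "PTV")
  vals <- array(40, c(n, n, n))  # below rx outside
  vals[ptv$mask] <- 70
  g <- dose_grid(vals, 2, origin = c(-39, -39, -39))
  idx <- ptv_indices(g, ptv, 70)
  expect_equal(idx[["CN"]], 1)
  expect_equal(idx[["HI"]], 0)

  # binary step dose: GI = 1 and HI = 0
  vals2 <- array(0, c(n, n, n))
  vals2[ptv$mask] <- 70
  g2 <- dose_grid(vals2, 2, origin = c(-39, -39, -39))
  idx2 <- ptv_indices(g2, ptv, 70)
  expect_equal(idx2[["GI"]], 1)
  expect_equal(idx2[["HI"]], 0)

  # forced arithmetic of the conformity number: volumes 100/200/90 cc
  # -> CN = (90/100) * (90/200); 2 mm voxels are 0.008 cc
  gv <- numeric(40^3)
  gv[1:11250] <- 70                # 90 cc of the PTV covered
  gv[12501:26250] <- 70            # pads v_ref to 200 cc total
  dim(gv) <- c(40, 40, 40)
  ptv_m <- array(FALSE, c(40, 40, 40))
  ptv_m[1:12500] <- TRUE           # v_t = 100 cc
  g3 <- dose_grid(gv, 2)
  idx3 <- ptv_indices(g3, structure_mask(ptv_m, g3, "PTV"), 70)
  expect_equal(idx3[["CN"]], (90 / 100) * (90 / 200))
})

test_that("GI matches the analytic shell ratio on a falloff phantom", {
  # linear radial falloff: dose rx at r <= R, dropping to rx/2 at R + w
  n <- 90; sp <- 2
  org <- rep(-(n - 1) / 2 * sp, 3)
  g0 <- dose_grid(array(0, c(n, n, n)), sp, origin = org)
  R <- 30; w <- 12
  r <- sqrt(vmatmetrics:::grid_dist2(g0, c(0, 0, 0)))
  vals <- ifelse(r <= R, 70, pmax(0, 70 * (1 - 0.5 * (r - R) / w)))
  g <- dose_grid(array(vals, dim(r)), sp, origin = org)
  ptv <- sphere_mask(g, c(0, 0, 0), R, "PTV")
  idx <- ptv_indices(g, ptv, 70)
  expect_equal(idx[["GI"]], ((R + w) / R)^3, tolerance = 0.02)
})
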