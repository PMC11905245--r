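# JSON fixture dialect and DICOM-RT Plan round trips

test_that("JSON fixtures round-trip a plan exactly", {
  plan <- generate_plan(11, c(30, 15), cp_spacing = 15, n_pairs = 8,
                        group = "C", patient_id = "P1")
  f <- withr::local_tempfile(fileext = ".json")
  write_plan_fixture(plan, f)
  back <- load_plan_fixture(f)
  expect_equal(back, plan)
})

test_that("fixture group label is inferred from the arc increments", {
  plan <- generate_plan(4, c(30, 15), cp_spacing = 15, n_pairs = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan_fixture(plan, f)
  x <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  x$group <- NULL
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  expect_equal(load_plan_fixture(f)$group, "C")
  expect_equal(infer_group(c(30, 30)), "A")
  expect_equal(infer_group(c(15, 15)), "B")
  expect_equal(infer_group(c(15, 30)), "C")
  expect_true(is.na(infer_group(c(20, 30))))
})

test_that("fixture schema violations name the offending keys", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(prescription_gy = 70, fractions = 35,
                            arcs = list()),
                       f, auto_unbox = TRUE)
  expect_error(load_plan_fixture(f), "empty arcs")
  jsonlite::write_json(list(fractions = 35, arcs = list(list())),
                       f, auto_unbox = TRUE)
  expect_error(load_plan_fixture(f), "prescription_gy")
  jsonlite::write_json(
    list(prescription_gy = 70, fractions = 35,
         arcs = list(list(increment_deg = 30))),
    f, auto_unbox = TRUE)
  expect_error(load_plan_fixture(f), "arc_mu, control_points")
})

test_that("DICOM writer and reader round-trip the plan model", {
  plan <- generate_plan(21, c(30, 15), cp_spacing = 15, n_pairs = 8,
                        group = "C", patient_id = "RT01")
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  back <- load_rtplan(f)
  expect_equal(back$patient_id, plan$patient_id)
  expect_equal(back$group, plan$group)
  expect_equal(back$prescription_gy, plan$prescription_gy)
  expect_equal(back$fractions, plan$fractions)
  expect_length(back$arcs, 2)
  for (k in 1:2) {
    a0 <- plan$arcs[[k]]; a1 <- back$arcs[[k]]
    expect_equal(a1$increment_deg, a0$increment_deg)
    expect_equal(a1$direction, a0$direction)
    expect_equal(a1$arc_mu, a0$arc_mu, tolerance = 1e-9)
    for (i in seq_along(a0$control_points)) {
      cp0 <- a0$control_points[[i]]; cp1 <- a1$control_points[[i]]
      expect_equal(cp1$gantry_deg, cp0$gantry_deg, tolerance = 1e-9)
      expect_equal(cp1$cum_weight, cp0$cum_weight, tolerance = 1e-9)
      expect_equal(cp1$mlc$left, cp0$mlc$left, tolerance = 1e-9)
      expect_equal(cp1$mlc$right, cp0$mlc$right, tolerance = 1e-9)
    }
  }
})

test_that("DICOM and JSON routes are metric-equivalent downstream", {
  plan <- generate_plan(31, c(30, 30), cp_spacing = 15, n_pairs = 8)
  fd <- withr::local_tempfile(fileext = ".dcm")
  fj <- withr::local_tempfile(fileext = ".json")
  write_rtplan(plan, fd)
  write_plan_fixture(plan, fj)
  cx_d <- plan_complexity(load_rtplan(fd))
  cx_j <- plan_complexity(load_plan_fixture(fj))
  for (field in c("mcs_v", "total_mu", "pa", "pi", "pm")) {
    expect_equal(cx_d[[field]], cx_j[[field]], tolerance = 1e-9)
  }
})

test_that("a minimal two-control-point single-arc file loads", {
  mlc <- mlc_positions(c(-10, -10), c(10, 10))
  plan <- vmat_plan(list(vmat_arc(
    list(control_point(0, mlc, 0), control_point(180, mlc, 1)),
    arc_mu = 100)))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  back <- load_rtplan(f)
  expect_length(back$arcs, 1)
  expect_length(back$arcs[[1]]$control_points, 2)
})

test_that("malformed DICOM inputs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), f)
  expect_error(load_rtplan(f), "DICM")

  # a plan whose cumulative weights decrease at CP 3: assembled from the
  # raw element encoders, since the model constructors refuse to build it
  enc <- asNamespace("vmatmetrics")
  cp_item <- function(i, w) c(
    enc$dcm_is(0x300A, 0x0112, i),
    enc$dcm_sq(0x300A, 0x011A, list(c(
      enc$dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
      enc$dcm_ds(0x300A, 0x011C, c(-10, -10, 10, 10))))),
    enc$dcm_ds(0x300A, 0x011E, i * 90),
    enc$dcm_ds(0x300A, 0x0134, w))
  beam <- c(
    enc$dcm_is(0x300A, 0x00C0, 1),
    enc$dcm_ds(0x300A, 0x010E, 1),
    enc$dcm_is(0x300A, 0x0110, 4),
    enc$dcm_sq(0x300A, 0x0111,
               list(cp_item(0, 0), cp_item(1, 0.6),
                    cp_item(2, 0.4), cp_item(3, 1))))
  dataset <- c(
    enc$dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.5"),
    enc$dcm_sq(0x300A, 0x0070, list(c(
      enc$dcm_is(0x300A, 0x0078, 35),
      enc$dcm_sq(0x300C, 0x0004, list(c(
        enc$dcm_ds(0x300A, 0x0086, 100),
        enc$dcm_is(0x300C, 0x0006, 1))))))),
    enc$dcm_sq(0x300A, 0x00B0, list(beam)))
  meta_body <- c(
    enc$dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.481.5"),
    enc$dcm_str(0x0002, 0x0003, "UI", "1.2.3"),
    enc$dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(enc$dcm_element(0x0002, 0x0000, "UL",
                            enc$u32le(length(meta_body))), meta_body)
  f2 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(c(rep(as.raw(0), 128), charToRaw("DICM"), meta, dataset), f2)
  expect_error(load_rtplan(f2), "beam 1, control point 3")

  # same file with the MLC positions stripped from one CP
  cp_no_mlc <- c(enc$dcm_is(0x300A, 0x0112, 1),
                 enc$dcm_ds(0x300A, 0x011E, 90),
                 enc$dcm_ds(0x300A, 0x0134, 0.5))
  beam2 <- c(
    enc$dcm_is(0x300A, 0x00C0, 1),
    enc$dcm_ds(0x300A, 0x010E, 1),
    enc$dcm_is(0x300A, 0x0110, 2),
    enc$dcm_sq(0x300A, 0x0111, list(cp_item(0, 0), cp_no_mlc)))
  dataset2 <- c(
    enc$dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.5"),
    enc$dcm_sq(0x300A, 0x0070, list(c(
      enc$dcm_is(0x300A, 0x0078, 35),
      enc$dcm_sq(0x300C, 0x0004, list(c(
        enc$dcm_ds(0x300A, 0x0086, 100),
        enc$dcm_is(0x300C, 0x0006, 1))))))),
    enc$dcm_sq(0x300A, 0x00B0, list(beam2)))
  f3 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(c(rep(as.raw(0), 128), charToRaw("DICM"), meta, dataset2), f3)
  expect_error(load_rtplan(f3), "BeamLimitingDevicePositionSequence")
})

test_that("pydicom parses the written file identically", {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  skip_if(py == "", "no python interpreter on PATH")
  plan <- generate_plan(7, c(30, 15), cp_spacing = 15, n_pairs = 6)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  script <- paste(
    "import pydicom, json, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "b = ds.BeamSequence[1]; cp = b.ControlPointSequence[3]",
    "out = {",
    " 'n_beams': len(ds.BeamSequence),",
    " 'n_cp': len(b.ControlPointSequence),",
    " 'gantry': float(cp.GantryAngle),",
    " 'weight': float(cp.CumulativeMetersetWeight),",
    " 'leaves': [float(v) for v in",
    "   cp.BeamLimitingDevicePositionSequence[0].LeafJawPositions],",
    " 'mu': float(ds.FractionGroupSequence[0]",
    "   .ReferencedBeamSequence[1].BeamMeterset)}",
    "print(json.dumps(out))", sep = "\n")
  out <- system2(py, c("-c", shQuote(script), shQuote(f)), stdout = TRUE)
  got <- jsonlite::fromJSON(paste(out, collapse = ""))
  cp <- plan$arcs[[2]]$control_points[[4]]
  expect_equal(got$n_beams, 2)
  expect_equal(got$n_cp, length(plan$arcs[[2]]$control_points))
  expect_equal(got$gantry, cp$gantry_deg, tolerance = 1e-9)
  expect_equal(got$weight, cp$cum_weight, tolerance = 1e-9)
  expect_equal(got$leaves, c(cp$mlc$left, cp$mlc$right), tolerance = 1e-9)
  expect_equal(got$mu, plan$arcs[[2]]$arc_mu, tolerance = 1e-9)
})
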