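# DICOM-RT Plan writer/reader round trips and error handling.

test_that("DICOM round-trip preserves positions, MU fractions and angles", {
  cfg <- cohort_config(n_plans = 1, n_control_points = 12, leaf_pairs = 10,
                       seed = 3)
  plan <- generate_plan(cfg, 1)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_plan(plan, path)
  back <- read_dicom_plan(path)
  expect_equal(back$plan_id, plan$plan_id)
  expect_equal(length(back$arcs), length(plan$arcs))
  for (i in seq_along(plan$arcs)) {
    a0 <- plan$arcs[[i]]; a1 <- back$arcs[[i]]
    expect_equal(a1$arc_id, a0$arc_id)
    expect_equal(a1$leaf_widths, a0$leaf_widths, tolerance = 1e-6)
    expect_equal(a1$arc_mu, a0$arc_mu, tolerance = 1e-6)
    for (j in seq_along(a0$control_points)) {
      c0 <- a0$control_points[[j]]; c1 <- a1$control_points[[j]]
      expect_equal(c1$bankA, c0$bankA, tolerance = 1e-6)
      expect_equal(c1$bankB, c0$bankB, tolerance = 1e-6)
      expect_equal(c1$mu_fraction, c0$mu_fraction, tolerance = 1e-6)
      expect_equal(c1$gantry_angle, c0$gantry_angle, tolerance = 1e-6)
      expect_equal(c1$jaw_x, c0$jaw_x, tolerance = 1e-6)
      expect_equal(c1$jaw_y, c0$jaw_y, tolerance = 1e-6)
    }
  }
})

test_that("cp_interval is recovered from the written gantry angles", {
  posA <- matrix(-5, 3, 2); posB <- matrix(5, 3, 2)
  arc <- make_arc(posA, posB, cp_interval = 2.0341)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_plan(vmat_plan("P1", list(arc)), path)
  back <- read_dicom_plan(path)
  # the file stores no explicit interval: it is derived from the angles
  expect_equal(back$arcs[[1]]$cp_interval, 2.0341, tolerance = 1e-4)
})

test_that("pydicom parses files written by the package identically", {
  cfg <- cohort_config(n_plans = 1, n_control_points = 6, leaf_pairs = 6,
                       seed = 11)
  plan <- generate_plan(cfg, 1)
  path <- tempfile(fileext = ".dcm")
  on.exit(unlink(path))
  write_dicom_plan(plan, path)
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "b = ds.BeamSequence[0]",
    "cp = b.ControlPointSequence[2]",
    "mlc = [d for d in cp.BeamLimitingDevicePositionSequence",
    "       if d.RTBeamLimitingDeviceType == 'MLCX'][0]",
    "print(len(ds.BeamSequence), b.BeamType,",
    "      float(cp.CumulativeMetersetWeight),",
    "      ' '.join(str(float(v)) for v in mlc.LeafJawPositions))",
    sep = "\n")
  out <- tryCatch(
    system2("python", c("-c", shQuote(script), shQuote(path)),
            stdout = TRUE, stderr = TRUE),
    error = function(e) NULL)
  # independent third-party parse of the same file
  expect_false(is.null(out))
  parts <- strsplit(paste(out, collapse = " "), "\\s+")[[1]]
  expect_equal(as.integer(parts[1]), length(plan$arcs))
  expect_equal(parts[2], "DYNAMIC")
  cp3 <- plan$arcs[[1]]$control_points[[3]]
  expect_equal(as.numeric(parts[3]), cp3$mu_fraction, tolerance = 1e-6)
  mlc <- as.numeric(parts[-(1:3)])
  expect_equal(mlc, c(cp3$bankA, cp3$bankB), tolerance = 1e-6)
})

test_that("malformed DICOM input fails loudly", {
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), path)
  expect_error(read_dicom_plan(path), "DICM magic")
  # a decreasing cumulative meterset is caught at validation, naming the CP
  posA <- matrix(-5, 3, 2); posB <- matrix(5, 3, 2)
  arc <- make_arc(posA, posB, mu = c(0, 0.7, 1), validate = TRUE)
  arc$control_points[[2]]$mu_fraction <- 1.2  # corrupt after construction
  arc$control_points[[3]]$mu_fraction <- 1
  write_dicom_plan(vmat_plan("P1", list(arc)), path)
  expect_error(read_dicom_plan(path), "MU fraction decreases at CP 2")
})

test_that("static beams are skipped with a message", {
  posA <- matrix(-5, 3, 2); posB <- matrix(5, 3, 2)
  arc <- make_arc(posA, posB)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_plan(vmat_plan("P1", list(arc)), path)
  # patch the BeamType bytes from DYNAMIC to STATIC_ (same length)
  buf <- readBin(path, raw(), file.info(path)$size)
  pat <- charToRaw("DYNAMIC ")
  hit <- which(vapply(seq_len(length(buf) - 7), function(i)
    all(buf[i:(i + 7)] == pat), logical(1)))[1]
  buf[hit:(hit + 7)] <- charToRaw("STATIC  ")
  writeBin(buf, path)
  expect_message(expect_error(read_dicom_plan(path), "no dynamic"),
                 "skipping non-dynamic beam")
})
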