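# Leaf speed/acceleration computation and the 32 kinematic features.

test_that("control-point time is interval over gantry speed", {
  expect_equal(round(cp_time(4.8, 2.0341), 3), 0.424)
  expect_equal(cp_time(1, 1), 1)
  expect_equal(cp_time(6, 3), 0.5)
  expect_error(cp_time(0, 1), "> 0")
  expect_error(cp_time(4.8, -1), "> 0")
})

test_that("leaf speeds and accelerations are magnitude differences over dt", {
  # trajectory [0, 2, 6] mm at dt = 0.424 s
  posA <- cbind(c(0, 2, 6)); posB <- cbind(c(10, 10, 10))
  arc <- make_arc(posA - 20, posB, widths = 5)  # shift A negative, keep deltas
  sp <- leaf_speeds(arc, "A", dt = 0.424)
  expect_equal(as.vector(sp), c(2, 4) / 0.424, tolerance = 1e-12)
  expect_equal(round(as.vector(sp), 3), c(4.717, 9.434))
  ac <- leaf_accelerations(sp)
  expect_equal(round(as.vector(ac), 3), 11.125)
  # static leaf: all zero
  spB <- leaf_speeds(arc, "B", dt = 0.424)
  expect_true(all(spB == 0))
  # 8.48 mm over one 0.424 s interval is 20 mm/s
  arc2 <- make_arc(cbind(c(-10, -10)), cbind(c(0, 8.48)), widths = 5)
  expect_equal(as.vector(leaf_speeds(arc2, "B", dt = 0.424)), 20)
  # speeds [20, 0] give acceleration 20/0.424
  m <- matrix(c(20, 0), 1, 2)
  attr(m, "cp_time") <- 0.424
  expect_equal(round(as.vector(leaf_accelerations(m)), 2), 47.17)
})

test_that("single-interval arcs yield an empty acceleration matrix", {
  arc <- make_arc(cbind(c(-10, -5)), cbind(c(5, 10)), widths = 5)
  sp <- leaf_speeds(arc, "A")
  expect_message(ac <- leaf_accelerations(sp), "single speed interval")
  expect_equal(ncol(ac), 0)
})

test_that("static arcs give zero means and all mass in the lowest bins", {
  posA <- matrix(-10, 4, 3); posB <- matrix(10, 4, 3)
  arc <- make_arc(posA, posB)
  f <- kinematic_features(arc)
  expect_equal(unname(f["MeanLS_A"]), 0)
  expect_equal(unname(f[c("LS0_4_A", "LS4_8_A", "LS8_12_A",
                          "LS12_16_A", "LS16_20_A")]), c(1, 0, 0, 0, 0))
  expect_equal(unname(f[c("LA0_40_B", "LA40_80_B", "LA80_120_B",
                          "LA120_160_B", "LA160_200_B")]), c(1, 0, 0, 0, 0))
})

test_that("one sample per speed bin gives fractions of 0.2 each", {
  # one leaf, 6 CPs: interval distances put speeds at 2, 6, 10, 14, 18 mm/s
  dt <- 1
  pos <- cumsum(c(0, 2, 6, 10, 14, 18) * c(1, 1, -1, 1, -1, 1))
  arc <- make_arc(cbind(pos - 60), cbind(rep(10, 6)), widths = 5,
                  gantry_speed = 1, cp_interval = 1)
  f <- kinematic_features(arc)
  expect_equal(unname(f[c("LS0_4_A", "LS4_8_A", "LS8_12_A",
                          "LS12_16_A", "LS16_20_A")]),
               rep(0.2, 5))
})

test_that("doubling dt halves speeds and quarters accelerations", {
  arc <- random_arc(5)
  s1 <- leaf_speeds(arc, "A", dt = 0.4); s2 <- leaf_speeds(arc, "A", dt = 0.8)
  expect_equal(s2, s1 / 2, ignore_attr = TRUE)
  a1 <- leaf_accelerations(s1, 0.4); a2 <- leaf_accelerations(s2, 0.8)
  expect_equal(a2, a1 / 4, ignore_attr = TRUE)
})

test_that("vectorized features equal the naive per-leaf loop on seeded arcs", {
  for (seed in 1:20) {
    arc <- random_arc(seed)
    fast <- kinematic_features(arc, all_leaves = TRUE)
    slow <- naive_kinematic_features(arc)
    expect_equal(fast[names(slow)], slow, tolerance = 1e-9)
  }
})

test_that("speed-bin fractions sum to 1 when the cap is respected", {
  for (seed in 1:5) {
    cfg <- cohort_config(n_plans = 1, n_control_points = 30, leaf_pairs = 20,
                         seed = seed)
    arc <- generate_plan(cfg, 1)$arcs[[1]]
    f <- kinematic_features(arc)
    expect_lt(f["MaxLS_A"], 20)
    for (b in c("A", "B")) {
      expect_equal(sum(f[paste0(c("LS0_4", "LS4_8", "LS8_12", "LS12_16",
                                  "LS16_20"), "_", b)]), 1)
      expect_equal(sum(f[paste0(c("LA0_40", "LA40_80", "LA80_120",
                                  "LA120_160", "LA160_200"), "_", b)]), 1)
    }
  }
})

test_that("samples above the caps go to an overflow bucket with a message", {
  # one leaf jumping 30 mm in 1 s: speed 30 > 20 cap
  arc <- make_arc(cbind(c(-40, -10)), cbind(c(0, 0)), widths = 5,
                  gantry_speed = 1, cp_interval = 1)
  expect_message(f <- kinematic_features(arc), "overflow")
  expect_equal(sum(f[paste0(c("LS0_4", "LS4_8", "LS8_12", "LS12_16",
                              "LS16_20"), "_A")]), 0)
})

test_that("out-of-field leaf pairs are excluded unless requested", {
  # 4 pairs of 5 mm: y spans [-10, 10]; jaw_y covers only the upper half
  posA <- matrix(rep(c(-10, -20), each = 2), 2, 4)
  posB <- matrix(10, 2, 4)
  arc <- make_arc(posA, posB, widths = rep(5, 4), jaw_y = c(0.5, 9.5))
  f_jaw <- kinematic_features(arc)
  f_all <- kinematic_features(arc, all_leaves = TRUE)
  # with the jaw, 2 of 4 pairs contribute; speeds identical per pair here
  expect_equal(unname(f_jaw["MeanLS_A"]), unname(f_all["MeanLS_A"]))
  expect_equal(attr(leaf_speeds(arc, "A", leaves = vmatqa:::included_leaves(arc)),
                    "cp_time"),
               cp_time(arc$gantry_speed, arc$cp_interval))
  expect_equal(length(vmatqa:::included_leaves(arc)), 2)
  expect_equal(length(vmatqa:::included_leaves(arc, all_leaves = TRUE)), 4)
})
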