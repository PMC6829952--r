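test_that("sigma-Z and its classification follow the activity rule", {
  expect_equal(sigma_z(1.3, 1.3), 0)
  expect_equal(sigma_z(2.0, -0.5), 2.5)
  expect_identical(classify_activity(sigma_z(2.0, -0.5)), "significantly_active")
  expect_equal(sigma_z(-0.5, 2.0), -sigma_z(2.0, -0.5))  # label swap negates
  expect_identical(classify_activity(1.96), "significantly_active")  # inclusive
  expect_identical(classify_activity(-0.5), "inactive")
  expect_identical(classify_activity(0), "inactive")
  expect_identical(classify_activity(0.01), "active")
  expect_identical(classify_activity(-1.96), "significantly_inactive")
})

test_that("contrast systems enumerate fixed and adjacent references", {
  stages <- c("0", "0.75", "6", "24", "48", "144")
  cs <- build_contrast_systems(stages)
  expect_equal(nrow(cs$fixed), 5)
  expect_equal(nrow(cs$continuous), 5)
  expect_true("144_vs_0" %in% cs$fixed$contrast_id)
  expect_true("144_vs_48" %in% cs$continuous$contrast_id)
  expect_identical(cs$fixed[1, c("test", "ref")],
                   cs$continuous[1, c("test", "ref")])
  two <- build_contrast_systems(c("a", "b"))
  expect_identical(two$fixed$contrast_id, two$continuous$contrast_id)
  expect_error(build_contrast_systems("a"), "two stages")
})

test_that("activity table uses Z = 0 for a missing direction", {
  enr <- data.frame(bincode = c("2", "2"), bin_name = "x",
                    contrast_id = c("6_vs_0", "24_vs_0"),
                    direction = c("up", "down"),
                    N = 10, K = 5, n = 3, k = 2, expected = 1.5,
                    p = c(0.04, 0.04), Z = c(2.05, 2.05))
  act <- activity_table(enr)
  r6 <- act[act$contrast_id == "6_vs_0", ]
  expect_equal(r6$sigma_Z, 2.05)      # no down cell -> Z_down = 0
  r24 <- act[act$contrast_id == "24_vs_0", ]
  expect_equal(r24$sigma_Z, -2.05)    # no up cell -> Z_up = 0
  expect_identical(r24$status, "significantly_inactive")
  expect_identical(r6$test, "6")
  expect_identical(r6$ref, "0")
})

test_that("concordance points are coloured by significance and quadrant", {
  mk <- function(x, y, bin = "2") {
    fx <- data.frame(bincode = bin, bin_name = "b", contrast_id = "24_vs_0",
                     test = "24", ref = "0", Z_up = x, Z_down = 0,
                     sigma_Z = x, status = "active")
    cy <- data.frame(bincode = bin, bin_name = "b", contrast_id = "24_vs_6",
                     test = "24", ref = "6", Z_up = y, Z_down = 0,
                     sigma_Z = y, status = "active")
    concordance(fx, cy, stages = "24")
  }
  p <- mk(2.5, 2.7)
  expect_identical(c(p$quadrant, p$color_class), c("I", "blue"))
  p <- mk(0.5, -0.3)
  expect_identical(p$color_class, "green")
  p <- mk(2.5, -2.2)
  expect_identical(c(p$quadrant, p$color_class), c("IV", "red"))
  p <- mk(-2.5, -0.4)
  expect_identical(c(p$quadrant, p$color_class), c("III", "blue"))
  p <- mk(1.96, 0.5)           # boundary counts as significant
  expect_identical(p$color_class, "blue")
  p <- mk(2.5, 0)              # on the axis: significant but not concordant
  expect_identical(c(p$quadrant, p$color_class), c("axis", "red"))
})

test_that("concordance drops bins present in one system only, with a warning", {
  fx <- data.frame(bincode = c("2", "11"), bin_name = "b",
                   contrast_id = "24_vs_0", test = "24", ref = "0",
                   Z_up = 1, Z_down = 0, sigma_Z = 1, status = "active")
  cy <- fx[1, ]
  cy$contrast_id <- "24_vs_6"; cy$ref <- "6"
  expect_warning(p <- concordance(fx, cy, stages = "24"), "one system only")
  expect_identical(p$bincode, "2")
})

test_that("the default concordance stages skip the shared first contrast", {
  stages <- c("0", "0.75", "6", "24")
  cs <- build_contrast_systems(stages)
  mkact <- function(sys) {
    do.call(rbind, lapply(seq_len(nrow(sys)), function(i)
      data.frame(bincode = "2", bin_name = "b",
                 contrast_id = sys$contrast_id[i],
                 test = sys$test[i], ref = sys$ref[i],
                 Z_up = 1, Z_down = 0, sigma_Z = 1, status = "active")))
  }
  p <- concordance(mkact(cs$fixed), mkact(cs$continuous))
  expect_setequal(unique(p$stage), c("6", "24"))
})

test_that("timetable extracts onset, peak and offset from a trajectory", {
  stages <- c("0", "s1", "s2", "s3", "s4", "s5")
  traj <- c(2.1, 2.5, 1.0, -0.2, -1.0)
  act <- data.frame(bincode = "2", bin_name = "b",
                    contrast_id = paste0(stages[-1], "_vs_0"),
                    test = stages[-1], ref = "0",
                    Z_up = traj, Z_down = 0, sigma_Z = traj,
                    status = classify_activity(traj))
  tt <- activation_timetable(act, stages)
  expect_identical(tt$onset, "s1")
  expect_identical(tt$peak, "s2")
  expect_identical(tt$offset, "s4")

  # never-significant bins get no onset and sort last
  act0 <- act
  act0$sigma_Z <- c(0, 0, 0, 0, 0)
  act0$bincode <- "11"
  both <- rbind(act, act0)
  tt2 <- activation_timetable(both, stages)
  expect_identical(tt2$bincode, c("2", "11"))
  expect_true(is.na(tt2$onset[2]))
  expect_equal(tt2$rank, 1:2)

  # invariant to input row order
  tt3 <- activation_timetable(both[sample(nrow(both)), ], stages)
  expect_identical(tt2, tt3)
})

test_that("offset requires loss of activity, not just of significance", {
  stages <- c("0", "s1", "s2", "s3")
  traj <- c(2.5, 1.2, 0.4)  # drops below 1.96 but stays positive
  act <- data.frame(bincode = "2", bin_name = "b",
                    contrast_id = paste0(stages[-1], "_vs_0"),
                    test = stages[-1], ref = "0",
                    Z_up = traj, Z_down = 0, sigma_Z = traj,
                    status = classify_activity(traj))
  tt <- activation_timetable(act, stages)
  expect_true(is.na(tt$offset))
})
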