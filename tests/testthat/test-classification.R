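test_that("classification boundaries follow the SD-band rules", {
  # all slopes equal: degenerate scale, everyone ER
  expect_warning(cls <- classify_sires(setNames(rep(0.3, 4), 1:4)),
                 "degenerate")
  expect_true(all(cls$class == "ER"))

  # two sires at +-0.5: both 0.707 SD from the mean, both ER
  cls <- classify_sires(setNames(c(-0.5, 0.5), 1:2))
  expect_equal(cls$slope_sd_units, rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_true(all(cls$class == "ER"))

  # explicit band checks via the zero-center path against manual units
  u <- setNames(c(0, 0.4, 1.1, 1.9, 2.2, -3.1), 1:6)
  cls <- classify_sires(u, center = "zero")
  manual <- abs(u) / sd(u)
  expect_equal(cls$slope_sd_units, unname(manual), tolerance = 1e-12)
  band <- function(x) if (x <= 1) "ER" else if (x < 2) "R" else
    if (x < 3) "P" else "EP"
  expect_equal(as.character(cls$class), unname(vapply(manual, band, "")))
})

test_that("boundary at exactly 1 SD is ER, 2 is P, 3 is EP", {
  # build slopes whose deviations in SD units hit the boundaries exactly:
  # with center = "zero", units = |x| / sd(x)
  x <- c(1, -1, 2, -2, 3, -3)
  x <- x / sd(x)  # now sd = 1 and values are at 1/sd(x) multiples
  u <- abs(x) / sd(x)
  cls <- classify_sires(setNames(x, seq_along(x)), center = "zero")
  expect_equal(cls$slope_sd_units, u, tolerance = 1e-12)
  lab <- as.character(cls$class)
  expect_equal(lab[abs(u - 1) < 1e-9], rep("ER", sum(abs(u - 1) < 1e-9)))
  expect_equal(lab[abs(u - 2) < 1e-9], rep("P", sum(abs(u - 2) < 1e-9)))
  expect_equal(lab[abs(u - 3) < 1e-9], rep("EP", sum(abs(u - 3) < 1e-9)))
})

test_that("classification is invariant to affine slope transforms", {
  set.seed(3)
  sl <- setNames(rnorm(500, 2, 0.7), 1:500)
  base <- classify_sires(sl)
  for (tr in list(c(10, 1), c(0, 5), c(-4, 0.2))) {
    moved <- classify_sires(tr[1] + tr[2] * sl)
    expect_equal(as.character(moved$class), as.character(base$class))
    expect_equal(moved$slope_sd_units, base$slope_sd_units, tolerance = 1e-9)
  }
})

test_that("progeny filter and percentage bookkeeping", {
  sl <- setNames(c(0, 0.1, 5, -5), c("a", "b", "c", "d"))
  cnt <- setNames(c(5, 2, 3, 3), c("a", "b", "c", "d"))
  cls <- classify_sires(sl, progeny_counts = cnt, min_progeny = 3)
  expect_equal(cls$sire, c("a", "c", "d"))

  pc <- class_percentages(classify_sires(setNames(c(-.1, .1, 2, -2), 1:4),
                                         center = "zero"))
  expect_equal(sum(pc), 100)
  expect_equal(length(pc), 4)
  expect_error(class_percentages(data.frame()), "empty")

  # one sire per class: 25 each (zero-count classes reported as 0 elsewhere)
  cls <- data.frame(sire = as.character(1:4),
                    class = factor(c("ER", "R", "P", "EP"),
                                   levels = c("ER", "R", "P", "EP")))
  expect_equal(unname(class_percentages(cls)), rep(25, 4))
  # all-ER degenerate case: 100/0/0/0
  cls <- data.frame(sire = "1", class = factor(rep("ER", 5),
                    levels = c("ER", "R", "P", "EP")))
  expect_equal(unname(class_percentages(cls)), c(100, 0, 0, 0))
})

test_that("normal slopes reproduce the normal-CDF class bands", {
  set.seed(99)
  sl <- rnorm(10000, 1.3, 0.8)
  pc <- class_percentages(classify_sires(setNames(sl, seq_along(sl))))
  expect_lt(abs(pc[["ER"]] - 68.27), 1.5)
  expect_lt(abs(pc[["ER"]] + pc[["R"]] - 95.45), 1)
  # the robust-or-extremely-robust share exceeds 90%, as in field data
  expect_gt(pc[["ER"]] + pc[["R"]], 90)
})
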