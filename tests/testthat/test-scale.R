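test_that("built-in FMA-LE has the published structure", {
  s <- load_scale("fma_le")
  expect_s3_class(s, "ordinal_scale")
  expect_equal(nrow(s$items), 17)
  expect_true(all(s$items$min_level == 0 & s$items$max_level == 2))
  maxima <- vapply(names(s$sum_groups), function(g) group_range(s, g)[2], 0L)
  expect_equal(maxima[c("SUM E II", "SUM E III", "SUM E IV",
                        "SUM E", "SUM F", "TOTAL E-F")],
               c("SUM E II" = 14L, "SUM E III" = 4L, "SUM E IV" = 4L,
                 "SUM E" = 28L, "SUM F" = 6L, "TOTAL E-F" = 34L))
  # total maximum is the sum of per-item maxima
  expect_equal(group_range(s, "TOTAL E-F")[2], sum(s$items$max_level))
})

test_that("scale construction validates its invariants", {
  one <- load_scale(list(name = "one",
                         items = list(list(id = "a", min = 0, max = 2))))
  expect_equal(nrow(one$items), 1)
  expect_error(
    ordinal_scale("dup", data.frame(
      item_id = c("a", "a"), label = "x", section = "S",
      min_level = 0L, max_level = 2L)),
    "duplicate item_id")
  expect_error(
    ordinal_scale("bad", data.frame(
      item_id = "a", label = "x", section = "S",
      min_level = 2L, max_level = 2L)),
    "max_level")
  expect_error(
    ordinal_scale("grp", data.frame(
      item_id = "a", label = "x", section = "S",
      min_level = 0L, max_level = 2L),
      sum_groups = list(G = c("a", "zz"))),
    "unknown item")
})

test_that("scale config round-trips through YAML and JSON files", {
  cfg <- list(name = "mini",
              items = list(list(id = "a", label = "A", section = "S1",
                                min = 0, max = 3),
                           list(id = "b", min = 0, max = 1)),
              sum_groups = list(ALL = list("a", "b")))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, js, auto_unbox = TRUE)
  for (path in c(yml, js)) {
    s <- load_scale(path)
    expect_equal(s$name, "mini")
    expect_equal(group_range(s, "ALL"), c(0L, 4L))
  }
})

test_that("the shipped example config loads with mixed level ranges", {
  p <- system.file("extdata", "example_scale.yaml", package = "rankagree")
  s <- load_scale(p)
  expect_equal(nrow(s$items), 4)
  expect_equal(group_range(s, "TOTAL"), c(0L, 9L))
  expect_equal(s$items$max_level[s$items$item_id == "standing_balance"], 3L)
})

test_that("sum scores hit the instrument's anchor points", {
  d <- constant_fma_ratings(n = 3, score = 2L)
  tot <- sum_scores(d, "fma_le", "TOTAL E-F")
  expect_true(all(tot$score == 34))
  e <- sum_scores(d, "fma_le", "SUM E")
  expect_true(all(e$score == 28))
  z <- constant_fma_ratings(n = 3, score = 0L)
  for (g in c("SUM E", "SUM F", "TOTAL E-F"))
    expect_true(all(sum_scores(z, "fma_le", g)$score == 0))
  # E items full, F items zero
  scale <- load_scale("fma_le")
  mixed <- d
  f_items <- scale$sum_groups[["SUM F"]]
  mixed$score[mixed$item_id %in% f_items] <- 0L
  expect_true(all(sum_scores(mixed, scale, "SUM E")$score == 28))
  expect_true(all(sum_scores(mixed, scale, "SUM F")$score == 0))
  expect_error(sum_scores(d, "fma_le", "nope"), "unknown sum group")
})

test_that("sum scores are record-order invariant and additive over subscales", {
  set.seed(42)
  cfg <- synthetic_config(n_subjects = 6, shift_prob = 0.3, noise_prob = 0.2,
                          seed = 99)
  d <- generate_study(cfg)
  shuffled <- d[sample.int(nrow(d)), ]
  a <- sum_scores(d, "fma_le", "TOTAL E-F")
  b <- sum_scores(shuffled, "fma_le", "TOTAL E-F")
  expect_equal(a, b)
  e <- sum_scores(d, "fma_le", "SUM E")
  f <- sum_scores(d, "fma_le", "SUM F")
  expect_equal(e$score + f$score, a$score)
})

test_that("assessments missing items are excluded with a warning", {
  d <- constant_fma_ratings(n = 3, score = 1L)
  drop_one <- d[!(d$subject_id == "S001" & d$rater_id == d$rater_id[1] &
                  d$occasion == 1 & d$item_id == "f_time"), ]
  expect_warning(tot <- sum_scores(drop_one, "fma_le", "TOTAL E-F"),
                 "excluded")
  full <- sum_scores(d, "fma_le", "TOTAL E-F")
  expect_equal(nrow(tot), nrow(full) - 1L)
  # the incomplete assessment still contributes to groups it is complete for
  expect_silent(e <- sum_scores(drop_one, "fma_le", "SUM E"))
  expect_equal(nrow(e), nrow(full))
})

test_that("floor/ceiling uses a strict >15% rule", {
  no_ceiling <- floor_ceiling(c(rep(34L, 9), rep(20L, 51)), 0, 34)
  expect_false(no_ceiling$ceiling_effect)
  expect_false(no_ceiling$floor_effect)
  expect_equal(no_ceiling$n_at_max, 9)
  ceiling <- floor_ceiling(c(rep(34L, 10), rep(20L, 50)), 0, 34)
  expect_true(ceiling$ceiling_effect)
  expect_false(floor_ceiling(rep(20L, 60), 0, 34)$floor_effect)
  expect_error(floor_ceiling(integer(), 0, 34), "no totals")
  expect_error(floor_ceiling(c(1, 40), 0, 34), "outside")
})

test_that("floor flag flips exactly when the count crosses the threshold", {
  n <- 40
  for (thr in c(0.1, 0.15, 0.2)) {
    boundary <- floor(thr * n)
    for (k in c(boundary, boundary + 1L)) {
      fc <- floor_ceiling(c(rep(0L, k), rep(5L, n - k)), 0, 10,
                          threshold = thr)
      expect_identical(fc$floor_effect, k / n > thr)
    }
  }
})

test_that("ratings validation names the offending record", {
  d <- constant_fma_ratings(n = 2, score = 1L)
  expect_error(validate_ratings(rbind(d, d[1, ]), "fma_le"),
               "duplicate rating record")
  bad <- d; bad$score[5] <- 7L
  expect_error(validate_ratings(bad, "fma_le"), "out of range")
  unk <- d; unk$item_id[1] <- "mystery"
  expect_error(validate_ratings(unk, "fma_le"), "unknown item")
  expect_error(validate_ratings(d[, -5], "fma_le"), "missing column")
})

test_that("ratings round-trip through CSV and TSV with metadata columns", {
  d <- constant_fma_ratings(n = 2, score = 1L)
  d$age <- 70L
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, p, row.names = FALSE)
  back <- read_ratings(p, "fma_le")
  expect_equal(back$score, d$score)
  expect_true("age" %in% names(back))
  pt <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d, pt, sep = "\t", row.names = FALSE)
  expect_equal(read_ratings(pt, "fma_le")$score, d$score)
})
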