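test_that("CSV round trip preserves values, counts and missingness", {
  set.seed(101)
  st <- generate_study(study_config(n_series = 2, seed = 101))
  path <- withr::local_tempfile(fileext = ".csv")
  write_esm_csv(st$series, path)
  back <- read_esm_csv(path)
  expect_length(back, 2)
  for (id in names(st$series)) {
    a <- st$series[[id]]
    b <- back[[id]]
    expect_equal(nrow(b$ratings), 70)
    expect_identical(b$missing_mask, a$missing_mask, ignore_attr = TRUE)
    keep <- !a$missing_mask
    expect_identical(b$ratings[keep], a$ratings[keep])
    expect_identical(b$timestamps, a$timestamps)
    expect_identical(b$day_index, a$day_index)
  }
})

test_that("an empty rating cell becomes a missing mask entry", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,t_hours,day,PA,NA",
               "p1,10.0,1,40,10",
               "p1,11.5,1,,12",
               "p1,13.0,1,55,"), path)
  s <- read_esm_csv(path)[["p1"]]
  expect_true(s$missing_mask[2, 1])
  expect_false(s$missing_mask[2, 2])
  expect_true(s$missing_mask[3, 2])
  expect_equal(s$ratings[1, ], c(PA = 40, "NA" = 10))
})

test_that("duplicated or non-increasing timestamps are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,t_hours,day,PA,NA",
               "p1,10.0,1,40,10",
               "p1,10.0,1,41,11"), path)
  expect_error(read_esm_csv(path), "p1")
  expect_error(esm_series("x", c(1, 1), c(1L, 1L), matrix(0, 2, 1)),
               "strictly increasing")
})

test_that("ISO datetimes convert to hours since the first day's midnight", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,datetime,day,PA",
               "p1,2020-03-02T10:30:00,1,40",
               "p1,2020-03-03T12:00:00,2,50"), path)
  s <- read_esm_csv(path)[["p1"]]
  expect_equal(s$timestamps, c(10.5, 36))
})

test_that("unknown rating columns in the schema are an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,t_hours,day,PA", "p1,10,1,40"), path)
  expect_error(read_esm_csv(path, schema = list(items = c("PA", "XX"))), "XX")
})

test_that("PA/NA aggregation averages observed items and propagates missing", {
  x <- rbind(c(40, 60, 50, 10, 20),
             c(40, NA, 50, NA, NA),
             c(NA, NA, NA, 30, 40))
  s <- esm_series("p", c(10, 11, 12), c(1L, 1L, 1L), x,
                  dim_names = c("happy", "relaxed", "cheerful", "sad", "anxious"))
  agg <- aggregate_pa_na(s, c("happy", "relaxed", "cheerful"), c("sad", "anxious"))
  expect_identical(agg$dim_names, c("PA", "NA"))
  expect_equal(agg$ratings[1, ], c(PA = 50, "NA" = 15))
  expect_equal(unname(agg$ratings[2, 1]), 45)        # mean of the two observed
  expect_true(agg$missing_mask[2, 2])                # all negative items missing
  expect_true(agg$missing_mask[3, 1])
  expect_equal(unname(agg$ratings[3, 2]), 35)
  expect_error(aggregate_pa_na(s, character(0), "sad"), "non-empty")
})

test_that("transition plan: one stationary item per day, chained transitions", {
  s <- toy_series(c(10, 11, 13), c(1, 1, 1), cbind(c(1, 2, 3), c(0, 1, 2)))
  p <- build_transition_plan(s)
  expect_equal(p$kind, c("stationary", "transition", "transition"))
  expect_equal(p$steps[-1], c(1L, 1L))
  expect_equal(p$dt[-1], c(1, 2))

  st <- generate_study(study_config(n_series = 1, missing_rate = 0, seed = 3))
  p7 <- build_transition_plan(st$series[[1]])
  expect_equal(sum(p7$kind == "stationary"), 7)
})

test_that("a missed beep doubles the pseudo-step and stretches the interval", {
  x <- cbind(c(1, 2, NA, 4), c(5, 6, NA, 8))
  s <- esm_series("p", c(10, 11.2, 12.4, 13.9), rep(1L, 4), x)
  p <- build_transition_plan(s)
  expect_equal(nrow(p), 3)
  last <- p[p$target == 4, ]
  expect_equal(last$source, 2)
  expect_equal(last$steps, 2L)
  expect_equal(last$dt, 13.9 - 11.2)
})

test_that("plan covers each non-missing beep exactly once and is deterministic", {
  st <- generate_study(study_config(n_series = 3, seed = 17))
  for (s in st$series) {
    p1 <- build_transition_plan(s)
    p2 <- build_transition_plan(s)
    expect_identical(p1, p2)
    obs <- which(!apply(s$missing_mask, 1, any))
    expect_identical(sort(p1$target), obs)
    expect_false(anyDuplicated(p1$target) > 0)
    # first non-missing beep of each day is stationary, never a target twice
    firsts <- tapply(obs, s$day_index[obs], min)
    expect_setequal(p1$target[p1$kind == "stationary"], as.integer(firsts))
  }
})
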