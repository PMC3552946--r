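test_that("log odds ratio matches closed forms on hand-checked tables", {
  balanced <- log_odds_ratio(1, 2, 1, 2, label = "balanced")
  expect_equal(balanced$effect, 0)
  expect_equal(balanced$se, 2)

  r <- log_odds_ratio(10, 100, 20, 100)
  expect_equal(r$effect, -0.81093022, tolerance = 1e-8)
  expect_equal(r$se, 0.41666667, tolerance = 1e-8)
  expect_equal(r$scale_tag, "log_ratio")
})

test_that("zero cells get the Haldane-Anscombe correction only where needed", {
  # a = 0, b = 10, c = 5, d = 5 -> all four cells get +0.5
  r <- log_odds_ratio(0, 10, 5, 10, zero_cell_policy = "haldane")
  expect_equal(r$effect, log(0.5 / 10.5), tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5), tolerance = 1e-12)

  # a clean table in the same call stays uncorrected
  both <- log_odds_ratio(c(0, 10), c(10, 100), c(5, 20), c(10, 100))
  expect_equal(both$effect[2], -0.81093022, tolerance = 1e-8)

  expect_error(
    log_odds_ratio(0, 10, 5, 10, zero_cell_policy = "strict"),
    "zero cell", class = "metapi_data_error"
  )
})

test_that("uninformative and invalid tables are rejected with the study label", {
  expect_error(log_odds_ratio(0, 10, 0, 10, label = "Empty"), "Empty",
               class = "metapi_data_error")
  expect_error(log_odds_ratio(10, 10, 5, 5, label = "AllEvents"), "AllEvents",
               class = "metapi_data_error")
  expect_error(log_odds_ratio(-1, 10, 5, 10, label = "Neg"), "Neg",
               class = "metapi_data_error")
  expect_error(log_odds_ratio(11, 10, 5, 10, label = "TooMany"), "TooMany",
               class = "metapi_data_error")
  expect_error(log_odds_ratio(1, 0, 5, 10, label = "ZeroArm"), "ZeroArm",
               class = "metapi_data_error")
})

test_that("swapping arms negates the log OR and keeps the SE", {
  set.seed(11)
  for (i in 1:25) {
    nt <- sample(20:200, 1); nc <- sample(20:200, 1)
    a <- sample(1:(nt - 1), 1); c_ <- sample(1:(nc - 1), 1)
    fwd <- log_odds_ratio(a, nt, c_, nc)
    rev <- log_odds_ratio(c_, nc, a, nt)
    expect_equal(fwd$effect, -rev$effect, tolerance = 1e-12)
    expect_equal(fwd$se, rev$se, tolerance = 1e-12)
  }
})

test_that("scaling all cells of a table never increases the SE", {
  set.seed(12)
  for (i in 1:25) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    c_ <- sample(1:50, 1); d <- sample(1:50, 1)
    m <- sample(2:10, 1)
    base <- log_odds_ratio(a, a + b, c_, c_ + d)
    scaled <- log_odds_ratio(m * a, m * (a + b), m * c_, m * (c_ + d))
    expect_lte(scaled$se, base$se + 1e-12)
    expect_equal(scaled$effect, base$effect, tolerance = 1e-12)
  }
})

test_that("study_effects handles both schemas and rejects mixtures", {
  counts <- tibble::tibble(
    label = c("x", "y"),
    events_trt = c(10, 20), total_trt = c(100, 100),
    events_ctl = c(20, 20), total_ctl = c(100, 100)
  )
  rec <- study_effects(counts)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$se[1], sqrt(1 / 10 + 1 / 90 + 1 / 20 + 1 / 80), tolerance = 1e-12)

  effects <- tibble::tibble(label = "z", effect = 0.3, se = 0.1)
  rec2 <- study_effects(effects)
  expect_equal(rec2$effect, 0.3)
  expect_equal(rec2$scale_tag, "linear")

  mixed <- dplyr::mutate(counts, effect = 1, se = 1)
  expect_error(study_effects(mixed), "Mixed schemas", class = "metapi_data_error")
  expect_error(study_effects(tibble::tibble(a = 1)), "schema",
               class = "metapi_data_error")
})

test_that("reading a study table validates cells with row numbers", {
  bad_se <- tibble::tibble(
    label = c("a", "b", "c"), effect = c(0.1, 0.2, 0.3), se = c(0.1, 0.2, 0)
  )
  expect_error(study_effects(bad_se), "row 3", class = "metapi_data_error")

  path <- write_temp_csv(tibble::tibble(
    label = c("a", "b"), effect = c("0.1", "oops"), se = c("0.1", "0.2")
  ))
  expect_error(read_study_table(path), "row 2", class = "metapi_data_error")

  path2 <- write_temp_csv(tibble::tibble(label = "a", effect = 0.1))
  expect_error(read_study_table(path2), "missing", class = "metapi_data_error")

  expect_error(read_study_table("no/such/file.csv"), "not found",
               class = "metapi_data_error")
})

test_that("a counts CSV converts row-wise and an effects CSV parses in order", {
  set.seed(13)
  counts <- tibble::tibble(
    label = paste("T", 1:8),
    events_trt = sample(5:30, 8), total_trt = 100,
    events_ctl = sample(5:30, 8), total_ctl = 100
  )
  path <- write_temp_csv(counts)
  rec <- read_study_table(path, format_hint = "counts")
  expect_equal(nrow(rec), 8)
  expect_equal(rec$label, counts$label)
  a <- counts$events_trt; b <- 100 - a; cc <- counts$events_ctl; d <- 100 - cc
  expect_equal(rec$se, sqrt(1 / a + 1 / b + 1 / cc + 1 / d), tolerance = 1e-12)
  expect_error(read_study_table(path, format_hint = "effects"),
               class = "metapi_data_error")
})

test_that("write/read round-trips study records", {
  set.seed(14)
  studies <- random_studies(6)
  studies$scale_tag <- "log_ratio"
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(studies, path)
  back <- read_study_table(path)
  expect_equal(as.data.frame(back), as.data.frame(studies), tolerance = 1e-12)
})
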