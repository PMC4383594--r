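test_that("a long-format excerpt reads and validates with ordered occasions", {
  d <- excerpt_data()
  expect_s3_class(d, "longitudinal_df")
  expect_equal(nrow(d), 8)
  expect_equal(dplyr::n_distinct(d$PatientID), 2)
  expect_equal(levels(d$Measurement), c("0", "14", "180", "365"))
  expect_s3_class(d$Date, "Date")
  expect_type(d$Fatigue, "double")

  ov <- data_overview(d)
  expect_equal(ov$n_rows, 8)
  expect_equal(ov$n_subjects, 2)
  expect_equal(ov$n_occasions, 4)
})

test_that("a header-only file yields an empty dataset", {
  path <- write_excerpt(excerpt_lines()[1])
  d <- validate_roles(read_long_table(path), excerpt_roles())
  expect_equal(nrow(d), 0)
  ov <- data_overview(d)
  expect_equal(ov$n_rows, 0)
  expect_equal(ov$n_subjects, 0)
  expect_equal(sum(ov$per_occasion$n_evaluated), 0)
})

test_that("structural defects are rejected with informative errors", {
  lines <- excerpt_lines()
  lines[3] <- "\t2010-01-15\t14\t1\t0.5\tM"  # row 2: missing ID
  expect_error(validate_roles(read_long_table(write_excerpt(lines)),
                              excerpt_roles()),
               class = "longmed_validation_error")

  lines <- excerpt_lines()
  lines[3] <- "1\t2010-01-01\t0\t1\t0.5\tM"  # duplicate (id, occasion)
  expect_error(validate_roles(read_long_table(write_excerpt(lines)),
                              excerpt_roles()),
               class = "longmed_validation_error")

  lines <- excerpt_lines()
  lines[3] <- "1\tnot-a-date\t14\t1\t0.5\tM"
  expect_error(validate_roles(read_long_table(write_excerpt(lines)),
                              excerpt_roles()),
               class = "longmed_validation_error", regexp = "row")

  dup_header <- c("PatientID\tDate\tDate\tFatigue", "1\t2010-01-01\t0\t2")
  expect_error(read_long_table(write_excerpt(dup_header)),
               class = "longmed_format_error")

  # grouping with three levels
  d <- read_long_table(write_excerpt())
  roles3 <- var_roles(id = "PatientID", date = "Date",
                      occasion = "Measurement", outcomes = "Fatigue",
                      grouping = "Measurement")
  expect_error(validate_roles(d, roles3), class = "longmed_role_error")

  # non-numeric outcome
  roles_bad <- var_roles(id = "PatientID", date = "Date",
                         occasion = "Measurement", outcomes = "Sex")
  expect_error(validate_roles(d, roles_bad), class = "longmed_type_error")
})

test_that("dichotomization follows the strictly-greater rule", {
  expect_equal(dichotomize(c(0, 0.1, 5, NA), 0), c(0L, 1L, 1L, NA))
  expect_equal(dichotomize(c(1, 2, 3), 5), c(0L, 0L, 0L))
  v <- c(2, 7, 7)
  expect_equal(dichotomize(v, max(v))[v == max(v)], c(0L, 0L))
  # idempotent on 0/1 input through threshold 0.5
  b <- c(0L, 1L, NA, 1L)
  expect_equal(dichotomize(as.numeric(b), 0.5), b)
  expect_error(dichotomize(letters, 0), class = "longmed_type_error")
})

test_that("days since first evaluation is per-subject date arithmetic", {
  d <- excerpt_data()
  d2 <- add_days_since_first(d)
  expect_equal(d2$days_since_first, rep(c(0, 14, 180, 365), 2))

  lines <- excerpt_lines()[1:2]  # single-evaluation subject
  d1 <- validate_roles(read_long_table(write_excerpt(lines)),
                       excerpt_roles(occasion_levels = "0"))
  expect_equal(add_days_since_first(d1)$days_since_first, 0)

  # jitter-free generated cohort: offsets equal the occasion day labels
  g <- small_cohort(n = 12, q = 2, seed = 3)
  g2 <- add_days_since_first(g)
  expect_equal(g2$days_since_first,
               as.numeric(as.character(g2$occasion)))
})

test_that("the evaluations-per-subject histogram sums to the row count", {
  for (seed in 1:3) {
    g <- small_cohort(n = 25, q = 3, seed = seed,
                      dropout_probs = c(0, 0.2, 0.3, 0.3))
    ov <- data_overview(g)
    h <- ov$evaluations_per_subject
    expect_equal(sum(h$n_evaluations * h$n_subjects), ov$n_rows)
    expect_equal(sum(h$n_subjects), ov$n_subjects)
  }
})

test_that("write-then-read round-trips values and roles", {
  g <- small_cohort(n = 10, q = 3, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_long_table(g, path)
  back <- validate_roles(read_long_table(path), roles_of(g))
  g_plain <- g
  attr(g_plain, "ground_truth") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(g_plain))
  expect_equal(roles_of(back)$outcomes, roles_of(g)$outcomes)
})

test_that("occasion subsetting keeps only the requested level", {
  g <- small_cohort(n = 10, q = 2, seed = 5)
  b <- at_occasion(g, "14")
  expect_true(all(as.character(b$occasion) == "14"))
  expect_error(at_occasion(g, "999"), class = "longmed_validation_error")
})
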