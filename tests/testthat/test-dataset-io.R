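test_that("a simple two-group CSV parses into a cohort table", {
  path <- write_csv_fixture(c(
    "group,age",
    "A,31", "A,45", "B,52", "B,38"))
  tab <- read_cohort_csv(path, "group", list(variable_spec("age", "numeric")))
  expect_equal(tab$n1, 2)
  expect_equal(tab$n2, 2)
  expect_equal(tab$group_labels, c("A", "B"))   # lexicographic mapping
  expect_false(any(missing_mask(tab)))
  expect_equal(tab$data$age, c(31, 45, 52, 38))
})

test_that("group columns with other than two levels are rejected", {
  path3 <- write_csv_fixture(c("group,age", "A,1", "B,2", "C,3"))
  expect_error(read_cohort_csv(path3, "group",
                               list(variable_spec("age", "numeric"))),
               "exactly two")
  path1 <- write_csv_fixture(c("group,age", "A,1", "A,2"))
  expect_error(read_cohort_csv(path1, "group",
                               list(variable_spec("age", "numeric"))),
               "exactly two")
})

test_that("NA tokens populate the missing mask and values out of level sets fail", {
  path <- write_csv_fixture(c(
    "group,age,smoker",
    "A,31,yes", "A,,no", "A,52,yes",
    "B,38,NA", "B,60,no", "B,41,yes"))
  tab <- read_cohort_csv(path, "group", small_specs())
  expect_equal(sum(missing_mask(tab)), 2)
  expect_true(is.na(tab$data$age[2]))
  expect_true(is.na(tab$data$smoker[4]))

  bad <- write_csv_fixture(c("group,smoker", "A,yes", "A,maybe", "B,no"))
  expect_error(
    read_cohort_csv(bad, "group",
                    list(variable_spec("smoker", "categorical",
                                       levels = c("yes", "no")))),
    "row 2.*smoker")
})

test_that("missing spec columns and unknown group columns raise configuration errors", {
  path <- write_csv_fixture(c("group,age", "A,1", "B,2"))
  expect_error(read_cohort_csv(path, "grp",
                               list(variable_spec("age", "numeric"))),
               "not found")
  expect_error(read_cohort_csv(path, "group",
                               list(variable_spec("bmi", "numeric"))),
               "missing from file")
})

test_that("write/read round-trip reproduces groups, values and mask exactly", {
  m <- default_model()
  m <- cohort_model(m$variables, n1 = 17, n2 = 23, missing_rate = 0.15)
  tab <- suppressWarnings(generate_cohort(m, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path, "group", tab$specs)
  expect_identical(back$groups, tab$groups)
  expect_identical(back$group_labels, tab$group_labels)
  expect_identical(missing_mask(back), missing_mask(tab))
  for (nm in names(tab$data)) expect_identical(back$data[[nm]],
                                               tab$data[[nm]])
})

test_that("extract_complete drops units per variable only", {
  tab <- small_cohort(missing_cells = list(list(2, "age"), list(5, "age"),
                                           list(3, "smoker")))
  cc_age <- extract_complete(tab, "age")
  expect_equal(length(cc_age$x1), 3)   # one of four group-1 ages missing
  expect_equal(length(cc_age$x2), 3)
  cc_smoker <- extract_complete(tab, "smoker")
  expect_equal(length(cc_smoker$x1), 3)
  expect_equal(length(cc_smoker$x2), 4)

  # complete-case counts reconcile with the mask for every variable
  mask <- missing_mask(tab)
  for (nm in names(tab$data)) {
    cc <- extract_complete(tab, nm)
    expect_equal(length(cc$x1) + length(cc$x2),
                 nrow(tab$data) - sum(mask[, nm]))
  }
})

test_that("a variable entirely missing in one group is a degenerate-variable error", {
  tab <- small_cohort(missing_cells = list(list(5, "age"), list(6, "age"),
                                           list(7, "age"), list(8, "age")))
  expect_error(extract_complete(tab, "age"), "degenerate")
  expect_error(extract_complete(tab, "weight"), "unknown variable")
})

test_that("summaries give n-1 SDs and percentages totalling 100", {
  s <- summarize_variable(c(1, 2, 3, 4), c(5, 5, 5),
                          variable_spec("x", "numeric"))
  expect_equal(s$mean1, 2.5)
  expect_equal(round(s$sd1, 4), 1.2910)   # hand-computed sample SD
  expect_equal(s$mean2, 5)
  expect_equal(s$sd2, 0)

  one <- summarize_variable(c(3), c(1, 2), variable_spec("x", "numeric"))
  expect_true(is.na(one$sd1))             # undefined, never zero

  spec <- variable_spec("smoker", "categorical", levels = c("yes", "no"))
  cs <- summarize_variable(c("yes", "yes", "no", "no"),
                           c("yes", "no", "no"), spec)
  expect_equal(unname(cs$pct1), c(50, 50))
  expect_equal(sum(cs$pct1), 100, tolerance = 1e-9)
  expect_equal(sum(cs$pct2), 100, tolerance = 1e-9)
})

test_that("variable specs round-trip through the YAML config", {
  specs <- small_specs()
  path <- withr::local_tempfile(fileext = ".yml")
  write_variable_specs(specs, path)
  back <- read_variable_specs(path)
  expect_equal(length(back), 2)
  expect_equal(back$age$kind, "numeric")
  expect_equal(back$smoker$levels, c("yes", "no"))
})
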