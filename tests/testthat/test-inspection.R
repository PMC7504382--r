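# inspection records: schema validation, YAML round trip, the full
# assessment pipeline and campaign mode

test_that("the packaged worked-example fixture parses and matches the in-code record", {
  path <- system.file("extdata", "worked_example.yaml", package = "lpac")
  rec <- read_inspection(path)
  expect_s3_class(rec, "lpac_inspection")
  fit_file <- assess_quiet(rec)
  fit_code <- assess_quiet(make_worked_example())
  expect_equal(fit_file$risks, fit_code$risks)
  expect_equal(fit_file$base, fit_code$base)
})

test_that("assessing the worked example reproduces the published results table", {
  fit <- assess_quiet(make_worked_example())
  expect_equal(fit$policy$epsilon, 4) # selected, not supplied
  expect_equal(
    stats::setNames(fit$base$cv, fit$base$parameter),
    c(r_r = 9, b_r = 6, e = 15, e_c = 5, p_i = 3, l_s = 15)
  )
  res <- fit$risks[match(table10$code, fit$risks$code), ]
  expect_equal(res$ab_r, table10$ab_r)
  expect_equal(res$a_pac_display, table10$a_pac_2dp)
  expect_equal(res$lpac_pct_display, table10$pct_int)
  expect_equal(res$control, unname(table12_controls[res$code]))
  expect_equal(fit$techniques$lpac_pct_display, c(32, 34, 51, 20))
  expect_equal(
    fit$techniques$technique,
    c("safety", "hygiene", "ergonomics", "psychosociology")
  )
})

test_that("assessment is deterministic and the YAML round trip is idempotent", {
  rec <- make_worked_example()
  f1 <- assess_quiet(rec)
  f2 <- assess_quiet(rec)
  expect_identical(tidy(f1), tidy(f2))

  p1 <- tempfile(fileext = ".yaml")
  p2 <- tempfile(fileext = ".yaml")
  write_inspection(rec, p1)
  write_inspection(read_inspection(p1), p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical re-serialisation
})

test_that("schema violations are rejected with distinct classes and field paths", {
  rec <- make_worked_example()

  empty <- rec
  empty$risks <- rec$risks[0, ]
  expect_error(validate_inspection(empty), regexp = "at least one risk",
               class = "lpac_error_schema")

  stray <- rec
  stray$overrides <- c(rec$overrides, list("999" = list(r_r = 5)))
  expect_error(validate_inspection(stray), regexp = "999",
               class = "lpac_error_schema")

  unknown <- rec
  unknown$risks$code[1] <- "999"
  expect_error(validate_inspection(unknown), class = "lpac_error_unknown_risk")

  nosurvey <- rec
  nosurvey$survey <- NULL
  expect_error(validate_inspection(nosurvey), regexp = "l_s",
               class = "lpac_error_schema")
  # ... but an explicit satisfaction value stands in for the survey
  nosurvey$parameters <- list(l_s = 15)
  expect_s3_class(validate_inspection(nosurvey), "lpac_inspection")
  expect_equal(assess_quiet(nosurvey)$techniques$lpac_pct_display,
               c(32, 34, 51, 20))

  expect_error(read_inspection(tempfile()), class = "lpac_error_schema")
  badyaml <- tempfile(fileext = ".yaml")
  writeLines(c("site: [unclosed"), badyaml)
  expect_error(read_inspection(badyaml), class = "lpac_error_parse")
})

test_that("a record with every observation at the safest end earns optimal control", {
  fit <- assess(minimal_record())
  expect_equal(unname(stats::setNames(fit$base$cv, fit$base$parameter)),
               c(1, 1, 1, 25, 25, 25))
  expect_equal(fit$risks$a_pac, 1 / 15625)
  expect_equal(fit$policy$epsilon, 0.4) # smallest menu factor suffices
  expect_true(all(fit$risks$control == "optimal"))
  expect_identical(fit$global$control, "optimal")
})

test_that("campaign mode binds per-risk rows, orders by date, and skips malformed files", {
  dir <- tempfile()
  dir.create(dir)
  recs <- generate_campaign(campaign_scenario(n_inspections = 3, seed = 11))
  # write out of order to check date ordering
  write_inspection(recs[[3]], file.path(dir, "a_third.yaml"))
  write_inspection(recs[[1]], file.path(dir, "b_first.yaml"))
  write_inspection(recs[[2]], file.path(dir, "c_second.yaml"))
  camp <- assess_batch(dir)
  expect_equal(nrow(camp$results), sum(purrr::map_int(recs, ~ nrow(.x$risks))))
  expect_equal(nrow(camp$series), 3)
  expect_identical(camp$series$inspection_number, 1:3)
  expect_false(is.unsorted(camp$series$date))
  expect_equal(nrow(camp$skipped), 0)

  writeLines("risks: []", file.path(dir, "broken.yaml"))
  expect_warning(camp2 <- assess_batch(dir), class = "lpac_warn_skipped_file")
  expect_equal(nrow(camp2$skipped), 1)
  expect_equal(nrow(camp2$series), 3)

  empty <- tempfile()
  dir.create(empty)
  expect_error(assess_batch(empty), class = "lpac_error_schema")
})

test_that("tidy, glance and the report writers expose the assessment", {
  fit <- assess_quiet(make_worked_example())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  expect_true(all(c("code", "ab_r", "a_pac", "lpac_pct", "control") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_risks, 10L)
  expect_equal(gl$epsilon, 4)
  expect_equal(gl$max_risk_code, "440")

  csv <- tempfile(fileext = ".csv")
  write_report(fit, csv, format = "csv")
  got <- utils::read.csv(csv, colClasses = "character")
  expect_equal(names(got)[1:8],
               c("code", "risk", "tolerance", "a_pac", "lpac", "control",
                 "technique", "technique_lpac"))
  expect_equal(got$a_pac[got$code == "010"], "4.38")
  expect_equal(got$lpac[got$code == "110"], "67%")
  expect_equal(got$technique_lpac[got$code == "010"], "32%")
  expect_equal(nrow(got), 11) # ten risks + global row

  js <- tempfile(fileext = ".json")
  write_report(fit, js, format = "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$epsilon, 4)
  expect_length(parsed$risks, 10)

  txt <- tempfile(fileext = ".txt")
  write_report(fit, txt, format = "text")
  expect_true(any(grepl("Technique aggregates", readLines(txt))))

  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
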