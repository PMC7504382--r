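# rubric-derived characteristic values and the borderline geometry

rr_facade <- list(
  graphics = 9, setting_out = 5, workers = 9, qualification = 5,
  auxiliary_systems_level = 15, tools_machinery = 15,
  material_weight = 3, manageability = 5
)

test_that("relative risk averages the eight factor selections and rounds to the scale", {
  got <- cv_relative_risk(rr_facade)
  expect_equal(got$raw, 8.25)
  expect_identical(got$cv, 9L)

  all1 <- purrr::map(rr_facade, ~1)
  expect_identical(cv_relative_risk(all1)$cv, 1L)
  all25 <- purrr::map(rr_facade, ~25)
  expect_identical(cv_relative_risk(all25)$cv, 25L)

  # selection order never matters
  expect_equal(cv_relative_risk(rev(rr_facade)), cv_relative_risk(rr_facade))
  # data-frame input is equivalent to the named list
  df <- tibble::tibble(factor = names(rr_facade), value = unlist(rr_facade))
  expect_equal(cv_relative_risk(df), cv_relative_risk(rr_facade))
})

test_that("rubric selections are validated: coverage, names, and scale membership", {
  expect_error(
    cv_relative_risk(rr_facade[-1]),
    regexp = "missing.*graphics", class = "lpac_error_validation"
  )
  expect_error(
    cv_relative_risk(c(rr_facade, list(extra_factor = 3))),
    regexp = "unknown", class = "lpac_error_validation"
  )
  bad <- rr_facade
  bad$workers <- 7 # not on the scale
  expect_error(
    cv_relative_risk(bad),
    regexp = "workers=7", class = "lpac_error_validation"
  )
})

test_that("degree of exposure averages the two criteria with midpoint-up rounding", {
  got <- cv_exposure(9, 15)
  expect_equal(got$raw, 12)
  expect_identical(got$cv, 15L) # midpoint rounds up
  expect_identical(cv_exposure(1, 1)$cv, 1L)
  expect_identical(cv_exposure(25, 9)$cv, 15L) # 17 is nearer 15 than 25
  expect_error(cv_exposure(9, 10), class = "lpac_error_validation")
})

test_that("economic capacity and participative interest reproduce the facade figures", {
  ec <- cv_economic_capacity(list(
    individual_organization = 9, team_organization = 5, work_organization = 5,
    individual_protection = 3, collective_safeguards = 5
  ))
  expect_equal(ec$raw, 5.40)
  expect_identical(ec$cv, 5L)
  ec9 <- cv_economic_capacity(list(
    individual_organization = 9, team_organization = 9, work_organization = 9,
    individual_protection = 9, collective_safeguards = 9
  ))
  expect_identical(ec9$cv, 9L)
  ec_low <- cv_economic_capacity(list(
    individual_organization = 1, team_organization = 1, work_organization = 1,
    individual_protection = 3, collective_safeguards = 3
  ))
  expect_equal(ec_low$raw, 1.8)
  expect_identical(ec_low$cv, 1L)

  pi_ <- cv_participative_interest(list(
    worker_information = 5, individual_participation = 5,
    group_participation = 3, external_appearance = 1
  ))
  expect_equal(pi_$raw, 3.50)
  expect_identical(pi_$cv, 3L)
  pi_mid <- cv_participative_interest(list(
    worker_information = 9, individual_participation = 9,
    group_participation = 5, external_appearance = 5
  ))
  expect_equal(pi_mid$raw, 7) # midpoint: up to 9
  expect_identical(pi_mid$cv, 9L)
})

test_that("borderline zones follow the height-dependent border distances", {
  expect_identical(borderline_zone(0.8, 130), "within_safe")
  expect_identical(borderline_zone(4, 125), "borderline") # border at 125 cm below 5 m
  expect_identical(borderline_zone(4, 0), "within_risk")
  # moving away from the hazard never moves toward a riskier zone
  zones <- c("within_risk", "close_to_risk", "borderline",
             "close_to_borderline", "within_safe")
  for (h in c(0.5, 2, 4, 6, 12, 20)) {
    idx <- match(borderline_zone(rep(h, 501), seq(0, 500, by = 1)), zones)
    expect_true(all(diff(idx) >= 0))
  }
  expect_error(borderline_zone(4, -1), class = "lpac_error_range")
  expect_error(borderline_zone(0, 100), class = "lpac_error_range")
})

test_that("borderline characteristic values come from the platform grid", {
  expect_identical(cv_borderline(4, distance_cm = 0)$cv, 6L) # facade: at the edge below 5 m
  expect_identical(cv_borderline(0.8, zone = "within_safe")$cv, 1L)
  expect_identical(cv_borderline(18, zone = "within_risk")$cv, 25L)
  # depth below ground uses the absolute magnitude
  expect_identical(cv_borderline(-4, distance_cm = 0)$cv, 6L)

  # supplying the zone directly agrees with deriving it from geometry
  for (h in c(0.8, 2, 4, 7, 12, 18)) {
    for (d in c(0, 60, 90, 110, 140, 190, 260)) {
      z <- borderline_zone(h, d)
      expect_identical(
        cv_borderline(h, distance_cm = d)$cv,
        cv_borderline(h, zone = z)$cv
      )
    }
  }
  # geometry wins over a mismatching explicit zone, with a warning
  expect_warning(
    got <- cv_borderline(4, distance_cm = 0, zone = "within_safe"),
    class = "lpac_warn_zone_mismatch"
  )
  expect_identical(got$cv, 6L)
  expect_error(cv_borderline(4, zone = "nowhere"), class = "lpac_error_validation")
  expect_error(cv_borderline(4), class = "lpac_error_validation")
})

test_that("the borderline grid is monotone across bands and zones and bounded by 1..25", {
  g <- lpac:::borderline_grid()
  expect_identical(dim(g), c(5L, 6L))
  expect_true(all(g >= 1 & g <= 25))
  expect_true(all(apply(g, 1, diff) >= 0)) # riskier with height
  expect_true(all(apply(g, 2, diff) >= 0)) # riskier toward the hazard
  expect_identical(unname(g["within_safe", ]), c(1, 2, 4, 7, 12, 19))
  expect_identical(unname(g["within_risk", ]), c(2, 4, 6, 11, 18, 25))
})

test_that("rubric tables load from the packaged file and are validated", {
  tabs <- load_rubric_tables()
  expect_named(
    tabs,
    c("relative_risk", "exposure", "economic_capacity", "participative_interest")
  )
  purrr::walk(tabs, function(t) {
    expect_true(all(table(t$factor) == 6))
    expect_identical(unique(t$value[t$option == 6]), 25L)
  })
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "values: [1, 3, 5, 9, 15, 25]",
    "tables:",
    "  relative_risk:",
    "    direction: increasing",
    "    factors:",
    "      graphics: [a, b, c]"
  ), bad)
  expect_error(load_rubric_tables(bad), class = "lpac_error_schema")
})
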