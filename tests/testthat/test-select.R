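test_that("cases keep exactly the visits before the first positive SDI", {
  cohort <- dplyr::bind_rows(
    make_series("A", c(0, 3, 6, 9), sdi = c(0, 0, 0, 1)),
    make_series("B", c(0, 3), sdi = c(1, 1)),          # damaged at baseline
    make_series("C", c(0, 3, 6), sdi = c(0, 1, 1)),    # 1-visit prefix
    make_series("D", c(0, 3, 6), sdi = c(0, 0, 0))     # never damaged
  )
  cases <- select_cases(cohort)
  expect_setequal(unique(cases$patient_id), c("A", "C"))
  expect_true(all(cases$label == 1))
  expect_equal(cases$month[cases$patient_id == "A"], c(0, 3, 6))
  expect_equal(cases$month[cases$patient_id == "C"], 0)
})

test_that("controls need >= 5 visits and a reserved 2-year damage-free window", {
  cohort <- dplyr::bind_rows(
    # 8 visits over 48 months: control, prefix = months <= 24
    make_series("A", seq(0, 48, length.out = 8), sdi = rep(0, 8)),
    # only 4 visits: excluded
    make_series("B", c(0, 12, 24, 48), sdi = rep(0, 4)),
    # 5 visits but follow-up too short to spare any pre-window visit
    make_series("C", c(0, 5, 10, 15, 20), sdi = rep(0, 5)),
    # damaged: never a control
    make_series("D", c(0, 6, 12, 24, 36, 48), sdi = c(0, 0, 0, 1, 1, 1))
  )
  controls <- select_controls(cohort)
  expect_equal(unique(controls$patient_id), "A")
  expect_true(all(controls$label == 0))
  expect_true(all(controls$month[controls$patient_id == "A"] <= 24))
  expect_equal(sum(controls$patient_id == "A"), 4) # months 0,6.86,13.7,20.6

  # the window is configurable
  expect_equal(
    unique(select_controls(cohort, min_horizon_months = 12)$patient_id),
    c("A", "C")
  )
})

test_that("cases and controls are disjoint and exclude baseline damage", {
  cohort <- generate_cohort(cohort_config(n_patients = 100, seed = 6))
  cases <- unique(select_cases(cohort)$patient_id)
  controls <- unique(select_controls(cohort)$patient_id)
  expect_length(intersect(cases, controls), 0)
  baseline_sdi <- cohort |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(first_sdi = dplyr::first(sdi))
  damaged_at_start <- baseline_sdi$patient_id[baseline_sdi$first_sdi >= 1]
  expect_length(intersect(c(cases, controls), damaged_at_start), 0)
})

test_that("default cohort yields case/control counts near the study structure", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  sel <- dplyr::distinct(select_analysis_set(cohort), patient_id, label)
  n_case <- sum(sel$label == 1)
  n_control <- sum(sel$label == 0)
  # order-of-magnitude band around 38 cases / 94 controls
  expect_gte(n_case, 15); expect_lte(n_case, 110)
  expect_gte(n_control, 60); expect_lte(n_control, 380)
})

test_that("rare binary features are dropped at the ever-positive cutoff", {
  # flag_a positive in 3 patients (dropped), flag_b in 4 (retained);
  # sex/activity are binary features too, so keep them above the cutoff
  cohort <- purrr::map_dfr(1:8, function(i) {
    make_series(paste0("P", i), c(0, 3, 6), sdi = c(0, 0, 0),
                activity = c(1L, as.integer(i %% 2), 0L),
                sex = if (i <= 4) "M" else "F",
                flag_a = as.integer(i <= 3), flag_b = as.integer(i <= 4))
  })
  cohort$label <- 1L
  cohort$label[cohort$patient_id %in% paste0("P", 5:8)] <- 0L
  ds <- encode_features(cohort, codebook = c("flag_a", "flag_b"))
  filtered <- filter_rare_binary_features(ds, min_positive = 4)
  expect_false("flag_a" %in% filtered$features)
  expect_true("flag_b" %in% filtered$features)
  expect_equal(attr(filtered, "dropped_features"), "flag_a")

  # a never-positive feature is likewise dropped; order is preserved
  expect_equal(filtered$features,
               setdiff(ds$features, "flag_a"))

  # idempotence
  again <- filter_rare_binary_features(filtered, min_positive = 4)
  expect_equal(again$features, filtered$features)
  expect_equal(
    purrr::map(again$sequences, "x"),
    purrr::map(filtered$sequences, "x")
  )

  expect_error(filter_rare_binary_features(ds, min_positive = 100),
               class = "lupusrnn_data_error")
})

test_that("encoding binarizes and standardizes as specified", {
  cohort <- dplyr::bind_rows(
    make_series("A", c(0, 3, 6), sdi = c(0, 0, 0),
                activity = c(0, 1, 1), sex = "M", age0 = 50),
    make_series("B", c(0, 3), sdi = c(0, 0), activity = c(1, 0), age0 = 30)
  )
  cohort$label <- rep(c(1L, 0L), c(3, 2))
  ds <- encode_features(cohort, codebook = c("flag_a", "flag_b"))
  expect_equal(ds$features, c("sex", "age", "flag_a", "flag_b", "activity"))
  xa <- ds$sequences[[1]]$x
  expect_equal(unname(xa[, "sex"]), c(1, 1, 1))
  expect_equal(unname(xa[, "activity"]), c(0, 1, 1))
  ages <- unlist(purrr::map(ds$sequences, function(s) s$x[, "age"]))
  expect_equal(mean(ages), 0, tolerance = 1e-12)
  expect_equal(sd(ages), 1, tolerance = 1e-12)
  expect_error(encode_features(cohort, codebook = c("flag_a", "nope")),
               "nope", class = "lupusrnn_schema_error")
})
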