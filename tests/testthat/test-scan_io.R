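test_that("roster round-trips through CSV and reports class counts", {
  ros <- make_roster(default_group_specs(), seed = 1)
  expect_equal(nrow(ros), 41)
  expect_equal(length(group_ids(ros)), 4)
  counts <- table(ros$deprivation_class)
  expect_equal(as.vector(counts[c("ELD", "LLD", "EMD", "ND")]),
               c(10, 8, 7, 16))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roster(ros, path)
  back <- read_roster(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ros),
               ignore_attr = TRUE)
})

test_that("roster validation rejects malformed tables", {
  base <- tibble::tibble(
    id = c("Gust", "Maxi"), group_id = "MS1", sex = "female",
    age_class = "mature", deprivation_class = "ELD")
  expect_s3_class(roster(base), "roster")
  expect_error(roster(base[, -2]), "missing column")
  expect_error(roster(dplyr::mutate(base, id = "Gust")), "duplicate id.*Gust")
  expect_error(roster(dplyr::mutate(base, sex = c("female", "f"))),
               "unknown sex")
  expect_error(roster(dplyr::mutate(base, deprivation_class = "XX")),
               "unknown deprivation_class")
  expect_error(roster(base[0, ]), "empty")
  expect_error(roster(dplyr::mutate(base, group_id = c("A", "B"))),
               "fewer than 2")
})

test_that("age class follows the birth-year rule", {
  expect_equal(age_class_from_age(c("female", "male"), c(13, 16)),
               c("mature", "mature"))
  expect_equal(age_class_from_age("female", 34), "old")
  expect_equal(age_class_from_age("male", 33), "mature")
  expect_error(age_class_from_age("male", 15), "adult threshold")
  expect_error(age_class_from_age("female", 12), "adult threshold")
})

write_scan_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("group,period,scan,behaviour,actor,recipient", lines), path)
  path
}

test_that("scan tables parse, symmetrize and validate ids", {
  ros <- tiny_roster(3, group = "MS1")   # ids MS1_01..MS1_03
  path <- write_scan_csv(c(
    "MS1,2003,1,proximity,MS1_01,MS1_02",
    "MS1,2003,1,grooming,MS1_01,MS1_02",
    "MS1,2003,2,none,,"))
  sets <- read_scan_table(path, ros)
  expect_named(sets, "MS1:2003")
  rec <- sets[[1]]
  expect_equal(rec$n_scans, 2L)
  expect_equal(sum(rec$events$behaviour == "proximity"), 1)
  expect_equal(sum(rec$events$behaviour == "grooming"), 1)

  # both orientations of a proximity pair collapse to one unordered pair
  path2 <- write_scan_csv(c(
    "MS1,2003,1,proximity,MS1_01,MS1_02",
    "MS1,2003,1,proximity,MS1_02,MS1_01"))
  rec2 <- read_scan_table(path2, ros)[[1]]
  expect_equal(nrow(rec2$events), 1)
  expect_equal(rec2$events$actor, "MS1_01")

  path3 <- write_scan_csv("MS1,2003,1,proximity,MS1_01,ZZ")
  expect_error(read_scan_table(path3, ros), "ZZ")
  path4 <- write_scan_csv("MS1,2003,1,grooming,MS1_01,MS1_01")
  expect_error(read_scan_table(path4, ros), "actor equals recipient")
})

test_that("scan record sets round-trip and parsing is row-order-insensitive", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_scan_table(inst$records, path)
    back <- read_scan_table(path, inst$roster)[[1]]
    expect_equal(back$events, inst$records$events)
    expect_equal(back$n_scans, inst$records$n_scans)
  }
  inst <- random_instance(42)
  ev <- inst$records$events
  shuffled <- scan_record_set("G1", "P1", inst$records$n_scans,
                              ev[sample(nrow(ev)), ])
  expect_equal(shuffled$events, inst$records$events)
})

test_that("validate_records reports violations without raising", {
  inst <- random_instance(7)
  rep <- validate_records(inst$records, inst$roster)
  expect_equal(rep$n_violations, 0)

  bad_events <- dplyr::bind_rows(
    inst$records$events,
    tibble::tibble(scan = 1L, behaviour = "proximity",
                   actor = "G1_01", recipient = "G1_01"))
  bad <- scan_record_set("G1", "P1", inst$records$n_scans, bad_events,
                         normalize = FALSE)
  rep_bad <- validate_records(bad, inst$roster)
  expect_equal(sum(rep_bad$violations$kind == "self_pair"), 1)

  # a set with the study-scale scan count reports it verbatim
  big <- scan_record_set("G1", "P1", 543,
                         inst$records$events)
  expect_equal(validate_records(big, inst$roster)$n_scans, 543)

  stranger <- scan_record_set("G1", "P1", 5, tibble::tibble(
    scan = 1L, behaviour = "grooming", actor = "G1_01", recipient = "QQ"),
    normalize = FALSE)
  expect_equal(validate_records(stranger, inst$roster)$violations$kind,
               "unknown_id")
})
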