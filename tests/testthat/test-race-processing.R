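triplet <- function(date = "2022-11-05", flags = c("", "", "")) {
  rbind(race_obs("P1", date, "swim", 70, 750, 600, flags[[1]]),
        race_obs("P1", date, "cycle", 170, 20000, 2100, flags[[2]]),
        race_obs("P1", date, "run", 85, 5000, 1400, flags[[3]]))
}

test_that("exclusion chaining drops dependent legs", {
  # flagged cycle: swim survives, cycle and run go
  out <- apply_exclusions(triplet(flags = c("", "gps_fail", "")))
  expect_equal(out$discipline, "swim")
  # clean triplet survives whole
  expect_equal(nrow(apply_exclusions(triplet())), 3)
  # run with no same-day swim/cycle rows is dropped
  out <- apply_exclusions(race_obs("P2", "2022-11-05", "run"))
  expect_equal(nrow(out), 0)
  # flagged swim removes everything
  out <- apply_exclusions(triplet(flags = c("unwell", "", "")))
  expect_equal(nrow(out), 0)
})

test_that("apply_exclusions is idempotent and ordered within participant-dates", {
  set.seed(42)
  flags_pool <- c("", "", "", "unwell", "gps_fail", "imu_attachment_fault",
                  "injured_during_race")
  for (rep in 1:20) {
    obs <- do.call(rbind, lapply(1:4, function(i) {
      triplet(date = sprintf("2022-11-%02d", i),
              flags = sample(flags_pool, 3, replace = TRUE))
    }))
    obs$participant_id <- sample(c("P1", "P2"), nrow(obs), replace = TRUE)
    once <- apply_exclusions(obs)
    expect_identical(apply_exclusions(once), once)
    # chaining implies run count <= cycle count <= swim count
    counts <- table(factor(once$discipline,
                           levels = c("swim", "cycle", "run")))
    expect_lte(counts[["run"]], counts[["cycle"]])
    expect_lte(counts[["cycle"]], counts[["swim"]])
  }
})

test_that("same-day races are averaged to a single result", {
  two <- rbind(race_obs("P1", "2022-12-01", "swim", 80, 740, 590),
               race_obs("P1", "2022-12-01", "swim", 84, 760, 610))
  m <- merge_same_day(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$cadence, 82)
  expect_equal(m$distance_m, 750)
  expect_equal(m$duration_s, 600)
  # single race untouched
  one <- race_obs("P1", "2022-12-01", "run", 85)
  expect_equal(merge_same_day(one)$cadence, 85)
  # three races -> mean
  three <- do.call(rbind, lapply(c(60, 70, 80), function(cc) {
    race_obs("P1", "2022-12-02", "cycle", cc)
  }))
  expect_equal(merge_same_day(three)$cadence, 70)
  # merging never increases rows and keeps every participant
  mixed <- rbind(two, race_obs("P2", "2022-12-01", "swim", 70))
  mm <- merge_same_day(mixed)
  expect_lte(nrow(mm), nrow(mixed))
  expect_setequal(unique(mm$participant_id), c("P1", "P2"))
})

test_that("same-day merge pools flags and rejects season conflicts", {
  two <- rbind(race_obs("P1", "2023-01-07", "swim", 80, flags = "gps_fail"),
               race_obs("P1", "2023-01-07", "swim", 84))
  m <- merge_same_day(two)
  expect_equal(m$flags, "gps_fail")
  # a pooled gps_fail then excludes the merged race
  expect_equal(nrow(apply_exclusions(m)), 0)
  bad <- rbind(race_obs("P1", "2023-01-07", "swim", 80, season = 1),
               race_obs("P1", "2023-01-07", "swim", 84, season = 2))
  expect_error(merge_same_day(bad), class = "inconsistent_record")
})

test_that("distance imputation averages peers and fails without peers", {
  expect_equal(as.numeric(impute_distance(c(5010, 4990))), 5000)
  expect_true(attr(impute_distance(c(5100)), "imputed"))
  expect_equal(as.numeric(impute_distance(5100)), 5100)
  expect_error(impute_distance(numeric(0)), class = "imputation_impossible")
})

test_that("race velocity arithmetic and validation", {
  expect_equal(race_velocity(5000, 1000), 5)
  expect_equal(race_velocity(0, 600), 0)
  expect_equal(race_velocity(750, 600), 1.25)
  expect_error(race_velocity(5000, 0), class = "invalid_parameter")
})

test_that("week numbering supports season and participant conventions", {
  obs <- rbind(race_obs("P1", "2022-10-01", "swim"),
               race_obs("P1", "2022-10-15", "swim"),
               race_obs("P2", "2022-10-08", "swim"),
               race_obs("P2", "2022-10-22", "swim"))
  s <- assign_weeks(obs, "season")
  expect_equal(s$week, c(0L, 2L, 1L, 3L))
  p <- assign_weeks(obs, "participant")
  expect_equal(p$week, c(0L, 2L, 0L, 2L))
})

test_that("assemble_dataset merges then excludes then assigns weeks", {
  obs <- rbind(
    triplet("2022-10-01"),
    race_obs("P1", "2022-10-08", "swim", 72),
    race_obs("P1", "2022-10-08", "swim", 74),
    race_obs("P1", "2022-10-08", "cycle", 170, flags = "gps_fail"))
  out <- assemble_dataset(obs)
  # same-day swims averaged; flagged cycle dropped
  expect_equal(out$cadence[out$discipline == "swim" & out$week == 1], 73)
  expect_false(any(out$discipline == "cycle" & out$week == 1))
  expect_equal(sort(unique(out$week)), c(0L, 1L))
})
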