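test_that("waveform constructor enforces its invariants", {
  expect_s3_class(waveform(rep(80, 32), fs = 100, kind = "pressure"),
                  "waveform")
  expect_error(waveform(rep(80, 10), fs = 100, kind = "pressure"),
               "at least 16")
  expect_error(waveform(rep(80, 32), fs = 0, kind = "pressure"), "positive")
  expect_error(waveform(c(rep(80, 31), -1), fs = 100, kind = "pressure"),
               "strictly positive")
  # flow may dip slightly negative (valve-closure transient) but not deeply
  expect_s3_class(waveform(c(seq(0, 100, length.out = 20),
                             seq(100, -10, length.out = 12)),
                           fs = 100, kind = "flow"), "waveform")
  expect_error(waveform(c(seq(0, 100, length.out = 20),
                          seq(100, -60, length.out = 12)),
                        fs = 100, kind = "flow"), "transient")
  # duration must match one cycle when HR is given
  expect_error(waveform(rep(80, 50), fs = 100, kind = "pressure", hr = 75),
               "inconsistent")
  expect_silent(waveform(rep(80, 80), fs = 100, kind = "pressure", hr = 75))
})

test_that("cohort table requires unique ids and non-emptiness", {
  beat <- default_beat()
  expect_error(cohort_table(list()), "at least one")
  r <- beat$record
  expect_error(cohort_table(list(r, r)), "duplicate")
})

test_that("write/read round-trip reproduces a synthetic cohort", {
  gc <- cached_cohort()
  small <- cohort_table(gc$cohort$records[1:3], provenance = "synthetic")
  dir <- withr::local_tempdir()
  write_cohort(small, dir)
  files <- list.files(dir)
  expect_length(files, 4L)              # 3 waveform files + cohort.csv
  expect_true("cohort.csv" %in% files)

  back <- read_cohort(dir, file.path(dir, "cohort.csv"))
  expect_length(back, 3L)
  expect_equal(attr(back, "exclusions")$id, character(0))
  for (i in 1:3) {
    orig <- small$records[[i]]
    got <- back$records[[match(orig$id,
                               vapply(back$records, `[[`, "", "id"))]]
    expect_equal(got$pressure$samples, orig$pressure$samples,
                 tolerance = 1e-6)
    expect_equal(got$flow$samples, orig$flow$samples, tolerance = 1e-6)
    expect_equal(got$pressure$fs, orig$pressure$fs, tolerance = 1e-9)
    expect_equal(got$sv, orig$sv, tolerance = 1e-6)
  }
})

test_that("a subject exported in kPa is dropped with a logged reason", {
  gc <- cached_cohort()
  small <- cohort_table(gc$cohort$records[1:3], provenance = "synthetic")
  dir <- withr::local_tempdir()
  write_cohort(small, dir)
  # corrupt one subject: convert pressure to kPa (values ~ 12)
  bad_id <- small$records[[2]]$id
  path <- file.path(dir, paste0(bad_id, ".csv"))
  wf <- read.csv(path)
  wf$pressure_mmHg <- wf$pressure_mmHg / 7.50062
  write.csv(wf, path, row.names = FALSE)

  back <- read_cohort(dir, file.path(dir, "cohort.csv"))
  expect_length(back, 2L)
  excl <- attr(back, "exclusions")
  expect_equal(excl$id, bad_id)
  expect_match(excl$reason, "units|20, 300")
})

test_that("reader errors name a missing required column", {
  gc <- cached_cohort()
  small <- cohort_table(gc$cohort$records[1:2], provenance = "synthetic")
  dir <- withr::local_tempdir()
  write_cohort(small, dir)
  tab <- read.csv(file.path(dir, "cohort.csv"))
  tab$sv <- NULL
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  expect_error(read_cohort(dir, file.path(dir, "cohort.csv")),
               "configuration error.*sv")
})

test_that("writer refuses duplicate ids before writing anything", {
  beat <- default_beat()
  fake <- structure(list(records = list(beat$record, beat$record),
                         provenance = "synthetic"),
                    class = "cohort_table")
  dir <- file.path(withr::local_tempdir(), "out")
  expect_error(write_cohort(fake, dir), "duplicate")
  expect_false(dir.exists(dir) && length(list.files(dir)) > 0)
})

test_that("every record surviving read_cohort satisfies the invariants", {
  gc <- cached_cohort()
  dir <- withr::local_tempdir()
  write_cohort(gc$cohort, dir)
  back <- read_cohort(dir, file.path(dir, "cohort.csv"))
  for (rec in back$records) expect_silent(validate_subject(rec))
})
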