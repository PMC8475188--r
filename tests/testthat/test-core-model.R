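test_that("montage enforces its invariants", {
  m <- study_montage()
  expect_length(m$channel_names, 18)
  expect_true(all(abs(sqrt(rowSums(m$positions^2)) - 1) < 1e-9))
  expect_error(montage(c("Fz", "Fz")), "duplicate")
  expect_error(montage("XX9"), "unknown channel")
  expect_error(montage(c("Fz", "Pz"), diag(3)[1:2, ] * 2), "unit sphere")
})

test_that("recording validates shapes, rates and annotations", {
  m <- toy_montage(2)
  expect_error(recording(matrix(0, 3, 4), 200, m), "channels")
  expect_error(recording(matrix(0, 2, 4), -1, m), "fs")
  ann <- data.frame(onset_s = 0, duration_s = 1, label = "eyes_closed")
  expect_error(recording(matrix(0, 2, 4), 200, m, ann), "outside")
  r <- recording(matrix(0, 2, 400), 200, m, ann)
  expect_s3_class(r, "ms_recording")
})

test_that("select_condition concatenates matching intervals", {
  m <- toy_montage(2)
  fs <- 200
  n <- 300 * fs
  dat <- matrix(rnorm(2 * n), 2)
  lab <- rep(c("eyes_open", "eyes_closed"), 5)
  ann <- data.frame(onset_s = seq(0, 270, by = 30), duration_s = 30,
                    label = lab)
  r <- recording(dat, fs, m, ann)
  ec <- select_condition(r, "eyes_closed")
  expect_equal(ncol(ec$data), 150 * fs)

  # single whole-recording interval: identity on data
  r1 <- recording(dat, fs, m, data.frame(onset_s = 0, duration_s = 300,
                                         label = "eyes_closed"))
  expect_equal(select_condition(r1, "eyes_closed")$data, dat,
               ignore_attr = TRUE)

  # two intervals vs manual slice-and-concatenate oracle
  r2 <- recording(dat, fs, m,
                  data.frame(onset_s = c(0, 2), duration_s = c(1, 1),
                             label = "eyes_closed"))
  got <- select_condition(r2, "eyes_closed")$data
  expect_equal(ncol(got), 400)
  expect_equal(got, cbind(dat[, 1:200], dat[, 401:600]),
               ignore_attr = TRUE)

  expect_error(select_condition(r, "nap"), "eyes_open")
})

test_that("epoch cuts non-overlapping epochs and drops the remainder", {
  m <- toy_montage(2)
  e <- epoch(recording(matrix(rnorm(2 * 1800), 2), 200, m), 3)
  expect_length(e$epochs, 3)
  expect_equal(ncol(e$epochs[[1]]), 600)
  e2 <- epoch(recording(matrix(rnorm(2 * 700), 2), 200, m), 3)
  expect_length(e2$epochs, 1)
  e3 <- epoch(recording(matrix(0, 2, 165 * 200), 200, m), 3)
  expect_length(e3$epochs, 55)
  expect_error(epoch(recording(matrix(0, 2, 100), 200, m), 3), "shorter")
})

test_that("epochs never span condition-interval boundaries", {
  m <- toy_montage(2)
  fs <- 200
  dat <- matrix(seq_len(2 * 20 * fs), 2)   # 20 s, values encode position
  ann <- data.frame(onset_s = c(0, 10), duration_s = c(7, 8),
                    label = "eyes_closed")
  ec <- select_condition(recording(dat, fs, m, ann), "eyes_closed")
  e <- epoch(ec, 3)
  # 7 s -> 2 epochs, 8 s -> 2 epochs (1 s + 2 s discarded at splices)
  expect_length(e$epochs, 4)
  jumps <- vapply(e$epochs, function(ep) max(abs(diff(ep[1, ]))), 0)
  expect_true(all(jumps == 2))             # consecutive samples only
})

test_that("matrix format round trips and rejects bad input", {
  m <- montage(c("Fz", "Pz"))
  rec <- recording(matrix(c(1.5, -2, 3.25, 4, 1e-7, 2, 3, 4), 2), 200, m,
                   data.frame(onset_s = 0, duration_s = 0.015,
                              label = "eyes_closed"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(rec, f)
  back <- read_matrix(f)
  expect_equal(back$data, rec$data, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$fs, 200)
  expect_equal(back$annotations$label, "eyes_closed")

  writeLines(c("# fs=200", "XX9\tPz", "1\t2"), f)
  expect_error(read_matrix(f), "unknown channel")
  writeLines(c("# fs=200", "Fz\tPz", "1\tabc"), f)
  expect_error(read_matrix(f), "non-numeric")
  writeLines(c("Fz\tPz", "1\t2"), f)
  expect_error(read_matrix(f), "fs")
})

test_that("feature tables round trip and normalize labels", {
  tab <- simulate_cohort(cohort_spec(seed = 7))
  expect_equal(nrow(tab), 16)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  expect_error(feature_table(data.frame(
    subject_id = c("a", "a"), group = "control", age = 1,
    gender = "female")), "duplicate subject_id")

  norm <- feature_table(data.frame(
    subject_id = "a", group = "Patient ", age = 50, gender = "Male"))
  expect_equal(norm$group, "patient")
  expect_equal(norm$gender, "male")

  empty <- feature_table(data.frame(subject_id = character(),
                                    group = character(), age = numeric(),
                                    gender = character()))
  write_feature_table(empty, f)
  expect_length(readLines(f), 1)          # header only
})

test_that("read_edf restores montage order, units and annotations", {
  fs <- 200
  labs <- study_montage()$channel_names
  set.seed(11)
  # quantized to the writer's 0.1 uV resolution for exact round trip
  dat <- matrix(round(rnorm(18 * 3 * fs, sd = 40), 1), 18)
  f <- withr::local_tempfile(fileext = ".edf")
  ann <- data.frame(onset_s = c(0, 1.5), duration_s = c(1.5, 1.5),
                    label = c("eyes_open", "eyes_closed"))
  # write channels in shuffled order with noisy label formatting
  shuf <- sample(18)
  write_edf_fixture(f, dat[shuf, ], fs, tolower(labs[shuf]), ann)
  rec <- read_edf(f)
  expect_equal(rec$fs, fs)
  expect_equal(rec$montage$channel_names, labs)
  expect_equal(rec$data, dat, ignore_attr = TRUE, tolerance = 1e-6)
  expect_setequal(rec$annotations$label, c("eyes_open", "eyes_closed"))

  expect_error(read_edf(withr::local_tempfile()), "not found")
})

test_that("read_edf agrees with the matrix route on identical content", {
  fs <- 200
  labs <- c("Fz", "Pz", "O1")
  set.seed(3)
  dat <- matrix(round(rnorm(3 * fs), 1), 3)
  fe <- withr::local_tempfile(fileext = ".edf")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_edf_fixture(fe, dat, fs, labs)
  write_matrix(recording(dat, fs, montage(labs)), fm)
  # montage ordering differs between the two readers; compare by label
  a <- read_edf(fe); b <- read_matrix(fm)
  expect_equal(a$data[labs, ], b$data[labs, ], tolerance = 1e-6)
})

test_that("read_edf rejects degenerate files", {
  f <- withr::local_tempfile(fileext = ".edf")
  expect_error(write_edf_fixture(f, matrix(numeric(), 1, 0), 200, "Fz"),
               NA)
  expect_error(read_edf(f), "empty recording")
})
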