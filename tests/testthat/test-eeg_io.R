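test_that("BrainVision triplets round-trip through the reader", {
  set.seed(11)
  dir <- withr::local_tempdir()
  data <- matrix(rnorm(31 * 400, sd = 15), 31)
  ev <- data.frame(sample = c(50L, 250L), code = c("S  1", "S  2"))
  vhdr <- write_bv_fixture(dir, data, 500, montage_31(), ev)
  r <- read_raw(vhdr)
  expect_s3_class(r, "eeg_raw")
  expect_equal(r$fs, 500)
  expect_equal(nrow(r$data), 31L)
  expect_equal(r$channel_names, montage_31())
  # INT_16 at 0.1 uV resolution quantizes to 0.05 uV worst case
  expect_lt(max(abs(r$data - data)), 0.05 + 1e-9)
  stim <- r$events[r$events$code %in% c("S  1", "S  2"), ]
  expect_equal(stim$sample, c(50L, 250L))

  # float32 variant is exact at single precision
  vhdr2 <- write_bv_fixture(dir, data, 500, montage_31(), ev,
                            binary_format = "IEEE_FLOAT_32", stem = "rec2")
  r2 <- read_raw(vhdr2)
  expect_lt(max(abs(r2$data - data)), 1e-5)
})

test_that("BrainVision reader flags missing header fields and truncation", {
  dir <- withr::local_tempdir()
  data <- matrix(rnorm(2 * 100), 2)
  vhdr <- write_bv_fixture(dir, data, 250, c("C3", "C4"))
  lines <- readLines(vhdr)
  writeLines(lines[!grepl("^NumberOfChannels", lines)], vhdr)
  expect_error(read_raw(vhdr), "NumberOfChannels")
  expect_error(read_raw(file.path(dir, "nope.vhdr")), "no such file")
})

test_that("GDF fixtures with the public-dataset geometry parse correctly", {
  set.seed(12)
  dir <- withr::local_tempdir()
  # 22 channels at 250 Hz, cue codes in the 769+ range
  data <- matrix(rnorm(22 * 1000, sd = 10), 22)
  ev <- data.frame(sample = c(100L, 500L, 900L),
                   code = c("769", "770", "771"))
  path <- write_gdf_fixture(file.path(dir, "a.gdf"), data, 250,
                            paste0("EEG", 1:22), ev)
  r <- read_raw(path)
  expect_equal(r$fs, 250)
  expect_equal(nrow(r$data), 22L)
  expect_equal(r$events$code, c("769", "770", "771"))
  expect_equal(r$events$sample, c(100L, 500L, 900L))
  expect_lt(max(abs(r$data - data)), 0.06)

  # zero events is not an error
  path2 <- write_gdf_fixture(file.path(dir, "b.gdf"), data, 250,
                             paste0("EEG", 1:22))
  expect_equal(nrow(read_raw(path2)$events), 0L)
})

test_that("EDF reader recovers signals and timestamped annotations", {
  set.seed(13)
  dir <- withr::local_tempdir()
  data <- matrix(rnorm(4 * 750, sd = 20), 4)
  ev <- data.frame(sample = c(10L, 700L), code = c("cueA", "cueB"))
  path <- write_edf_fixture(file.path(dir, "a.edf"), data, 250,
                            c("C3", "C4", "Cz", "Pz"), ev)
  r <- read_raw(path)
  expect_equal(r$fs, 250)
  expect_equal(nrow(r$data), 4L)
  expect_lt(max(abs(r$data - data)), 0.06)
  expect_equal(r$events$code, c("cueA", "cueB"))
  expect_equal(r$events$sample, c(10L, 700L))
})

test_that("epoch extraction matches the cue windows exactly", {
  set.seed(14)
  fs <- 500
  n_samp <- fs * 60
  data <- matrix(rnorm(3 * n_samp), 3)
  cues <- seq(fs, by = 6 * fs, length.out = 9L)
  codes <- rep(c("up", "box", "down"), 3L)
  raw <- eeg_raw(data, fs, c("C1", "Cz", "C2"),
                 data.frame(sample = cues, code = codes))
  ep <- extract_epochs(raw, c(up = 1L, box = 2L, down = 3L), 0, 5)
  expect_equal(dim(ep$data), c(3L, 2500L, 9L))
  expect_equal(ep$labels, rep(1:3, 3L))
  # half-open window: starts at the cue sample, round((t1-t0)*fs) long
  expect_equal(ep$data[, , 1L], data[, cues[1L]:(cues[1L] + 2499L)])
  # offset window
  ep2 <- extract_epochs(raw, c(up = 1L), 0.5, 1.5)
  expect_equal(dim(ep2$data)[2L], 500L)
  expect_equal(ep2$data[, , 1L],
               data[, (cues[1L] + 250L):(cues[1L] + 749L)])
})

test_that("epoch extraction rejects degenerate and out-of-bounds windows", {
  raw <- eeg_raw(matrix(rnorm(2 * 100), 2), 100, c("a", "b"),
                 data.frame(sample = 95L, code = "x"))
  expect_error(extract_epochs(raw, c(x = 1L), 0, 0), "t_end")
  expect_error(extract_epochs(raw, c(x = 1L), 0, 1), "trial 1")
  expect_error(extract_epochs(raw, c(y = 1L), 0, 0.1), "no events match")
})

test_that("bundle save/load is the identity on every field", {
  ep <- tiny_epochs(n_tr = 7L, n_classes = 3L, seed = 21)
  ep$labels <- sample(ep$labels)            # shuffled label order preserved
  path <- withr::local_tempfile(fileext = ".mdb")
  save_bundle(ep, path)
  back <- load_bundle(path)
  expect_identical(back$data, ep$data)      # bit-exact
  expect_identical(back$labels, ep$labels)
  expect_identical(back$fs, ep$fs)
  expect_identical(back$class_names, ep$class_names)
  expect_identical(back$channel_names, ep$channel_names)
})

test_that("bundle loader rejects corrupted and mismatched files", {
  ep <- tiny_epochs()
  path <- withr::local_tempfile(fileext = ".mdb")
  save_bundle(ep, path)
  # truncate the payload
  sz <- file.info(path)$size
  con <- file(path, "r+b")
  truncate_ok <- tryCatch({
    raw_all <- readBin(con, "raw", sz)
    close(con)
    writeBin(raw_all[seq_len(sz - 200)], path)
    TRUE
  }, error = function(e) { close(con); FALSE })
  if (truncate_ok) expect_error(load_bundle(path), ".")
  writeLines("not a bundle at all", path)
  expect_error(load_bundle(path), "bundle")
  expect_error(load_bundle(file.path(tempdir(), "absent.mdb")), "no such")
})
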