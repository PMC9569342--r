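test_that("ms_spectrum validates and orders peaks", {
  s <- ms_spectrum(c(300, 100, 200), c(1, 2, 3), 400, 60, "x")
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(2, 3, 1))
  expect_error(ms_spectrum(1:3, 1:2, 400), "lengths differ")
  expect_error(ms_spectrum(100, -1, 400), ">= 0")
  expect_error(ms_spectrum(100, 1, -5), "> 0")
})

test_that("window_filter keeps locally top-ranked peaks and is idempotent", {
  # 7 equal-spaced peaks within 10 Da, intensities 1..7: default (6, 50)
  # drops exactly the weakest
  s <- ms_spectrum(seq(100, 110, length.out = 7), 1:7, 400)
  f <- window_filter(s)
  expect_equal(length(f$mz), 6L)
  expect_false(1 %in% f$intensity)
  # spectra with <= top_k peaks pass unchanged
  small <- ms_spectrum(c(100, 150), c(5, 1), 400)
  expect_identical(window_filter(small)$mz, small$mz)
  # idempotence
  ff <- window_filter(f)
  expect_identical(ff$mz, f$mz)
  # a peak far away is judged in its own window
  s2 <- ms_spectrum(c(seq(100, 110, length.out = 7), 300), c(1:7, 0.5), 400)
  f2 <- window_filter(s2)
  expect_true(300 %in% f2$mz)
})

test_that("precursor_exclusion removes the +/- 17 Da neighborhood", {
  s <- ms_spectrum(c(380, 390), c(1, 1), 400)
  f <- precursor_exclusion(s)
  expect_equal(f$mz, 380)
  # untouched when nothing is near
  s2 <- ms_spectrum(c(100, 200), c(1, 1), 400)
  expect_identical(precursor_exclusion(s2)$mz, s2$mz)
  # all peaks in range -> valid empty spectrum
  s3 <- ms_spectrum(c(395, 405), c(1, 1), 400)
  expect_equal(length(precursor_exclusion(s3)), 0L)
})

test_that("window_filter and precursor_exclusion commute at defaults", {
  set.seed(31)
  for (k in 1:25) {
    s <- random_spectrum(sample(3:25, 1), runif(1, 250, 600))
    a <- precursor_exclusion(window_filter(s))
    b <- window_filter(precursor_exclusion(s))
    expect_equal(a$mz, b$mz)
    expect_equal(a$intensity, b$intensity)
    # idempotence of the composition
    expect_equal(preprocess_spectrum(a)$mz, a$mz)
  }
})

test_that("MGF round-trips spectra losslessly", {
  set.seed(32)
  specs <- lapply(1:3, function(i)
    random_spectrum(5, 300 + 50 * i, id = paste0("scan_", i)))
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(specs, path)
  back <- read_mgf(path)
  expect_identical(names(back), names(specs))
  for (i in seq_along(specs)) {
    expect_equal(back[[i]]$mz, specs[[i]]$mz, tolerance = 1e-5)
    expect_equal(back[[i]]$intensity, specs[[i]]$intensity,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$precursor_mz, specs[[i]]$precursor_mz,
                 tolerance = 1e-5)
    expect_equal(back[[i]]$rt, specs[[i]]$rt)
  }
  # second cycle is byte-identical
  path2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("MGF parser handles missing PEPMASS and malformed nesting", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=a", "PEPMASS=400.1", "100.0 10", "END IONS", "",
    "BEGIN IONS", "TITLE=b", "100.0 10", "END IONS", "",
    "BEGIN IONS", "TITLE=c", "PEPMASS=500.2", "200.0 5", "END IONS"), path)
  expect_warning(got <- read_mgf(path), "lacks PEPMASS")
  expect_identical(names(got), c("a", "c"))

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "BEGIN IONS"), bad)
  expect_error(read_mgf(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), empty)
  expect_identical(read_mgf(empty), list())
})

test_that("feature CSV round-trips with envelopes", {
  set.seed(33)
  sim <- generate_dataset(generator_config(seed = 5, n_series = 2,
                                           n_full = 1, n_decoys = 3))
  ft <- sim$features
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- read_feature_csv(path)
  expect_identical(back$features$id, ft$features$id)
  expect_equal(back$features$mz, ft$features$mz, tolerance = 1e-5)
  expect_equal(back$features$rt, ft$features$rt, tolerance = 1e-3)
  expect_identical(back$features$condition, ft$features$condition)
  env0 <- ft$features$envelope[[1]]
  env1 <- back$features$envelope[[1]]
  expect_equal(nrow(env1), nrow(env0))
  expect_equal(env1[, 1], env0[, 1], tolerance = 1e-5,
               ignore_attr = TRUE)
  # second cycle byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("feature CSV schema errors are explicit", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,rt_s", "a,100,5"), path)
  expect_error(read_feature_csv(path), "intensity")

  env <- "391.13090:100.0000;393.12800:32.0000"
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,rt_s,intensity,condition,envelope,msms_ref",
               sprintf("f1,391.13090,60,1000,PDA,%s,", env)), p2)
  ft <- read_feature_csv(p2)
  expect_equal(nrow(ft$features$envelope[[1]]), 2L)
  expect_equal(diff(ft$features$envelope[[1]][, 1]), 1.9971,
               tolerance = 1e-4)

  # duplicate ids rejected
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,rt_s,intensity,condition,envelope,msms_ref",
               "f1,100,5,1,PDA,,", "f1,200,6,1,PDA,,"), p3)
  expect_error(read_feature_csv(p3), "unique")
})
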