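test_that("label encoding is multi-hot over the vocabulary", {
  expect_equal(unname(encodeLabels("AF")), c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  two <- encodeLabels(c("AF", "RBBB"))
  expect_equal(sum(two), 2L)
  expect_equal(names(which(two == 1L)), c("AF", "RBBB"))
  expect_equal(sum(encodeLabels(character())), 0L)
  expect_error(encodeLabels("XX"), "XX")
  expect_true(all(overlapSubset() %in% classVocabulary()))
})

test_that("delimited records auto-detect orientation and lead names", {
  dir <- withr::local_tempdir()
  sig <- matrix(rnorm(12 * 300), 12, 300)
  rec <- ecgRecord(sig, 500)
  p1 <- file.path(dir, "a.csv")
  writeRecord(rec, p1, format = "delimited")      # samples x leads + header
  back <- readRecord(p1)
  expect_equal(ecgSignal(back), sig, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(leadNames(back), standardLeads())
  # bare numeric matrix, leads x samples (wide): longer axis is time
  p2 <- file.path(dir, "b.csv")
  data.table::fwrite(data.table::as.data.table(sig), p2, col.names = FALSE)
  back2 <- readRecord(p2)
  expect_equal(dim(ecgSignal(back2)), c(12L, 300L))
  # transposed bare matrix comes back in the same orientation
  p3 <- file.path(dir, "c.csv")
  data.table::fwrite(data.table::as.data.table(t(sig)), p3, col.names = FALSE)
  back3 <- readRecord(p3)
  expect_equal(dim(ecgSignal(back3)), c(12L, 300L))
  expect_equal(ecgSignal(back3), ecgSignal(back2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("WFDB-style header + format-16 signal pairs round-trip", {
  dir <- withr::local_tempdir()
  sig <- matrix(round(rnorm(12 * 256), 3), 12, 256)
  rec <- ecgRecord(sig, 500, labels = "AF", recordId = "w1")
  stem <- file.path(dir, "w1")
  writeRecord(rec, stem, format = "wfdb")
  expect_true(file.exists(paste0(stem, ".hea")))
  expect_true(file.exists(paste0(stem, ".dat")))
  back <- readRecord(paste0(stem, ".hea"))
  expect_equal(samplingRate(back), 500)
  expect_equal(leadNames(back), standardLeads())
  expect_equal(ecgSignal(back), sig, tolerance = 1e-3, ignore_attr = TRUE)
  # leads listed out of order are restored to standard order
  hea <- readLines(paste0(stem, ".hea"))
  hea[2:13] <- hea[c(3, 2, 4:13)]
  writeLines(hea, paste0(stem, ".hea"))
  back2 <- readRecord(paste0(stem, ".hea"))
  expect_equal(leadNames(back2), standardLeads())
  expect_equal(ecgSignal(back2)[2, ], sig[1, ], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("container round-trip preserves signal and metadata exactly", {
  dir <- withr::local_tempdir()
  rec <- synthRecord(c("AF", "RBBB"), syntheticCohortConfig(length = 600L), 3)
  rec@age <- 61; rec@sex <- "F"
  p <- file.path(dir, "r.rds")
  writeRecord(rec, p, format = "container")
  back <- readRecord(p, format = "container")
  expect_lt(max(abs(ecgSignal(back) - ecgSignal(rec))), 1e-10)
  expect_identical(recordLabels(back), recordLabels(rec))
  expect_identical(recordId(back), recordId(rec))
  expect_identical(back@age, rec@age)
  expect_identical(back@sex, rec@sex)
})

test_that("empty signals are flagged for exclusion", {
  rec <- ecgRecord(matrix(0, 12, 100), 500)
  expect_true(rec@excluded)
  rec2 <- ecgRecord(matrix(rnorm(1200), 12, 100), 500)
  expect_false(rec2@excluded)
})

test_that("Fourier resampling preserves duration and sinusoids", {
  rec <- ecgRecord(matrix(rnorm(2 * 4000), 2, 4000), 400,
                   leadNames = c("I", "II"))
  up <- resampleTo(rec, 500)
  expect_equal(ncol(ecgSignal(up)), 5000L)
  expect_equal(samplingRate(up), 500)
  # identity at the same rate is bit-exact
  expect_identical(ecgSignal(resampleTo(rec, 400)), ecgSignal(rec))
  # 5 Hz unit sine resampled 400 -> 500 Hz matches the analytic sine
  t400 <- (0:3999) / 400
  sine <- ecgRecord(matrix(sin(2 * pi * 5 * t400), 1, 4000), 400,
                    leadNames = "II")
  res <- resampleTo(sine, 500)
  t500 <- (0:4999) / 500
  mid <- 200:4800
  expect_lt(max(abs(ecgSignal(res)[1, mid] - sin(2 * pi * 5 * t500[mid]))),
            1e-2)
  expect_error(resampleTo(rec, -1), "targetRate")
})

test_that("resampling at a fixed rate is idempotent", {
  rec <- ecgRecord(matrix(rnorm(1000), 1, 1000), 400, leadNames = "II")
  a <- resampleTo(rec, 500)
  b <- resampleTo(a, 500)
  expect_lt(max(abs(ecgSignal(a) - ecgSignal(b))), 1e-8)
})

test_that("length standardization truncates, pads and is idempotent", {
  long <- ecgRecord(matrix(seq_len(2 * 5000), 2, 5000), 500,
                    leadNames = c("I", "II"))
  tr <- standardizeLength(long, 4096)
  expect_equal(ncol(ecgSignal(tr)), 4096L)
  expect_equal(ecgSignal(tr), ecgSignal(long)[, 1:4096])  # first samples kept
  expect_false(tr@padded)
  short <- ecgRecord(matrix(rnorm(2 * 4000), 2, 4000), 500,
                     leadNames = c("I", "II"))
  pd <- standardizeLength(short, 4096)
  expect_equal(ncol(ecgSignal(pd)), 4096L)
  expect_true(pd@padded)
  expect_true(all(ecgSignal(pd)[, 4001:4096] == 0))
  # discard mode flags instead of padding
  ex <- standardizeLength(short, 4096, pad = FALSE)
  expect_true(ex@excluded)
  # idempotence
  again <- standardizeLength(tr, 4096)
  expect_identical(ecgSignal(again), ecgSignal(tr))
  exact <- standardizeLength(ecgRecord(matrix(1, 1, 4096), 500,
                                       leadNames = "II"), 4096)
  expect_equal(ncol(ecgSignal(exact)), 4096L)
})

test_that("lead selection returns requested leads in order", {
  rec <- synthRecord(character(), syntheticCohortConfig(length = 600L), 5)
  ii <- selectLeads(rec, "II")
  expect_equal(dim(ecgSignal(ii)), c(1L, 600L))
  expect_equal(ecgSignal(ii)[1, ], ecgSignal(rec)[2, ])
  all12 <- selectLeads(rec, standardLeads())
  expect_identical(ecgSignal(all12), ecgSignal(rec))
  rev2 <- selectLeads(rec, c("V1", "I"))
  expect_equal(leadNames(rev2), c("V1", "I"))
  expect_error(selectLeads(rec, "V9"), "V9")
})

test_that("manifest and cohort containers round-trip", {
  dir <- withr::local_tempdir()
  ds <- shortCohort(8, seed = 4)
  p <- file.path(dir, "manifest.csv")
  writeManifest(ds$records, p)
  back <- readManifest(p)
  expect_equal(back$record_id, ds$manifest$record_id)
  expect_equal(back$labels, ds$manifest$labels)
  cp <- file.path(dir, "cohort.rds")
  writeCohort(ds$records, cp)
  recs <- readCohort(cp)
  expect_length(recs, 8L)
  expect_lt(max(abs(ecgSignal(recs[[3]]) - ecgSignal(ds$records[[3]]))), 1e-12)
  expect_identical(recordLabels(recs[[3]]), recordLabels(ds$records[[3]]))
})
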