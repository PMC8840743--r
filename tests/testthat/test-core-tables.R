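test_that("exactly six ordered measurement conditions exist", {
  keys <- condition_keys()
  expect_equal(nrow(keys), 6L)
  expect_equal(anyDuplicated(paste(keys$mode, keys$ph)), 0L)
  ord <- condition_order(keys$mode, keys$ph)
  expect_equal(ord, sort(ord))
  # positive sorts before negative at every pH, pH ascending within mode
  expect_true(all(condition_order("positive", mobile_phase_ph()) <
                    condition_order("negative", 2.7)))
  expect_error(condition_label("positive", 7.0), "pH")
  expect_error(condition_label("both", 2.7), "mode")
})

test_that("feature-table round trip through CSV preserves records", {
  recs <- bind_recs(
    peak_rec("b", "negative", 10.0, 2, area = 3.25e6, rt = 7.123456789,
             mz = 314.15926535),
    peak_rec("a", "positive", 2.7, 1, area = 1.5e9, rt = 5.5,
             na_adduct = TRUE),
    peak_rec("a", "positive", 8.0, 4)  # not detected
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(recs, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 3L)
  # deterministic order: by compound, condition, dilution
  expect_equal(back$compound_id, c("a", "a", "b"))
  expected <- esiquant:::sort_feature_table(
    esiquant:::validate_feature_table(recs))
  expect_equal(back, expected, tolerance = 1e-12)
  # rewrite is byte-identical (determinism)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty area and rt cells parse as not-detected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,mode,ph,dilution_factor,area,rt,mz,na_adduct",
               "c1,positive,2.7,1,1e9,5.1,195.0877,FALSE",
               "c1,positive,2.7,2,,,195.0877,FALSE"), path)
  recs <- read_feature_table(path)
  expect_false(is.na(recs$area[1]))
  expect_true(is.na(recs$area[2]) && is.na(recs$rt[2]))
})

test_that("malformed feature tables are rejected with named problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,mode,ph,dilution_factor,area,rt,na_adduct",
               "c1,positive,2.7,1,1e9,5.1,FALSE"), path)
  expect_error(read_feature_table(path), "mz")
  writeLines(c("compound_id,mode,ph,dilution_factor,area,rt,mz,na_adduct",
               "c1,positive,5.5,1,1e9,5.1,195.1,FALSE"), path)
  expect_error(read_feature_table(path), "pH")
  writeLines(c("compound_id,mode,ph,dilution_factor,area,rt,mz,na_adduct",
               "c1,positive,2.7,1,1e9,,195.1,FALSE"), path)
  expect_error(read_feature_table(path), "absent together")
  expect_error(read_feature_table(tempfile()), "not found")
})

test_that("empty collections write header-only files", {
  recs <- peak_rec("x", "positive", 2.7, area = 1, rt = 1)[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(recs, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_feature_table(path)), 0L)
})

test_that("split peaks merge by summing areas and averaging RTs", {
  recs <- bind_recs(
    peak_rec("c1", "positive", 2.7, 1, area = 1e6, rt = 5.0),
    peak_rec("c1", "positive", 2.7, 1, area = 2e6, rt = 5.2))
  merged <- merge_split_peaks(recs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$area, 3e6)
  expect_equal(merged$rt, 5.1)

  # three-way split handled by the same rule
  recs3 <- bind_recs(
    peak_rec("c1", "negative", 8.0, 2, area = 1e5, rt = 4.0),
    peak_rec("c1", "negative", 8.0, 2, area = 2e5, rt = 4.1),
    peak_rec("c1", "negative", 8.0, 2, area = 3e5, rt = 4.2))
  merged3 <- merge_split_peaks(recs3)
  expect_equal(merged3$area, 6e5)
  expect_equal(merged3$rt, 4.1)

  # single record passes through unchanged
  single <- peak_rec("c2", "positive", 8.0, 1, area = 5e5, rt = 3.3)
  expect_equal(merge_split_peaks(single)$area, 5e5)
})

test_that("merging is idempotent, conserves area, keeps not-detected rows", {
  set.seed(101)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    peak_rec(sample(c("a", "b", "c"), 1), sample(esi_modes(), 1),
             sample(mobile_phase_ph(), 1), sample(c(1, 2, 4), 1),
             area = runif(1, 1e5, 1e7), rt = runif(1, 1, 19))
  }))
  recs <- rbind(recs, peak_rec("a", "positive", 2.7, 20))  # not detected
  once <- merge_split_peaks(recs)
  expect_equal(merge_split_peaks(once), once)
  expect_equal(sum(once$area, na.rm = TRUE), sum(recs$area, na.rm = TRUE))
  expect_equal(sum(is.na(once$area)), 1L)
  key <- with(once[!is.na(once$area), ],
              paste(compound_id, mode, ph, dilution_factor))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("mean retention time averages detected dilutions only", {
  recs <- bind_recs(
    peak_rec("c", "positive", 2.7, 1, area = 1, rt = 5.0),
    peak_rec("c", "positive", 2.7, 2, area = 1, rt = 5.2),
    peak_rec("c", "positive", 2.7, 4),
    peak_rec("c", "positive", 2.7, 20, area = 1, rt = 5.1),
    peak_rec("c", "positive", 2.7, 40))
  expect_equal(mean_retention_time(recs), 5.1)
  expect_equal(mean_retention_time(peak_rec("c", "positive", 2.7, 1,
                                            area = 1, rt = 7.7)), 7.7)
  expect_error(mean_retention_time(peak_rec("c", "positive", 2.7, 1)),
               "no detected record")
  # mean lies within [min, max] of its inputs
  rts <- runif(7, 1, 19)
  recs2 <- do.call(rbind, lapply(seq_along(rts), function(i) {
    peak_rec("c", "positive", 8.0, i, area = 1, rt = rts[i])
  }))
  m <- mean_retention_time(recs2)
  expect_gte(m, min(rts)); expect_lte(m, max(rts))
})

test_that("standards and RF tables round-trip through CSV", {
  std <- data.frame(compound_id = c("a", "b"), dilution_factor = c(1, 2),
                    concentration_M = c(2e-6, 1e-6), stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_standards_table(std, p1)
  expect_equal(read_standards_table(p1), std, tolerance = 1e-12)

  rf <- rbind(rf_row("a", 1e15, 5.1), rf_row("b", 2.5e16, 9.9, "negative", 8))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_rf_table(rf, p2)
  expect_equal(read_rf_table(p2), rf, tolerance = 1e-12)
})
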