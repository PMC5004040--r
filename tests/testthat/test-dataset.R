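test_that("the bundled fixture reproduces every printed record", {
  recs <- phellinus45()
  # the source text claims 45 experiments but its tables print 44 rows
  expect_equal(nrow(recs), 44)
  expect_s3_class(recs, "experiment_records")
  # first record: pH-sweep start
  expect_equal(unlist(recs[1, ]),
               c(inoculum = 0.05, ph = 1, volume = 100, temperature = 28,
                 seed_age = 8, ferm_time = 8, rotation = 140,
                 yield = 45.929))
  # inoculum-sweep row at 10 %
  hit <- recs[recs$inoculum == 0.10 & recs$ph == 6 & recs$volume == 100 &
                recs$rotation == 140 & recs$yield > 1800, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$yield, 1841.729)
})

test_that("reading rejects malformed files with the offending location", {
  bad <- tempfile(fileext = ".csv")
  recs <- phellinus45()
  write_experiments(recs, bad)
  txt <- readLines(bad)
  writeLines(sub("^5,1", "5,oops", txt), bad)
  expect_error(read_experiments(bad), "non-numeric")

  writeLines(txt[-1][-1], bad)  # drop header
  expect_error(read_experiments(bad), "missing column")

  writeLines(sub("^5,1,100", "5,-1,100", txt), bad)
  expect_error(read_experiments(bad), "non-positive")
})

test_that("records round-trip through CSV without change", {
  recs <- phellinus45()
  path <- tempfile(fileext = ".csv")
  write_experiments(recs, path)
  back <- read_experiments(path)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 0)
})

test_that("range filtering keeps exactly the in-box records, in order", {
  recs <- phellinus45()
  kept <- filter_records(recs, factor_bounds())
  expect_equal(nrow(kept), 16)
  # pH 1 row excluded, pH 6 base row retained
  expect_false(any(kept$ph == 1))
  expect_true(any(kept$ph == 6 & kept$volume == 100 &
                    kept$temperature == 28 & kept$inoculum == 0.05))
  # boundary settings (100 mL, 140 r/min) are retained: closed intervals
  expect_true(any(kept$volume == 100 & kept$rotation == 140))
  # subset of input, idempotent
  expect_true(nrow(kept) <= nrow(recs))
  expect_equal(filter_records(kept, factor_bounds()), kept)
  # order preserved
  expect_true(!is.unsorted(match(
    interaction(kept$ph, kept$yield),
    interaction(recs$ph, recs$yield))))
})

test_that("literal inoculum preset excludes everything below 2 %", {
  kept <- filter_records(phellinus45(), factor_bounds("literal"))
  expect_equal(nrow(kept), 0)
})

test_that("deduplication drops exact repeats only, keeps replicates", {
  recs <- phellinus45()
  expect_equal(dedup_records(recs), recs)  # no verbatim repeats
  doubled <- rbind(recs, recs[3, ])
  class(doubled) <- class(recs)
  expect_equal(nrow(dedup_records(doubled)), nrow(recs))
  # same condition, different yield: both kept (biological replicates)
  same_cond <- recs[recs$inoculum == 0.10 & recs$ph == 6 &
                      recs$volume == 100 & recs$temperature == 28 &
                      recs$rotation == 140, ]
  expect_equal(nrow(same_cond), 2)
  expect_equal(nrow(dedup_records(same_cond)), 2)
  # idempotent, never grows
  dd <- dedup_records(doubled)
  expect_equal(dedup_records(dd), dd)
  expect_true(nrow(dd) <= nrow(doubled))
})

test_that("condition validation enforces the domain invariants", {
  expect_error(culture_condition(1.2, 6, 100, 28, 8, 8, 140), "fraction")
  expect_error(culture_condition(0.1, 15, 100, 28, 8, 8, 140), "pH")
  expect_error(culture_condition(0.1, 6, -5, 28, 8, 8, 140), "non-positive")
  expect_silent(culture_condition(0.12, 5.8, 100, 28, 9, 9, 150))
})
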