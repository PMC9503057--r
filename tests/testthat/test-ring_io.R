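test_that("RWL dialect is detected from the terminating sentinel", {
  # -9999 sentinel: values in 0.001 mm
  f1 <- tempfile(fileext = ".rwl")
  writeLines(c("TREE01    1978  1234  2345   890  1500",
               "TREE01    1982   777 -9999"), f1)
  d1 <- read_rwl(f1)
  expect_equal(unname(d1$wide[, "TREE01"]),
               c(1.234, 2.345, 0.890, 1.500, 0.777))
  expect_equal(as.integer(rownames(d1$wide)), 1978:1982)

  # 999 sentinel: values in 0.01 mm
  f2 <- tempfile(fileext = ".rwl")
  writeLines(c("TREE02    1990   123   234    89   999"), f2)
  d2 <- read_rwl(f2)
  expect_equal(unname(d2$wide[, "TREE02"]), c(1.23, 2.34, 0.89))
})

test_that("malformed RWL input fails with a line number", {
  f <- tempfile(fileext = ".rwl")
  writeLines(c("TREE01    1978  1234  2345 -9999",
               "TREE01    1990   100 -9999"), f)
  expect_error(read_rwl(f), "duplicate series")

  f2 <- tempfile(fileext = ".rwl")
  writeLines(c("TREE01    1978  1234   abc -9999"), f2)
  expect_error(read_rwl(f2), "line 1")

  f3 <- tempfile(fileext = ".rwl")
  writeLines(c("TREE01    19x8  1234 -9999"), f3)
  expect_error(read_rwl(f3), "line 1")

  # decade line that does not continue the series
  f4 <- tempfile(fileext = ".rwl")
  writeLines(c("TREE01    1978  1234  2345",
               "TREE01    1985   100 -9999"), f4)
  expect_error(read_rwl(f4), "line 2")
})

test_that("RWL write/read round-trips randomized datasets exactly", {
  for (seed in 1:3) {
    d <- random_trw(n_series = 5, seed = seed)
    path <- tempfile(fileext = ".rwl")
    write_rwl(d, path)
    d2 <- read_rwl(path)
    expect_equal(d2$wide[, sort(colnames(d2$wide))],
                 d$wide[, sort(colnames(d$wide))], tolerance = 1e-9)
  }
})

test_that("write_rwl rejects what the format cannot hold", {
  d <- random_trw(2)
  bi <- ring_data(data.frame(series_id = "B1", year = 2000:2010,
                             value = seq(2.1, 2.3, length.out = 11)),
                  proxy = "BI")
  expect_error(write_rwl(bi, tempfile()), "write_series_csv")

  long_id <- ring_data(data.frame(series_id = "VERYLONGID1",
                                  year = 2000:2005, value = rep(1, 6)),
                       proxy = "TRW")
  expect_error(write_rwl(long_id, tempfile()), "8 characters")

  empty <- d
  empty$wide <- d$wide[, 0, drop = FALSE]
  expect_error(write_rwl(empty, tempfile()), "empty")
})

test_that("series CSV round-trips BI data at full precision", {
  bi <- ring_data(data.frame(series_id = "B1", year = 2000:2010,
                             value = round(runif(11, 1.9, 2.4), 4)),
                  proxy = "BI")
  path <- tempfile(fileext = ".csv")
  write_series_csv(bi, path)
  bi2 <- read_series_csv(path, proxy = "BI")
  expect_equal(bi2$wide, bi$wide)
})

test_that("daily climate reader counts a 42-year record and flags gaps", {
  dates <- seq(as.Date("1978-01-01"), as.Date("2019-12-31"), by = "day")
  # calendar oracle: 42 * 365 plus the leap days of 1980..2016
  expect_equal(length(dates), 42 * 365 + 10)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(date = format(dates), tmean = 5), path,
            row.names = FALSE)
  cl <- read_daily_climate(path)
  expect_equal(nrow(cl$data), 15340)
  expect_length(cl$gaps, 0)

  # one missing day -> one gap
  drop <- format(dates) != "1990-06-15"
  write.csv(data.frame(date = format(dates[drop]), tmean = 5), path,
            row.names = FALSE)
  cl2 <- read_daily_climate(path)
  expect_length(cl2$gaps, 1)
  expect_equal(format(cl2$gaps), "1990-06-15")
})

test_that("daily climate reader rejects bad rows by position", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(date = c("2000-01-01", "2000-01-02"),
                       tmean = c("4.5", "cold")), path, row.names = FALSE)
  expect_error(read_daily_climate(path), "row 2")

  write.csv(data.frame(date = c("2000-01-02", "2000-01-01"),
                       tmean = c(1, 2)), path, row.names = FALSE)
  expect_error(read_daily_climate(path), "increasing")

  write.csv(data.frame(date = c("2000-01-01", "not-a-date"),
                       tmean = c(1, 2)), path, row.names = FALSE)
  expect_error(read_daily_climate(path), "row 2")
})

test_that("ring series must be gapless and calendar-consistent", {
  expect_error(ring_data(data.frame(series_id = "A",
                                    year = c(2000, 2001, 2003),
                                    value = c(1, 1, 1)), "TRW"),
               "consecutive")
  d <- random_trw(3, seed = 9)
  for (s in ringclim:::series_list(d))
    expect_length(s$values, diff(range(
      seq.int(s$first_year, length.out = length(s$values)))) + 1L)
})
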