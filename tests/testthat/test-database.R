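test_that("a minimal file parses to records with other fields missing", {
  path <- write_tmp_csv(c("dmi,ch4_g", "18.2,350", "21.0,390", "24.5,440"))
  db <- read_ch4_db(path)
  expect_equal(nrow(db), 3)
  expect_equal(db$dmi, c(18.2, 21.0, 24.5))
  expect_equal(db$ch4_g, c(350, 390, 440))
  expect_true(all(is.na(db$gei)))
  expect_true(all(is.na(db$study_id)))
})

test_that("headers match case-insensitively and through the alias map", {
  path <- write_tmp_csv(c("Study,Dry_Matter_Intake,Methane,FP",
                          "a,20,380,60"))
  db <- read_ch4_db(path)
  expect_equal(db$study_id, "a")
  expect_equal(db$dmi, 20)
  expect_equal(db$ch4_g, 380)
  expect_equal(db$forage, 60)
})

test_that("tab-delimited input is accepted", {
  path <- write_tmp_csv(c("dmi\tch4_g", "20\t380"))
  db <- read_ch4_db(path, delim = "\t")
  expect_equal(db$dmi, 20)
})

test_that("CH4 reported in L/d is converted to g/d on load", {
  path <- write_tmp_csv(c("dmi,ch4_l", "20,22.4"))
  db <- read_ch4_db(path)
  expect_equal(db$ch4_g, 16.0)
})

test_that("unparseable numerics become missing with a warning, rows kept", {
  path <- write_tmp_csv(c("dmi,ch4_g", "20,380", "n.d.,395", "24,abc"))
  w <- capture_warnings(db <- read_ch4_db(path))
  expect_length(w, 2)  # one per affected column
  expect_match(w, "unparseable", all = TRUE)
  expect_equal(nrow(db), 3)
  expect_true(is.na(db$dmi[2]))
  expect_true(is.na(db$ch4_g[3]))
})

test_that("empty data section yields an empty database without error", {
  path <- write_tmp_csv("dmi,ch4_g")
  db <- read_ch4_db(path)
  expect_equal(nrow(db), 0)
})

test_that("unusable files raise format/schema errors", {
  expect_error(read_ch4_db(file.path(tempdir(), "nope.csv")), "not found")
  path <- write_tmp_csv(c("foo,bar", "1,2"))
  expect_error(read_ch4_db(path), "schema error")
})

test_that("write then read round-trips all values", {
  db <- tiny_db()
  db$mei[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_ch4_db(db, path)
  back <- read_ch4_db(path)
  for (v in c("dmi", "ndf", "ch4_g", "ch4_mj", "mei")) {
    expect_equal(back[[v]], db[[v]], tolerance = 1e-12)
  }
  expect_equal(back$study_id, db$study_id)
})

test_that("record invariants are enforced", {
  db <- tiny_db()
  db$dmi[1] <- -2
  expect_error(validate_ch4_db(db), "out-of-range")
  db <- tiny_db()
  db$forage[1] <- 130
  expect_error(validate_ch4_db(db), "forage")
  db <- tiny_db()
  db$ch4_mj[1] <- db$ch4_g[1] * 0.05565 + 1
  expect_error(validate_ch4_db(db), "inconsistent CH4 units")
})

test_that("IQR mask flags only genuine extremes", {
  expect_false(any(iqr_outlier_mask(1:10)))
  mask <- iqr_outlier_mask(c(1:9, 100))
  expect_equal(which(mask), 10L)
  expect_error(iqr_outlier_mask(c(1, 2, 3)), "insufficient data")
})

test_that("IQR mask ignores missing values and is affine-invariant", {
  x <- c(2, NA, 3, 4, 5, 50)
  mask <- iqr_outlier_mask(x)
  expect_false(mask[2])
  expect_equal(which(mask), 6L)
  set.seed(42)
  for (i in 1:25) {
    y <- rnorm(30, 10, 3)
    y[sample(30, 2)] <- c(60, -40)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -50, 50)
    expect_identical(iqr_outlier_mask(a * y + b), iqr_outlier_mask(y))
  }
})

test_that("filter_ch4_outliers screens observed CH4 with MJ/d fallback", {
  db <- tiny_db()
  db$ch4_g[4] <- NA  # only MJ/d reported for this record
  db$ch4_g[2] <- 5000
  db$ch4_mj[2] <- 5000 * 0.05565
  scr <- filter_ch4_outliers(db)
  expect_equal(which(scr$mask), 2L)
  expect_equal(nrow(scr$db), nrow(db) - 1)
})

test_that("database summaries follow the documented conventions", {
  db <- tibble::tibble(dmi = c(18, 20, 22, 26), ch4_g = c(380, 380, 380, 380),
                       mei = rep(NA_real_, 4))
  s <- summarize_ch4_db(db)
  dmi <- s[s$name == "dmi", ]
  expect_equal(dmi$n, 4L)
  expect_equal(dmi$sd, sd(c(18, 20, 22, 26)))  # sample (n-1) convention
  expect_equal(dmi$cv, dmi$sd / dmi$mean * 100)
  expect_equal(dmi$median, 21)  # midpoint rule for even n
  ch4 <- s[s$name == "ch4_g", ]
  expect_equal(ch4$sd, 0)
  expect_equal(ch4$cv, 0)
  expect_equal(ch4$min, ch4$max)
  mei <- s[s$name == "mei", ]
  expect_equal(mei$n, 0L)
  expect_true(is.na(mei$mean))
})

test_that("summary CV matches the emulated database's printed style", {
  # mean 21.17 and sd 3.81 give CV 18.00 at this rounding
  db <- tibble::tibble(dmi = c(21.17 - 3.81, 21.17, 21.17 + 3.81))
  s <- summarize_ch4_db(db)
  expect_equal(round(s$sd[1] / s$mean[1] * 100, 2), 18.00)
})
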