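# A single complete record at the marginal-target means of the emulated
# database; eligible for every registry model.
mean_record <- function() {
  tibble::tibble(
    study_id = "S001", treatment_id = "T1",
    bw = 610.90, ndf = 346.18, ee = 33.24, dmi = 21.17, omi = 20.37,
    gei = 361.34, mei = 246.38, ndfi = 7.10, adfi = 4.09, omd = 71.39,
    ndfd = 51.47, forage = 58.71, ch4_g = 381.34,
    ch4_mj = 381.34 * 0.05565, method = "chamber"
  )
}

# small complete database with a linear DMI-CH4 relation plus fixed jitter
tiny_db <- function(n = 12) {
  dmi <- seq(12, 28, length.out = n)
  jit <- rep_len(c(-20, 10, -5, 15, 0, -10), n)
  db <- mean_record()[rep(1, n), ]
  db$study_id <- sprintf("S%03d", seq_len(n))
  db$treatment_id <- "T1"
  db$dmi <- dmi
  db$ch4_g <- 38 + 19.22 * dmi + jit
  db$ch4_mj <- db$ch4_g * 0.05565
  db
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# published 15-row evaluation summary, used by several suites
pub <- methaneval::published_evaluation()
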