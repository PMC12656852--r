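test_that("the registry holds the 40 published equations in stable order", {
  tab <- ch4_models()
  expect_equal(nrow(tab), 40)
  expect_equal(tab$id, 1:40)
  expect_false(anyDuplicated(tab$id) > 0)
  expect_true(all(nchar(tab$predictors) > 0))
  # every stored coefficient is finite
  for (m in tab$model) expect_true(all(is.finite(m$coefficients)))
})

test_that("registry filters reproduce the DMI-only and MJ/d model sets", {
  dmi_only <- ch4_models(predictors_within = "dmi")$id
  expect_equal(dmi_only, c(1, 2, 4, 6, 10, 16, 18, 19, 20, 21, 22, 23,
                           27, 29, 30, 31, 32, 35))
  mj <- ch4_models(output_unit = "MJ_d")$id
  expect_equal(mj, c(1, 2, 4, 5, 15, 16, 22, 31, 39, 40))
  quads <- ch4_models(filter = function(m) m$form == "quadratic")$id
  expect_equal(quads, c(2, 21, 22))
})

test_that("predictions match hand-computed values", {
  rec <- tibble::tibble(dmi = 20, gei = 100, ee = 50)
  # quadratic DMI model: (20 + 716 - 200) * 16/22.4
  expect_equal(predict(ch4_model(21), rec), 536 * 16 / 22.4, tolerance = 1e-12)
  # fixed methane conversion factor Ym = 0.065 on gross energy
  expect_equal(predict(ch4_model(7), rec), 0.065 * 100 / 0.05565,
               tolerance = 1e-12)
  # whole-equation g-to-MJ conversion, not slope-only
  expect_equal(predict(ch4_model(1), rec), (75.42 + 94.28 * 20) * 0.05524,
               tolerance = 1e-12)
  # Mitscherlich form divided whole by the MJ/g constant
  expect_equal(predict(ch4_model(6), rec),
               56.27 * (1 - exp(-0.028 * 20)) / 0.05565, tolerance = 1e-12)
  # EE enters as % of DM via the printed /10
  expect_equal(predict(ch4_model(33), rec), 160 + 14.2 * 20 - 13.5 * 50 / 10,
               tolerance = 1e-12)
})

test_that("OMD-driven models use the g/kg input scale", {
  means <- mean_record()
  p38 <- predict(ch4_model(38), means)
  # published predicted mean for this model is 430.31 g/d at these inputs
  expect_lt(abs(p38 - 430.31) / 430.31, 0.05)
  # with OMD left in percent the prediction would collapse to ~148 g/d
  expect_gt(p38, 400)
  p37 <- predict(ch4_model(37), means)
  expect_gt(p37, 400)
  expect_lt(p37, 550)
})

test_that("missing predictors raise an eligibility error naming the field", {
  rec <- tibble::tibble(dmi = 20)
  expect_error(predict(ch4_model(5), rec), "mei")
  rec2 <- tibble::tibble(dmi = c(20, NA))
  expect_error(predict(ch4_model(21), rec2), "missing values")
})

test_that("eligibility needs predictors plus observed CH4 in a usable unit", {
  db <- tiny_db()
  expect_true(all(vapply(1:40, function(id) all(eligible_records(id, db)), TRUE)))
  expect_identical(eligible_records(21, db[0, ]), logical(0))

  db$mei[1:5] <- NA
  db$forage[4:8] <- NA
  expect_equal(sum(eligible_records(12, db)), nrow(db) - 8)

  # MJ/d observation alone suffices for a g/d model (units interconvert)
  db2 <- tiny_db()
  db2$ch4_g <- NA_real_
  expect_true(all(eligible_records(21, db2)))
  db2$ch4_mj <- NA_real_
  expect_false(any(eligible_records(21, db2)))
})

test_that("models increase with intake except where the printed form bends", {
  rec <- mean_record()
  grad <- function(m, v, at = rec) {
    h <- 1e-4
    up <- at; up[[v]] <- up[[v]] + h
    dn <- at; dn[[v]] <- dn[[v]] - h
    (predict(m, up) - predict(m, dn)) / (2 * h)
  }
  neg_adfi <- c(9, 15, 39)   # printed negative ADFI coefficients
  in_range_vertex <- 2       # quadratic peaking at DMI ~ 12.6 kg/d
  for (m in ch4_models()$model) {
    for (v in intersect(m$predictors, c("dmi", "gei", "mei", "ndfi", "adfi", "omi"))) {
      if (v == "adfi" && m$id %in% neg_adfi) {
        expect_lt(grad(m, v), 0)
      } else if (v == "dmi" && m$id == in_range_vertex) {
        next
      } else {
        expect_gt(grad(m, v), 0)
      }
    }
  }
  # quadratic vertices: model 2 declines past its vertex, the DMI-squared
  # model 21 (vertex 35.8 kg/d) still rises at the top of the data range
  m2 <- ch4_model(2); m21 <- ch4_model(21)
  expect_lt(grad(m2, "dmi", tibble::tibble(dmi = 15)), 0)
  expect_gt(grad(m2, "dmi", tibble::tibble(dmi = 10)), 0)
  expect_gt(grad(m21, "dmi", tibble::tibble(dmi = 28.9)), 0)
})

test_that("the sanity envelope flags only the known extrapolators", {
  env <- prediction_envelope()
  expect_equal(nrow(env), 40)
  expect_true(env$within_envelope[env$id == 21])
  expect_true(env$within_envelope[env$id == 38])
  # the oldest equation extrapolates far above modern emissions at todays intakes
  expect_false(env$within_envelope[env$id == 1])
})

test_that("MJ/d model output converts consistently to g/d", {
  rec <- mean_record()
  for (id in ch4_models(output_unit = "MJ_d")$id) {
    mj <- predict(ch4_model(id), rec)
    expect_equal(convert_emission(mj, "MJ_d", "g_d"), mj / 0.05565,
                 tolerance = 1e-10)
  }
})

test_that("user-defined models join the evaluation machinery", {
  m <- new_ch4_model(id = 99L, label = "custom", output_unit = "g_d",
                     predictors = "dmi", expression = "10 + 18 * dmi")
  db <- tiny_db()
  expect_equal(predict(m, db), 10 + 18 * db$dmi)
  res <- evaluate_model(m, db)
  expect_equal(res$model_id, 99L)
  expect_equal(res$n, nrow(db))
})
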