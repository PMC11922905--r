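test_that("the default generator reproduces the measurement protocol", {
  tr <- synthetic_truth(default_truth_params("ye"), kind = "ETR", seed = 1)
  syn <- generate_synthetic(tr)
  expect_equal(sort(unique(syn$I)),
               c(0, 25, 50, 100, 200, 300, 400, 600, 800, 1000, 1200, 1400,
                 1600, 1800, 1900, 2000))
  expect_equal(length(unique(syn$replicate_id)), 5) # default replication
  expect_equal(nrow(syn), 16 * 5)
  expect_identical(unique(syn$quantity), "ETR")
  # noise scale: sd is 2% of the curve maximum by default
  mu <- eval_curve(default_truth_params("ye"), protocol_grid(), "ETR")
  resid <- syn$value - rep(mu, times = 5)
  expect_lt(abs(stats::sd(resid) / (0.02 * max(mu)) - 1), 0.25)
})

test_that("generation is seed-deterministic with independent replicates", {
  tr <- synthetic_truth(default_truth_params("negexp"), kind = "PHI",
                        seed = 99)
  expect_identical(generate_synthetic(tr), generate_synthetic(tr))
  s2 <- generate_synthetic(
    synthetic_truth(default_truth_params("negexp"), kind = "PHI", seed = 100))
  expect_false(identical(generate_synthetic(tr)$value, s2$value))
  # replicates differ from each other under noise
  syn <- generate_synthetic(tr)
  r1 <- syn$value[syn$replicate_id == unique(syn$replicate_id)[1]]
  r2 <- syn$value[syn$replicate_id == unique(syn$replicate_id)[2]]
  expect_false(identical(r1, r2))
  # but are identical when noiseless
  syn0 <- generate_synthetic(
    synthetic_truth(default_truth_params("negexp"), kind = "PHI",
                    noise_sd = 0, seed = 1))
  r01 <- syn0$value[syn0$replicate_id == unique(syn0$replicate_id)[1]]
  r02 <- syn0$value[syn0$replicate_id == unique(syn0$replicate_id)[2]]
  expect_identical(r01, r02)
})

test_that("long CSV survives a write-read round trip", {
  syn <- generate_synthetic(
    synthetic_truth(default_truth_params("exp"), kind = "PHI", seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_light_curves(syn, path)
  back <- read_light_curves(path)
  expect_equal(back$value, syn$value)
  expect_equal(back$I, syn$I)
  expect_equal(back$replicate_id, syn$replicate_id)
  # idempotence: a second round trip is byte-identical data
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_light_curves(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("wide fluorescence CSV is converted on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicate_id,I,F0,Fm,Fprime,Fmprime",
               "r1,0,400,2500,700,2500",
               "r1,1000,400,2500,600,2000"), path)
  out <- read_light_curves(path)
  expect_equal(out$value[out$quantity == "PHI" & out$I == 1000], 0.7)
  expect_equal(out$value[out$quantity == "ETR" & out$I == 1000], 294)
  expect_equal(out$value[out$quantity == "NPQ" & out$I == 0], 0)
})

test_that("malformed rows are dropped with their CSV line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicate_id,I,quantity,value",
               "r1,0,PHI,0.7",
               "r1,banana,PHI,0.6",      # line 3: non-numeric I
               "r1,100,PHI,0.65",
               "r1,-5,PHI,0.6",          # line 5: negative I
               "r1,200,FOO,0.6"), path)  # line 6: unknown quantity
  expect_warning(out <- read_light_curves(path), "dropped")
  probs <- attr(out, "problems")
  expect_equal(probs$line, c(3L, 5L, 6L))
  expect_equal(nrow(out), 2)
  # duplicates are a hard error, not a drop
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicate_id,I,quantity,value",
               "r1,0,PHI,0.7", "r1,0,PHI,0.7"), path2)
  expect_error(read_light_curves(path2), class = "lrc_error_format")
  # empty file
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("replicate_id,I,quantity,value", path3)
  expect_error(read_light_curves(path3), class = "lrc_error_empty")
  expect_error(read_light_curves("/nonexistent/file.csv"),
               class = "lrc_error_io")
})

test_that("results serialise to JSON losslessly, with flag tokens", {
  syn <- generate_synthetic(
    synthetic_truth(default_truth_params("nrh"), kind = "ETR",
                    noise_sd = 0, n_reps = 1, seed = 17))
  fit <- fit_light_curve(syn, fit_config("nrh", "ETR", seed = 18))
  path <- withr::local_tempfile(fileext = ".json")
  write_results(fit, path)
  back <- read_results(path)
  expect_equal(back$parameters$etr_max, fit$params$etr_max) # full precision
  expect_identical(back$model, "nrh")
  # NRH has no saturation irradiance: serialised as a readable token
  expect_identical(back$derived$i_sat, "NA(not-defined)")

  cmp <- compare_models(syn, kind = "ETR", seed = 19,
                        models = c("nrh", "negexp"))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_results(cmp, jpath)
  jb <- read_results(jpath)
  expect_identical(jb$kind, "ETR")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_results(cmp, cpath)
  tab <- readr::read_csv(cpath, show_col_types = FALSE)
  expect_identical(names(tab), c("term", "observed", "nrh", "negexp"))
  expect_true(any(grepl("NA(not-estimable)", tab$nrh, fixed = TRUE)))
})

test_that("synthetic metadata regenerates the same data", {
  syn <- generate_synthetic(
    synthetic_truth(default_truth_params("ye"), kind = "ETR", seed = 77))
  tr <- attr(syn, "truth")
  again <- generate_synthetic(tr)
  expect_identical(syn$value, again$value)
  expect_identical(attr(syn, "provenance"), attr(again, "provenance"))
})
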