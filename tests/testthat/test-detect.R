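make_features <- function(...) {
  tibble::tribble(~sample_id, ~mz, ~charge, ~rt_min, ~intensity, ...)
}

test_that("feature tables read with dialect mapping and error reporting", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,m/z,z,rt,abundance",
               "s1,1554.69,2,30.0,1e6",
               "s1,1036.80,3,30.1,5e5",
               "s1,900.00,,12.0,1e4"), path)
  f <- read_feature_table(path)
  expect_equal(nrow(f), 3)
  expect_named(f, c("sample_id", "mz", "charge", "rt_min", "intensity"))
  expect_true(is.na(f$charge[3]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,mz,charge,rt_min,intensity", "s1,abc,2,30,1"), bad)
  err <- tryCatch(read_feature_table(bad), error = identity)
  expect_s3_class(err, "cycloscreen_format_error")
  expect_match(conditionMessage(err), "mz")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,charge,rt_min,intensity", "s1,2,30,1"), nocol)
  expect_error(read_feature_table(nocol), class = "cycloscreen_format_error")
})

test_that("co-eluting charge states deconvolve to one neutral observation", {
  M <- 3307.43
  f <- make_features(
    "s1", mz_from_mass(M, 2), 2L, 30.0, 2e6,
    "s1", mz_from_mass(M, 3), 3L, 30.1, 1e6
  )
  obs <- deconvolute(f)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$neutral_mass, M, tolerance = 0.01)
  expect_equal(obs$charges, "2/3")
  expect_false(obs$ambiguous)
})

test_that("features far apart in RT or mass stay separate", {
  f <- make_features(
    "s1", 1500, 2L, 30.0, 1e6,
    "s1", 1500, 2L, 35.0, 1e6, # 5 min apart
    "s1", 1400, 2L, 30.0, 1e6  # different mass
  )
  obs <- deconvolute(f)
  expect_equal(nrow(obs), 3)
  expect_true(all(obs$ambiguous))
})

test_that("unknown-charge features yield ranked candidate interpretations", {
  f <- make_features("s1", 1200, NA_integer_, 30, 1e5)
  obs <- deconvolute(f, charge_range = 1:4)
  expect_equal(nrow(obs), 4)
  expect_true(all(obs$ambiguous))
  expect_setequal(obs$candidate_rank, 1:4)
  # prior favors 2+ then 3+
  expect_equal(obs$charges[obs$candidate_rank == 1], "2")
  expect_equal(obs$charges[obs$candidate_rank == 2], "3")
  # an unknown-charge feature consistent with a known observation attaches
  M <- 3100
  f2 <- make_features(
    "s1", mz_from_mass(M, 2), 2L, 30.0, 1e6,
    "s1", mz_from_mass(M, 3), NA_integer_, 30.05, 5e5
  )
  obs2 <- deconvolute(f2)
  expect_equal(nrow(obs2), 1)
  expect_equal(obs2$charges, "2/3")
})

test_that("deconvolution assigns each feature at most once and is complete", {
  set.seed(11)
  masses <- runif(30, 2800, 3800)
  f <- purrr::map_dfr(seq_along(masses), function(i) {
    tibble::tibble(sample_id = "s1",
                   mz = mz_from_mass(masses[i], 2:3),
                   charge = 2:3,
                   rt_min = 20 + i, intensity = 1e6)
  })
  obs <- deconvolute(f)
  expect_equal(nrow(obs), 30)
  expect_equal(sum(obs$n_features), nrow(f))
  expect_true(all(abs(sort(obs$neutral_mass) - sort(masses)) < 0.5))
  # empty input: empty output, not an error
  expect_equal(nrow(deconvolute(f[0, ])), 0)
})

test_that("cyclotide calling applies both windows and is idempotent", {
  obs <- tibble::tibble(
    sample_id = "s1",
    neutral_mass = c(3113.4, 2500, 3000, 3900),
    rt = c(30, 30, 10, 30),
    intensity = 1, charges = "2/3", n_charges = 2L, n_features = 2L,
    ambiguous = FALSE, candidate_rank = 1L
  )
  calls <- call_cyclotides(obs)
  expect_equal(calls$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$in_mass_window, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$in_rt_window, c(TRUE, TRUE, FALSE, TRUE))
  # idempotent and order-independent
  again <- call_cyclotides(calls[, names(obs)])
  expect_equal(again$accepted, calls$accepted)
  shuffled <- call_cyclotides(obs[c(3, 1, 4, 2), ])
  expect_equal(shuffled$accepted[order(shuffled$neutral_mass)],
               calls$accepted[order(calls$neutral_mass)])
})

test_that("hexose ladders are annotated and spurious deltas are not", {
  base <- 3138.4
  obs <- tibble::tibble(
    sample_id = "s1",
    neutral_mass = c(base, base + 162.0528, base + 2 * 162.0528, base + 150.0),
    rt = c(30, 30.2, 29.9, 30.1),
    intensity = 1, charges = "2/3", n_charges = 2L, n_features = 2L,
    ambiguous = FALSE, candidate_rank = 1L
  )
  ann <- annotate_derivatives(call_cyclotides(obs))
  ann <- ann[order(ann$neutral_mass), ] # base, base+150, base+162, base+324
  expect_equal(ann$derivative_type, c("none", "none", "hexose_x1", "hexose_x2"))
  expect_equal(ann$n_hexose, c(0L, 0L, 1L, 2L))
  expect_equal(ann$base_mass[3:4], c(base, base), tolerance = 1e-6)
  # every hexose link satisfies the stated mass identity
  hex <- ann[ann$n_hexose > 0, ]
  expect_true(all(abs(hex$neutral_mass - hex$base_mass -
                        hex$n_hexose * 162.0528) <= 0.5))
})

test_that("derivative links require co-elution and respect resolution flags", {
  base <- 3138.4
  obs <- tibble::tibble(
    sample_id = "s1",
    neutral_mass = c(base, base + 162.0528, base + 0.984),
    rt = c(30, 33, 30), # glycoform 3 min away
    intensity = 1, charges = "2/3", n_charges = 2L, n_features = 2L,
    ambiguous = FALSE, candidate_rank = 1L
  )
  ann <- annotate_derivatives(call_cyclotides(obs), mass_tol = 0.5)
  expect_equal(ann$derivative_type[ann$rt == 33], "none")
  # deamidation disabled at unit resolution, enabled below 0.5 Da
  expect_false("deamidation" %in% ann$derivative_type)
  ann_hr <- annotate_derivatives(call_cyclotides(obs), mass_tol = 0.05)
  expect_true("deamidation" %in% ann_hr$derivative_type)
})

test_that("alkylation verification detects the six-cysteine shift", {
  expect_true(verify_alkylation(3113.37, 3461.55, 6, 0.5)$pass)
  expect_false(verify_alkylation(3113.37, 3461.55, 4, 0.5)$pass)
  expect_true(verify_alkylation(3000, 3000, 0, 0.1)$pass)
  expect_equal(verify_alkylation(3113.37, 3113.37 + 6 * 58.02929, 6)$residual,
               0, tolerance = 1e-9)
})
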