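fake_calls <- function(mass, rt, sample_id = paste0("s", seq_along(mass)),
                       intensity = 1) {
  tibble::tibble(sample_id = sample_id, neutral_mass = mass, rt = rt,
                 intensity = intensity)
}

test_that("the both-criteria linkage rule separates and merges correctly", {
  # same mass, same RT -> one record
  r <- cluster_observations(fake_calls(c(3100.0, 3100.3), c(30.0, 30.4)))
  expect_equal(nrow(r), 1)
  # mass matches but RT differs by 2 min -> two records
  r <- cluster_observations(fake_calls(c(3100.0, 3100.1), c(30.0, 32.0)))
  expect_equal(nrow(r), 2)
  # RT matches but mass differs by 2 Da -> two records
  r <- cluster_observations(fake_calls(c(3100.0, 3102.0), c(30.0, 30.0)))
  expect_equal(nrow(r), 2)
  # singleton
  r <- cluster_observations(fake_calls(3100, 30))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_calls, 1)
})

test_that("records partition the accepted calls", {
  set.seed(21)
  calls <- fake_calls(runif(200, 2800, 3800), runif(200, 15, 60),
                      sample_id = sample(paste0("s", 1:20), 200, TRUE))
  r <- cluster_observations(calls)
  expect_equal(sum(r$n_calls), nrow(calls))
  ids <- dplyr::bind_rows(r$members)
  expect_equal(nrow(ids), nrow(calls))
  expect_lte(nrow(r), nrow(calls))
})

test_that("record count equals brute-force connected components (<=30 calls)", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    # cramped ranges so that chains actually form
    mass <- runif(n, 3000, 3006)
    rt <- runif(n, 30, 33)
    r <- cluster_observations(fake_calls(mass, rt), mass_tol = 1, rt_tol = 1)
    comp <- oracle_components(mass, rt, 1, 1)
    expect_equal(nrow(r), length(unique(comp)))
  }
})

test_that("shrinking tolerances never decreases the record count", {
  set.seed(23)
  mass <- runif(80, 3000, 3010)
  rt <- runif(80, 28, 34)
  calls <- fake_calls(mass, rt)
  n_loose <- nrow(cluster_observations(calls, mass_tol = 1.0, rt_tol = 1.0))
  n_mid <- nrow(cluster_observations(calls, mass_tol = 0.5, rt_tol = 1.0))
  n_tight <- nrow(cluster_observations(calls, mass_tol = 0.5, rt_tol = 0.5))
  expect_lte(n_loose, n_mid)
  expect_lte(n_mid, n_tight)
})

test_that("clustering is deterministic under input reordering", {
  set.seed(24)
  calls <- fake_calls(runif(50, 3000, 3005), runif(50, 30, 32))
  r1 <- cluster_observations(calls)
  r2 <- cluster_observations(calls[sample(nrow(calls)), ])
  expect_equal(r1$consensus_mass, r2$consensus_mass, tolerance = 1e-12)
  expect_equal(r1$n_calls, r2$n_calls)
})

test_that("derivative satellites are excluded from the registry", {
  calls <- fake_calls(c(3100, 3262.05), c(30, 30)) |>
    dplyr::mutate(accepted = TRUE,
                  derivative_type = c("none", "hexose_x1"))
  r <- cluster_observations(calls)
  expect_equal(nrow(r), 1)
})

test_that("occurrence matrix enumerates memberships and collapses species", {
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         species = c("A", "A", "B"),
                         genus = c("g1", "g1", "g2"))
  calls <- fake_calls(c(3100, 3100.2, 3200, 3300),
                      c(30, 30.2, 40, 20),
                      sample_id = c("s1", "s2", "s3", "s3"))
  r <- cluster_observations(calls)
  occ <- build_occurrence_matrix(r, meta)
  expect_equal(dim(occ), c(3L, 2L))
  m <- unclass(occ)
  # the record seen in s1 and s2 collapses to the single species A
  two_sample <- r$record_id[r$n_samples == 2]
  expect_equal(unname(m[two_sample, ]), c(TRUE, FALSE))
  expect_equal(sum(m), 3) # one species incidence per record after collapse
  expect_error(
    build_occurrence_matrix(r, meta[meta$sample_id != "s3", ]),
    class = "cycloscreen_metadata_error"
  )
})

test_that("occurrence stats match hand-enumerated values on a 5x3 matrix", {
  # hand-built: records r1..r5, species A,B,C
  records <- tibble::tibble(
    record_id = paste0("r", 1:5),
    consensus_mass = c(2900, 3000, 3100, 3200, 3300),
    consensus_rt = 30,
    n_calls = c(3, 1, 1, 2, 1),
    n_samples = c(3, 1, 1, 2, 1),
    samples = list(c("a", "b", "c"), "a", "b", c("b", "c"), "c"),
    members = vector("list", 5)
  )
  class(records) <- c("cyclotide_records", class(records))
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         species = c("A", "B", "C"),
                         genus = c("V", "V", "W"))
  occ <- build_occurrence_matrix(records, meta)
  st <- occurrence_stats(occ, group = "genus")
  expect_equal(st$summary$n_records, 5)
  expect_equal(st$summary$n_detections, 8) # 3+1+1+2+1
  expect_equal(st$summary$shared_fraction, 2 / 5) # r1 and r4
  expect_equal(st$summary$mass_mean, 3100)
  expect_equal(st$summary$mass_median, 3100)
  expect_equal(sort(st$per_column$n_records), c(2, 3, 3))
  # r1 present in both V-genus species -> prevalence 1; r4 in 1 of 2
  prev <- st$prevalence
  expect_equal(prev$prevalence[prev$group == "V" & prev$record_id == "r1"], 1)
  expect_equal(prev$prevalence[prev$group == "V" & prev$record_id == "r4"], 0.5)
  # prevalence semantics: a record in 7 of 10 species of a genus -> 70%
  expect_error(occurrence_stats(build_occurrence_matrix(records[0, ], meta)),
               class = "cycloscreen_empty_input")
})

test_that("tidy and glance methods expose records as rectangles", {
  calls <- fake_calls(c(3100, 3100.2), c(30, 30.1), c("s1", "s2"))
  r <- cluster_observations(calls)
  td <- tidy(r)
  expect_equal(nrow(td), 2)
  expect_true(all(c("record_id", "sample_id", "neutral_mass") %in% names(td)))
  g <- glance(r)
  expect_equal(g$n_records, 1)
  expect_equal(g$n_calls, 2)
})
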