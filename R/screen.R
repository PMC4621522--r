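# End-to-end screen orchestration: detect -> registry -> statistics ->
# chemotaxonomy -> diversity, with optional on-disk report.

#' Run the full cyclotide screen pipeline
#'
#' Executes deconvolution, cyclotide calling, derivative annotation,
#' cross-sample deduplication, occurrence statistics, chemotaxonomic
#' clustering and diversity extrapolation on a set of per-sample feature
#' tables. The result is a pure function of the inputs and parameters.
#'
#' @param features A feature tibble (or path to a feature CSV readable by
#'   [read_feature_table()]); may span many samples.
#' @param metadata A tibble (or CSV path) with `sample_id`, `species`, and
#'   optionally `genus`.
#' @param mass_tol,rt_tol Within-run deconvolution tolerances (Da, min).
#' @param mass_window,rt_window Cyclotide acceptance windows. The classic
#'   elution region is 25-40 min; the default here is the full 15-60 min
#'   span over which screen detections actually range.
#' @param link_mass_tol,link_rt_tol Derivative-ladder linking tolerances.
#' @param registry_mass_tol,registry_rt_tol Cross-run deduplication
#'   tolerances (the "same cyclotide" criterion: both within tolerance).
#' @param group Metadata column for prevalence statistics (default
#'   `"genus"` when present).
#' @param tree_method `"upgma"`, `"nj"`, or `NULL` to skip clustering.
#' @param metric Profile distance metric for the tree.
#' @param n_species_total,correction Diversity-extrapolation inputs: total
#'   species in the family and the under-detection multiplier.
#' @param out_dir Optional output directory; when given, writes
#'   `calls.csv`, `records.csv`, `matrix.tsv`, `tree.nwk`, `report.json`.
#' @return An object of class `cyclotide_screen`: list with `calls`,
#'   `records`, `occurrence`, `stats`, `uniqueness`, `diversity`, `tree`,
#'   `report` (a flat named list of headline numbers), and `params`.
#' @export
run_screen <- function(features, metadata,
                       mass_tol = 0.5, rt_tol = 0.2,
                       mass_window = c(2800, 3800), rt_window = c(15, 60),
                       link_mass_tol = 0.5, link_rt_tol = 1.0,
                       registry_mass_tol = 1.0, registry_rt_tol = 1.0,
                       group = NULL, tree_method = "upgma",
                       metric = "jaccard",
                       n_species_total = 1050, correction = 1,
                       out_dir = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(metadata)) {
    metadata <- readr::read_csv(metadata, show_col_types = FALSE)
  }
  if (is.null(group) && "genus" %in% names(metadata)) group <- "genus"

  obs <- deconvolute(features, mass_tol = mass_tol, rt_tol = rt_tol)
  calls <- call_cyclotides(obs, mass_window = mass_window,
                           rt_window = rt_window) |>
    annotate_derivatives(mass_tol = link_mass_tol, rt_link_tol = link_rt_tol)

  records <- cluster_observations(calls, mass_tol = registry_mass_tol,
                                  rt_tol = registry_rt_tol)
  occurrence <- build_occurrence_matrix(records, metadata)
  stats <- occurrence_stats(occurrence, group = group)
  uniqueness <- unique_per_species(occurrence)
  diversity <- extrapolate_total(
    max(uniqueness$mean_unique_per_species, .Machine$double.eps),
    n_species_total, correction
  )

  tree <- NULL
  if (!is.null(tree_method) && ncol(occurrence) >= 3L) {
    d <- profile_distance(occurrence, metric = metric)
    tree <- if (tree_method == "upgma") upgma_tree(d) else nj_tree(d)
  }

  glyco <- calls |>
    dplyr::filter(.data$n_hexose > 0, .data$candidate_rank == 1L)
  glyco_records <- dplyr::n_distinct(round(glyco$base_mass))

  report <- c(
    n_features = nrow(features),
    n_observations = nrow(obs),
    n_accepted_calls = sum(calls$accepted),
    n_records = stats$summary$n_records,
    n_detections = stats$summary$n_detections,
    mass_min = stats$summary$mass_min,
    mass_mean = stats$summary$mass_mean,
    mass_median = stats$summary$mass_median,
    mass_max = stats$summary$mass_max,
    shared_fraction = stats$summary$shared_fraction,
    n_glyco_calls = nrow(glyco),
    n_glyco_samples = dplyr::n_distinct(glyco$sample_id),
    mean_unique_per_species = uniqueness$mean_unique_per_species,
    diversity_estimate = diversity$estimate
  )

  out <- structure(list(
    calls = calls, records = records, occurrence = occurrence,
    stats = stats, uniqueness = uniqueness, diversity = diversity,
    tree = tree, report = as.list(report),
    params = list(
      mass_tol = mass_tol, rt_tol = rt_tol, mass_window = mass_window,
      rt_window = rt_window, link_mass_tol = link_mass_tol,
      link_rt_tol = link_rt_tol, registry_mass_tol = registry_mass_tol,
      registry_rt_tol = registry_rt_tol, group = group,
      tree_method = tree_method, metric = metric,
      n_species_total = n_species_total, correction = correction
    )
  ), class = "cyclotide_screen")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(calls, file.path(out_dir, "calls.csv"))
    write_records_csv(records, file.path(out_dir, "records.csv"))
    write_occurrence_tsv(occurrence, file.path(out_dir, "matrix.tsv"))
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(c(out$report, out$params),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.cyclotide_screen <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("Cyclotide screen: %d records from %d detections ",
           "(%d accepted calls)\n  masses %.0f-%.0f Da (mean %.0f, median %.0f); ",
           "shared fraction %.2f\n  glycoform calls: %d in %d samples; ",
           "diversity estimate: %d\n"),
    r$n_records, r$n_detections, r$n_accepted_calls,
    r$mass_min, r$mass_max, r$mass_mean, r$mass_median,
    r$shared_fraction, r$n_glyco_calls, r$n_glyco_samples,
    r$diversity_estimate
  ))
  invisible(x)
}

#' @export
tidy.cyclotide_screen <- function(x, ...) {
  x$records |>
    dplyr::select(-"members") |>
    dplyr::mutate(samples = purrr::map_chr(.data$samples, paste,
                                           collapse = ";")) |>
    tibble::as_tibble()
}

#' @export
glance.cyclotide_screen <- function(x, ...) {
  tibble::as_tibble(x$report)
}
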