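# Cross-sample deduplication of calls into distinct cyclotide records,
# the occurrence matrix, and screen-level statistics.

#' Deduplicate cyclotide calls into distinct records
#'
#' Two accepted calls are deemed the same cyclotide iff their neutral
#' masses agree within `mass_tol` AND their retention times agree within
#' `rt_tol` (a peak differing in either is a new cyclotide); records are
#' the connected components of this link graph (single-linkage transitive
#' closure). Processing order is fixed (mass, then RT, then sample), so the
#' output is deterministic.
#'
#' @param calls A calls tibble (from [call_cyclotides()] /
#'   [annotate_derivatives()]); only rows with `accepted == TRUE` and
#'   `derivative_type == "none"` (when those columns are present) are
#'   clustered, so glycoforms and other satellites do not inflate the
#'   registry.
#' @param mass_tol Cross-run mass tolerance, Da (default 1.0, looser than
#'   the within-run 0.5 because inter-run calibration drift dominates).
#' @param rt_tol Cross-run retention-time tolerance, minutes (default 1.0).
#' @return A tibble of class `cyclotide_records`: `record_id`,
#'   `consensus_mass` (intensity-weighted mean), `consensus_rt`,
#'   `n_calls`, `n_samples`, `samples` (list column), and `members`
#'   (list column of the member call rows).
#' @export
cluster_observations <- function(calls, mass_tol = 1.0, rt_tol = 1.0) {
  stopifnot(mass_tol > 0, rt_tol > 0)
  x <- calls
  if ("accepted" %in% names(x)) x <- x[x$accepted, , drop = FALSE]
  if ("derivative_type" %in% names(x)) {
    x <- x[x$derivative_type == "none", , drop = FALSE]
  }
  x <- dplyr::arrange(x, .data$neutral_mass, .data$rt, .data$sample_id)
  if (nrow(x) == 0L) {
    out <- tibble::tibble(record_id = character(), consensus_mass = numeric(),
                          consensus_rt = numeric(), n_calls = integer(),
                          n_samples = integer(), samples = list(),
                          members = list())
    class(out) <- c("cyclotide_records", class(out))
    return(out)
  }
  grp <- link_by_mass_rt(x$neutral_mass, x$rt, mass_tol, rt_tol)
  x$record_id <- sprintf("R%04d", grp)
  out <- x |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(
      consensus_mass = weighted.mean(.data$neutral_mass, .data$intensity),
      consensus_rt = weighted.mean(.data$rt, .data$intensity),
      n_calls = dplyr::n(),
      n_samples = dplyr::n_distinct(.data$sample_id),
      samples = list(sort(unique(.data$sample_id))),
      members = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$consensus_mass)
  class(out) <- c("cyclotide_records", class(out))
  out
}

#' @export
tidy.cyclotide_records <- function(x, ...) {
  x |>
    dplyr::select("record_id", "members") |>
    tidyr::unnest("members", names_sep = NULL)
}

#' @export
glance.cyclotide_records <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x),
    n_calls = sum(x$n_calls),
    mass_min = min(x$consensus_mass),
    mass_mean = mean(x$consensus_mass),
    mass_median = median(x$consensus_mass),
    mass_max = max(x$consensus_mass)
  )
}

#' Build a record-by-sample (or record-by-species) occurrence matrix
#'
#' @param records A `cyclotide_records` tibble from
#'   [cluster_observations()].
#' @param metadata A tibble with columns `sample_id`, `species`, and
#'   optionally grouping columns such as `genus`.
#' @param collapse `"species"` (default; columns are species, an entry is
#'   1 iff any sample of that species carries the record) or `"sample"`.
#' @return An object of class `occurrence_matrix`: a logical matrix with
#'   records as rows, with attributes `metadata` (one row per column) and
#'   `consensus` (record-level mass/RT).
#' @export
build_occurrence_matrix <- function(records, metadata,
                                    collapse = c("species", "sample")) {
  collapse <- match.arg(collapse)
  stopifnot(all(c("sample_id", "species") %in% names(metadata)))
  all_samples <- unique(unlist(records$samples))
  unknown <- setdiff(all_samples, metadata$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("sample id(s) missing from metadata: %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "cycloscreen_metadata_error")
  }
  long <- records |>
    dplyr::select("record_id", "samples") |>
    tidyr::unnest_longer("samples", values_to = "sample_id") |>
    dplyr::mutate(sample_id = as.character(.data$sample_id)) |>
    dplyr::left_join(metadata, by = "sample_id")
  col_var <- if (collapse == "species") "species" else "sample_id"
  cols <- sort(unique(metadata[[col_var]]))
  m <- matrix(FALSE, nrow = nrow(records), ncol = length(cols),
              dimnames = list(records$record_id, cols))
  if (nrow(long) > 0L) {
    m[cbind(long$record_id, long[[col_var]])] <- TRUE
  }
  col_meta <- metadata |>
    dplyr::distinct(dplyr::across(dplyr::all_of(
      unique(c(col_var, setdiff(names(metadata), "sample_id")))
    ))) |>
    dplyr::rename(label = dplyr::all_of(col_var)) |>
    dplyr::distinct(.data$label, .keep_all = TRUE) |>
    dplyr::arrange(.data$label)
  structure(m,
            metadata = col_meta,
            consensus = records[, c("record_id", "consensus_mass", "consensus_rt")],
            collapse = collapse,
            class = c("occurrence_matrix", "matrix", "array"))
}

#' @export
tidy.occurrence_matrix <- function(x, ...) {
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  tibble::as_tibble(as.table(m), .name_repair = "minimal") |>
    setNames(c("record_id", "label", "present")) |>
    dplyr::mutate(present = as.logical(.data$present)) |>
    tibble::as_tibble()
}

#' Summary statistics of an occurrence matrix
#'
#' Reports the screen-level numbers: total detections (record-species
#' incidences), distinct records, per-column record-count distribution,
#' consensus-mass distribution, the fraction of records present in more
#' than one species, and, when a grouping column (e.g. `genus`) is
#' available in the metadata, the prevalence of each record within each
#' group (share of that group's species carrying the record).
#'
#' @param x An `occurrence_matrix`.
#' @param group Optional metadata column name for prevalence (e.g.
#'   `"genus"`).
#' @return A list of class `occurrence_stats` with elements `summary`
#'   (one-row tibble), `per_column` (records per species/sample), and
#'   `prevalence` (per record x group; `NULL` when no `group` given).
#' @export
occurrence_stats <- function(x, group = NULL) {
  stopifnot(inherits(x, "occurrence_matrix"))
  if (nrow(x) == 0L || ncol(x) == 0L) {
    abort("empty occurrence matrix", class = "cycloscreen_empty_input")
  }
  m <- unclass(x)
  consensus <- attr(x, "consensus")
  per_col <- tibble::tibble(label = colnames(m), n_records = unname(colSums(m)))
  n_species_per_record <- rowSums(m)
  masses <- consensus$consensus_mass[match(rownames(m), consensus$record_id)]
  summary <- tibble::tibble(
    n_records = nrow(m),
    n_detections = sum(m),
    n_columns = ncol(m),
    records_per_column_min = min(per_col$n_records),
    records_per_column_mean = mean(per_col$n_records),
    records_per_column_median = median(per_col$n_records),
    records_per_column_max = max(per_col$n_records),
    mass_min = min(masses),
    mass_mean = mean(masses),
    mass_median = median(masses),
    mass_max = max(masses),
    shared_fraction = mean(n_species_per_record > 1)
  )
  prevalence <- NULL
  meta <- attr(x, "metadata")
  if (!is.null(group)) {
    if (!group %in% names(meta)) {
      abort(sprintf("metadata has no column '%s'", group),
            class = "cycloscreen_metadata_error")
    }
    grp <- meta[[group]][match(colnames(m), meta$label)]
    prevalence <- purrr::map_dfr(unique(grp), function(g) {
      cols <- which(grp == g)
      tibble::tibble(
        group = g,
        record_id = rownames(m),
        n_in_group = unname(rowSums(m[, cols, drop = FALSE])),
        n_group = length(cols),
        prevalence = unname(rowSums(m[, cols, drop = FALSE])) / length(cols)
      )
    }) |>
      dplyr::filter(.data$n_in_group > 0)
  }
  structure(list(summary = summary, per_column = per_col,
                 prevalence = prevalence),
            class = "occurrence_stats")
}

#' @export
print.occurrence_stats <- function(x, ...) {
  cat("Occurrence statistics\n")
  print(x$summary)
  invisible(x)
}

#' Write records and occurrence matrix to disk
#'
#' @param records A `cyclotide_records` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  records |>
    dplyr::mutate(samples = purrr::map_chr(.data$samples, paste, collapse = ";")) |>
    dplyr::select(-"members") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_records_csv
#' @param x An `occurrence_matrix`.
#' @export
write_occurrence_tsv <- function(x, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(x) * 1L), rownames = "record_id")
  readr::write_tsv(df, path)
  invisible(path)
}
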