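# Diversity accounting: per-species uniqueness, family-wide extrapolation,
# and the combinatorial loop-library size.

#' Species-unique records and the shared fraction
#'
#' For each species, counts the records found in exactly that species and
#' nowhere else; also reports the global shared fraction (records present
#' in more than one species divided by all records). In the Violaceae
#' screen roughly a third of cyclotides are shared, i.e. about two thirds
#' of a species' cyclotides are unique to it.
#'
#' @param x An `occurrence_matrix` (records x species) or 0-1 matrix.
#' @return A list of class `uniqueness_summary`: `per_species` (tibble
#'   with `species`, `n_records`, `n_unique`), `shared_fraction`,
#'   `n_records`, `n_shared`, `mean_unique_per_species`.
#' @export
unique_per_species <- function(x) {
  m <- unclass(x) * 1
  if (length(m) == 0L || nrow(m) == 0L) {
    abort("empty occurrence matrix", class = "cycloscreen_empty_input")
  }
  n_sp_per_record <- rowSums(m > 0)
  uniq <- m > 0 & n_sp_per_record == 1
  per_species <- tibble::tibble(
    species = colnames(m),
    n_records = unname(colSums(m > 0)),
    n_unique = unname(colSums(uniq))
  )
  structure(list(
    per_species = per_species,
    shared_fraction = mean(n_sp_per_record > 1),
    n_records = nrow(m),
    n_shared = sum(n_sp_per_record > 1),
    mean_unique_per_species = mean(per_species$n_unique)
  ), class = "uniqueness_summary")
}

#' @export
print.uniqueness_summary <- function(x, ...) {
  cat(sprintf(
    "%d records, %d shared across species (%.1f%%); mean %.2f species-unique records per species\n",
    x$n_records, x$n_shared, 100 * x$shared_fraction,
    x$mean_unique_per_species
  ))
  invisible(x)
}

#' Extrapolate total cyclotide diversity
#'
#' The naive family-wide product: average number of species-unique
#' cyclotides per species, times the total species count of the family,
#' times an optional abundance-bias correction (deep single-species
#' studies find several-fold more cyclotides than a one-shot screen, so a
#' correction up to ~5 is defensible). No richness estimator is
#' substituted; the estimate is floor-rounded.
#'
#' @param avg_unique Mean species-unique cyclotides per species (> 0).
#' @param n_species_total Total species in the family (e.g. ~1050 for the
#'   Violaceae).
#' @param correction Multiplier >= 1 for under-detection (default 1).
#' @return A one-row tibble of class `diversity_estimate` with
#'   `avg_unique_per_species`, `n_species_total`, `correction_factor`,
#'   `estimate`.
#' @export
#' @examples
#' extrapolate_total(5, 1050)        # >= 5000
#' extrapolate_total(5, 1000, 5)     # 25000
extrapolate_total <- function(avg_unique, n_species_total, correction = 1) {
  if (avg_unique <= 0 || n_species_total <= 0 || correction <= 0) {
    abort("all extrapolation inputs must be positive",
          class = "cycloscreen_domain_error")
  }
  out <- tibble::tibble(
    avg_unique_per_species = avg_unique,
    n_species_total = n_species_total,
    correction_factor = correction,
    estimate = floor(avg_unique * n_species_total * correction)
  )
  class(out) <- c("diversity_estimate", class(out))
  out
}

#' @export
glance.diversity_estimate <- function(x, ...) tibble::as_tibble(x)

#' Combinatorial loop-library size
#'
#' The theoretical number of chimeric cyclotides obtainable by freely
#' recombining observed inter-cysteine loop variants: the product of the
#' six per-loop distinct-variant counts. With natural variant counts this
#' reaches the hundreds of millions.
#'
#' @param variant_counts Numeric vector of exactly six nonnegative
#'   per-loop counts.
#' @return The exact product (error if it would exceed exact double
#'   integer range).
#' @export
#' @examples
#' loop_library_size(c(10, 10, 10, 10, 10, 10)) # 1e6
loop_library_size <- function(variant_counts) {
  if (length(variant_counts) != 6L) {
    abort("exactly six per-loop variant counts are required",
          class = "cycloscreen_input_error")
  }
  if (any(variant_counts < 0) || any(variant_counts != floor(variant_counts))) {
    abort("variant counts must be nonnegative integers",
          class = "cycloscreen_input_error")
  }
  p <- prod(as.numeric(variant_counts))
  if (p > 2^53) {
    abort("product exceeds exact integer range",
          class = "cycloscreen_domain_error")
  }
  p
}

#' Count distinct loop variants in a sequence collection
#'
#' Runs [parse_loops()] over a set of cyclotide sequences and counts the
#' distinct variants per loop, the input to [loop_library_size()].
#'
#' @param sequences Character vector of cyclotide sequences.
#' @return A tibble with `loop` (1-6) and `n_variants`.
#' @export
#' @examples
#' ref <- violaceae_cyclotides()
#' # rigra A carries a second Glu and needs an explicit loop-1 anchor,
#' # so it is excluded from automatic counting here
#' counts <- count_loop_variants(ref$sequence[ref$name != "rigra A"])
#' loop_library_size(counts$n_variants)
count_loop_variants <- function(sequences) {
  loops <- purrr::map_dfr(sequences, parse_loops)
  loops |>
    dplyr::group_by(.data$loop) |>
    dplyr::summarise(n_variants = dplyr::n_distinct(.data$sequence),
                     .groups = "drop")
}
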