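# Per-sample detection: feature ingestion, charge-state deconvolution,
# mass/RT window calling, derivative (glycoform etc.) annotation.

# Header synonyms accepted on input; canonical names are
# sample_id, mz, charge, rt_min, intensity.
.feature_dialect <- c(
  "sample_id" = "sample_id", "sample" = "sample_id", "sampleid" = "sample_id",
  "mz" = "mz", "m/z" = "mz", "m.z" = "mz",
  "charge" = "charge", "z" = "charge",
  "rt_min" = "rt_min", "rt" = "rt_min", "retention_time" = "rt_min",
  "rt(min)" = "rt_min", "rt_minutes" = "rt_min",
  "intensity" = "intensity", "abundance" = "intensity", "height" = "intensity"
)

#' Read an LC-MS feature table
#'
#' Reads a per-sample feature CSV with columns `sample_id`, `mz`, `charge`,
#' `rt_min`, `intensity`. Common header variants (`m/z`, `z`, `rt`,
#' `abundance`, ...) are mapped to the canonical names; a blank or missing
#' `charge` denotes an unknown charge state. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A tibble of features with canonical column names and types.
#' @export
read_feature_table <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  key <- tolower(trimws(names(df)))
  mapped <- .feature_dialect[key]
  names(df)[!is.na(mapped)] <- mapped[!is.na(mapped)]
  required <- c("sample_id", "mz", "rt_min", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("feature table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cycloscreen_format_error")
  }
  if (!"charge" %in% names(df)) df$charge <- NA_character_
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(out))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                    x[bad[1]], col, bad[1]),
            class = "cycloscreen_format_error")
    }
    out
  }
  tibble::tibble(
    sample_id = as.character(df$sample_id),
    mz = parse_num(df$mz, "mz"),
    charge = as.integer(parse_num(df$charge, "charge")),
    rt_min = parse_num(df$rt_min, "rt_min"),
    intensity = parse_num(df$intensity, "intensity")
  )
}

# Single-linkage grouping of points by |dmass| <= mass_tol AND |drt| <= rt_tol,
# scanning in mass order. Returns an integer group id per row.
link_by_mass_rt <- function(mass, rt, mass_tol, rt_tol) {
  n <- length(mass)
  if (n == 0L) return(integer(0))
  ord <- order(mass, rt)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (mass[j] - mass[i] > mass_tol) break
      if (abs(rt[j] - rt[i]) <= rt_tol) union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(mass)]))
}

#' Deconvolute features into neutral-mass observations
#'
#' Within one sample, features whose implied neutral masses (from their
#' known charge, or from each charge in `charge_range` when the charge is
#' unknown) agree within `mass_tol` and co-elute within `rt_tol` are merged
#' into one neutral observation. Observations supported by two or more
#' charge states are unambiguous; those seen at a single charge state are
#' flagged `ambiguous`. An unknown-charge feature that cannot be attached
#' to any known-charge observation yields one candidate observation per
#' plausible charge, ranked by the charge prior, with only the top-ranked
#' candidate counted as the feature's assignment.
#'
#' @param features A feature tibble, as from [read_feature_table()]; may
#'   contain several samples (each is deconvolved independently).
#' @param mass_tol Neutral-mass agreement tolerance, Da (default 0.5 for
#'   unit-resolution ion-trap data).
#' @param rt_tol Co-elution tolerance, minutes (default 0.2).
#' @param charge_range Integer charges tried for unknown-charge features
#'   (default 1:4).
#' @param charge_prior Named numeric prior over charge states used to rank
#'   candidate interpretations; defaults to favoring 2+ and 3+.
#' @return A tibble of observations: `sample_id`, `neutral_mass`
#'   (intensity-weighted mean), `rt` (intensity-weighted mean),
#'   `intensity` (summed), `charges` (slash-separated), `n_charges`,
#'   `n_features`, `ambiguous`, `candidate_rank` (1 for assigned
#'   observations, >1 for lower-ranked charge interpretations of
#'   unassignable unknown-charge features).
#' @export
deconvolute <- function(features, mass_tol = 0.5, rt_tol = 0.2,
                        charge_range = 1:4,
                        charge_prior = c(`1` = 0.05, `2` = 0.45, `3` = 0.40, `4` = 0.10)) {
  stopifnot(mass_tol > 0, rt_tol > 0)
  if (nrow(features) == 0L) {
    return(tibble::tibble(
      sample_id = character(), neutral_mass = numeric(), rt = numeric(),
      intensity = numeric(), charges = character(), n_charges = integer(),
      n_features = integer(), ambiguous = logical(), candidate_rank = integer()
    ))
  }
  features |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ deconvolute_one(.x, .y$sample_id, mass_tol, rt_tol,
                                          charge_range, charge_prior)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$neutral_mass)
}

deconvolute_one <- function(f, sample_id, mass_tol, rt_tol, charge_range,
                            charge_prior) {
  known <- f[!is.na(f$charge), , drop = FALSE]
  unknown <- f[is.na(f$charge), , drop = FALSE]

  obs <- NULL
  if (nrow(known) > 0L) {
    known$neutral <- mass_from_mz(known$mz, known$charge)
    grp <- link_by_mass_rt(known$neutral, known$rt_min, mass_tol, rt_tol)
    obs <- known |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        neutral_mass = weighted.mean(.data$neutral, .data$intensity),
        rt = weighted.mean(.data$rt_min, .data$intensity),
        intensity = sum(.data$intensity),
        charges = paste(sort(unique(.data$charge)), collapse = "/"),
        n_charges = dplyr::n_distinct(.data$charge),
        n_features = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(ambiguous = .data$n_charges < 2L, candidate_rank = 1L) |>
      dplyr::select(-".grp")
  }

  extra <- list()
  if (nrow(unknown) > 0L) {
    prior <- charge_prior[as.character(charge_range)]
    prior[is.na(prior)] <- min(charge_prior) / 2
    for (i in seq_len(nrow(unknown))) {
      cand_mass <- mass_from_mz(unknown$mz[i], charge_range)
      attached <- FALSE
      if (!is.null(obs) && nrow(obs) > 0L) {
        # attach to the closest existing observation consistent with some charge
        dmat <- outer(cand_mass, obs$neutral_mass, function(a, b) abs(a - b))
        drt <- abs(unknown$rt_min[i] - obs$rt)
        dmat[, drt > rt_tol] <- Inf
        if (min(dmat) <= mass_tol) {
          idx <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
          j <- idx[2]
          z <- charge_range[idx[1]]
          w <- obs$intensity[j] + unknown$intensity[i]
          obs$neutral_mass[j] <- (obs$neutral_mass[j] * obs$intensity[j] +
                                    cand_mass[idx[1]] * unknown$intensity[i]) / w
          obs$rt[j] <- (obs$rt[j] * obs$intensity[j] +
                          unknown$rt_min[i] * unknown$intensity[i]) / w
          obs$intensity[j] <- w
          zs <- sort(unique(c(as.integer(strsplit(obs$charges[j], "/")[[1]]), z)))
          obs$charges[j] <- paste(zs, collapse = "/")
          obs$n_charges[j] <- length(zs)
          obs$n_features[j] <- obs$n_features[j] + 1L
          obs$ambiguous[j] <- obs$n_charges[j] < 2L
          attached <- TRUE
        }
      }
      if (!attached) {
        rk <- rank(-prior, ties.method = "first")
        extra[[length(extra) + 1L]] <- tibble::tibble(
          neutral_mass = cand_mass,
          rt = unknown$rt_min[i],
          intensity = unknown$intensity[i],
          charges = as.character(charge_range),
          n_charges = 1L,
          n_features = 1L,
          ambiguous = TRUE,
          candidate_rank = as.integer(rk)
        )
      }
    }
  }
  out <- dplyr::bind_rows(c(list(obs), extra))
  out
}

#' Call cyclotide candidates by mass and retention-time windows
#'
#' A neutral observation is accepted as a putative cyclotide iff its mass
#' lies in `mass_window` and its retention time in `rt_window`. Rejected
#' observations are retained with their window flags for audit. Candidate
#' interpretations beyond rank 1 (unknown-charge features) are never
#' accepted.
#'
#' @param observations Output of [deconvolute()].
#' @param mass_window Numeric length-2, Da; default `c(2800, 3800)`.
#' @param rt_window Numeric length-2, minutes; default `c(25, 40)`, the
#'   classic cyclotide elution region (widen to `c(15, 60)` for screens
#'   where detections span the full gradient).
#' @return The observations tibble with logical columns `in_mass_window`,
#'   `in_rt_window`, `accepted`, plus placeholder derivative columns
#'   (`derivative_type = "none"`, `base_mass = NA`, `n_hexose = 0`)
#'   filled in by [annotate_derivatives()].
#' @export
call_cyclotides <- function(observations, mass_window = c(2800, 3800),
                            rt_window = c(25, 40)) {
  stopifnot(length(mass_window) == 2L, mass_window[1] < mass_window[2],
            length(rt_window) == 2L, rt_window[1] < rt_window[2])
  observations |>
    dplyr::mutate(
      in_mass_window = .data$neutral_mass >= mass_window[1] &
        .data$neutral_mass <= mass_window[2],
      in_rt_window = .data$rt >= rt_window[1] & .data$rt <= rt_window[2],
      accepted = .data$in_mass_window & .data$in_rt_window &
        .data$candidate_rank == 1L,
      derivative_type = "none",
      base_mass = NA_real_,
      n_hexose = 0L
    )
}

#' Annotate glycoform and other derivative mass ladders
#'
#' Within each sample, links a candidate call to a lighter base call when
#' their mass difference matches `n` hexoses (n = 1..`max_hexose`;
#' 162.0528 Da each) within `mass_tol` and they elute within `rt_link_tol`
#' (glycoforms elute closely or co-elute with their parent). Single-event
#' links for oxidation (+15.995 Da) and, when the resolution permits
#' (`mass_tol < 0.5`), deamidation (+0.984 Da) are annotated the same way.
#' Each candidate links to at most one base, the one with the smallest
#' mass residual; links are acyclic by the mass ordering.
#'
#' @param calls Output of [call_cyclotides()].
#' @param mass_tol Mass residual tolerance, Da (default 0.5).
#' @param rt_link_tol Maximum RT gap between derivative and base, minutes
#'   (default 1.0).
#' @param max_hexose Longest hexose ladder considered (default 3).
#' @param allow_deamidation Whether +0.984 links are attempted; default
#'   `mass_tol < 0.5`, since deamidation is not resolvable on
#'   unit-resolution data.
#' @return `calls` with `derivative_type` (`"none"`, `"hexose_x1"` ...,
#'   `"oxidation"`, `"deamidation"`), `base_mass` and `n_hexose` filled in.
#' @export
annotate_derivatives <- function(calls, mass_tol = 0.5, rt_link_tol = 1.0,
                                 max_hexose = 3L,
                                 allow_deamidation = mass_tol < 0.5) {
  stopifnot(mass_tol > 0, rt_link_tol > 0)
  deltas <- c(
    setNames(seq_len(max_hexose) * HEXOSE_DELTA,
             paste0("hexose_x", seq_len(max_hexose))),
    oxidation = OXIDATION_DELTA
  )
  if (allow_deamidation) deltas <- c(deltas, deamidation = DEAMIDATION_DELTA)

  calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$neutral_mass)
      usable <- which(g$candidate_rank == 1L)
      n <- nrow(g)
      # ascending mass order: bases are resolved before their satellites,
      # and ladders (n = 1, 2, ...) all anchor on the same underived base
      for (ci in usable) {
        best <- NULL
        for (bi in usable) {
          if (bi == ci) next
          if (g$derivative_type[bi] != "none") next
          dm <- g$neutral_mass[ci] - g$neutral_mass[bi]
          if (dm <= 0) next
          if (abs(g$rt[ci] - g$rt[bi]) > rt_link_tol) next
          resid <- abs(dm - deltas)
          k <- which.min(resid)
          if (resid[k] <= mass_tol &&
              (is.null(best) || resid[k] < best$resid)) {
            best <- list(bi = bi, type = names(deltas)[k], resid = resid[k])
          }
        }
        if (!is.null(best)) {
          g$derivative_type[ci] <- best$type
          g$base_mass[ci] <- g$neutral_mass[best$bi]
          g$n_hexose[ci] <- if (startsWith(best$type, "hexose_x")) {
            as.integer(sub("hexose_x", "", best$type))
          } else 0L
        }
      }
      g
    }) |>
    dplyr::ungroup()
}

#' Verify cysteine count by reduction/alkylation mass shift
#'
#' Reduction plus carbamidomethylation adds 58.0293 Da per cysteine; a
#' cyclotide (six Cys) therefore shifts by a nominal 348 Da. The check
#' passes iff the observed shift matches `n_cys` alkylation events within
#' `tol`.
#'
#' @param native_mass Neutral mass before treatment, Da.
#' @param treated_mass Neutral mass after reduction/alkylation, Da.
#' @param n_cys Expected number of cysteines (default 6).
#' @param tol Tolerance on the residual, Da (default 0.5).
#' @return A tibble with `expected_shift`, `observed_shift`, `residual`,
#'   `pass`.
#' @export
#' @examples
#' verify_alkylation(3113.37, 3461.55, n_cys = 6)
verify_alkylation <- function(native_mass, treated_mass, n_cys = 6L,
                              tol = 0.5) {
  stopifnot(n_cys >= 0)
  expected <- n_cys * ALKYLATION_DELTA
  observed <- treated_mass - native_mass
  tibble::tibble(
    expected_shift = expected,
    observed_shift = observed,
    residual = observed - expected,
    pass = abs(observed - expected) <= tol
  )
}
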