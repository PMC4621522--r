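# Synthetic-data generator emulating a herbarium LC-MS cyclotide screen,
# with full ground truth so every pipeline stage can be validated
# end-to-end.

# Deterministic per-stage seed derivation so that each generation stage
# draws from its own named substream of the master seed.
substream_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 7919L +
    (sum(utf8ToInt(stage)) %% 1000L) * 104729L %% 2147483647L
}

# Residue alphabet used inside loops: no Cys (the six framework Cys are
# fixed) and no Glu (conserved Glu is placed in loop 1), weighted toward
# the small/polar residues that dominate natural cyclotide loops.
.loop_alphabet <- c(
  G = 0.10, A = 0.07, S = 0.11, P = 0.06, V = 0.08, T = 0.10,
  L = 0.10, I = 0.03, N = 0.07, D = 0.05, K = 0.06, R = 0.04,
  Y = 0.04, W = 0.02, F = 0.03, H = 0.02, Q = 0.01, M = 0.01
)

#' Configuration for the synthetic screen generator
#'
#' Defaults reproduce the statistical structure of a large herbarium
#' screen: 143 species across ten genus blocks, 744 distinct cyclotides of
#' which one third occur in more than one species, neutral masses in
#' 2800-3800 Da, ions at 2+/3+ within m/z 800-1900, retention times
#' 15-60 min with the bulk in the 25-40 min cyclotide region, a 0.15
#' glycosylation rate, and a few widespread "varv A-like" cyclotides
#' planted in 50-70% of the Viola block.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_species Number of species (one sample each).
#' @param n_distinct Distinct cyclotides planted.
#' @param shared_fraction Fraction of the pool planted in >1 species.
#' @param max_per_species Cap on cyclotides per species.
#' @param extra_share_rate Poisson rate for extra species beyond the
#'   minimum two for shared cyclotides.
#' @param mass_window Neutral-mass window for generated cyclotides, Da.
#' @param mass_noise_sd Per-feature mass error, Da.
#' @param rt_noise_sd Per-detection retention-time error, minutes.
#' @param rt_intercept,rt_slope Linear retention model
#'   `rt = intercept + slope * Kyte-Doolittle sum`, clamped to `rt_range`.
#' @param rt_range Clamp range for retention times, minutes.
#' @param glyco_rate Fraction of distinct cyclotides carrying a hexose
#'   glycoform satellite wherever they are expressed.
#' @param glyco_intensity Relative intensity of glycoform satellites.
#' @param charge_states Charge states emitted per detection.
#' @param mz_range Instrument scan range; features outside it are dropped.
#' @param noise_features Expected number of unrelated noise features per
#'   sample (Poisson; 0 disables).
#' @param n_common,common_prevalence,common_genus Widespread cyclotides:
#'   how many, the share of the `common_genus` block each occupies, and
#'   the genus block.
#' @param mobius_fraction Fraction of generated sequences with a Mobius
#'   loop 5 (aromatic + Pro); the rest are bracelets.
#' @param messy Relax the loop grammar (allows stray Glu outside loop 1)
#'   for robustness testing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 143L,
                       n_distinct = 744L,
                       shared_fraction = 1 / 3,
                       max_per_species = 25L,
                       extra_share_rate = 0.1,
                       mass_window = c(2800, 3800),
                       mass_noise_sd = 0.15,
                       rt_noise_sd = 0.15,
                       rt_intercept = 32,
                       rt_slope = 0.55,
                       rt_range = c(15, 60),
                       glyco_rate = 0.15,
                       glyco_intensity = 0.3,
                       charge_states = c(2L, 3L),
                       mz_range = c(800, 1900),
                       noise_features = 0,
                       n_common = 3L,
                       common_prevalence = c(0.70, 0.50, 0.50),
                       common_genus = "Viola",
                       mobius_fraction = 1 / 3,
                       messy = FALSE) {
  stopifnot(
    n_species >= 2L, n_distinct >= 1L,
    shared_fraction >= 0, shared_fraction <= 1,
    glyco_rate >= 0, glyco_rate <= 1,
    mass_window[1] < mass_window[2],
    length(common_prevalence) == n_common
  )
  structure(as.list(environment()), class = "sim_config")
}

genus_proportions <- c(
  Viola = 0.28, Hybanthus = 0.18, Rinorea = 0.18, Melicytus = 0.07,
  Gloeospermum = 0.06, Orthion = 0.05, Leonia = 0.05, Pombalia = 0.05,
  Paypayrola = 0.04, Amphirrhox = 0.04
)

sample_loop <- function(len, alphabet = .loop_alphabet) {
  paste(sample(names(alphabet), len, replace = TRUE, prob = alphabet),
        collapse = "")
}

# One random cyclotide sequence under the loop grammar: six framework Cys,
# conserved Glu in loop 1, a short loop 4, variable loops 2/3/5/6, and a
# subfamily-determining loop 5.
random_cyclotide <- function(mobius, messy = FALSE) {
  alph <- .loop_alphabet
  if (messy && runif(1) < 0.2) alph <- c(alph, E = 0.05)
  loop1 <- paste0("GE", sample_loop(sample(0:1, 1), alph[names(alph) != "P"]))
  loop2 <- sample_loop(sample(3:5, 1), alph)
  loop3 <- sample_loop(sample(4:6, 1), alph)
  loop4 <- sample_loop(1L, alph[c("S", "T", "G", "K", "V")])
  loop5 <- if (mobius) {
    paste0(sample_loop(1L, alph[names(alph) != "P"]),
           sample(c("W", "F", "Y"), 1), "P",
           sample_loop(1L, alph[names(alph) != "P"]))
  } else {
    paste0(sample_loop(sample(3:5, 1),
                       alph[!names(alph) %in% "P"]),
           sample(c("K", "R", "V"), 1))
  }
  loop6 <- sample_loop(sample(4:7, 1), alph)
  paste0("C", loop2, "C", loop3, "C", loop4, "C", loop5, "C", loop6,
         "C", loop1)
}

kd_sum <- function(sequence) {
  kd <- setNames(.residues$hydropathy, .residues$code)
  vapply(strsplit(vapply(sequence, clean_sequence, character(1),
                         USE.NAMES = FALSE), ""),
         function(ch) sum(kd[ch]), numeric(1))
}

rt_from_sequence <- function(sequence, config) {
  rt <- config$rt_intercept + config$rt_slope * kd_sum(sequence)
  pmin(pmax(rt, config$rt_range[1]), config$rt_range[2])
}

#' Generate a ground-truth cyclotide pool
#'
#' Rejection-samples cyclotide sequences under the loop grammar until `n`
#' are accepted: each must have its cyclic monoisotopic mass inside
#' `config$mass_window` and must be distinguishable from every previously
#' accepted cyclotide under the registry criterion (mass within 1 Da AND
#' retention time within 1 min means "same cyclotide"), with a 3-sigma
#' noise guard, so the planted pool contains exactly `n` cyclotides by the
#' screen's own counting rule.
#'
#' @param n Number of cyclotides; defaults to `config$n_distinct`.
#' @param config A [sim_config()].
#' @return A tibble: `cyclotide_id`, `sequence`, `mass` (Da), `rt_true`
#'   (min), `subfamily`, `glycosylated`.
#' @export
generate_sequences <- function(config = sim_config(), n = config$n_distinct) {
  set.seed(substream_seed(config$seed, "pool"))
  guard_mass <- 1.0 + 3 * config$mass_noise_sd
  guard_rt <- 1.0 + 3 * config$rt_noise_sd
  masses <- numeric(0)
  rts <- numeric(0)
  seqs <- character(0)
  fams <- character(0)
  tries <- 0L
  max_tries <- 100L * n
  while (length(seqs) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "could not generate %d distinguishable cyclotides in the mass window after %d tries",
        n, max_tries
      ), class = "cycloscreen_generation_error")
    }
    mob <- runif(1) < config$mobius_fraction
    s <- random_cyclotide(mob, config$messy)
    m <- tryCatch(cyclic_mass(s, 3L), error = function(e) NA_real_)
    if (is.na(m) || m < config$mass_window[1] || m > config$mass_window[2]) next
    rt <- rt_from_sequence(s, config)
    if (any(abs(masses - m) <= guard_mass & abs(rts - rt) <= guard_rt)) next
    if (s %in% seqs) next
    seqs <- c(seqs, s)
    masses <- c(masses, m)
    rts <- c(rts, rt)
    fams <- c(fams, if (mob) "mobius" else "bracelet")
  }
  glyc <- rep(FALSE, n)
  glyc[sample.int(n, round(config$glyco_rate * n))] <- TRUE
  tibble::tibble(
    cyclotide_id = sprintf("cy%04d", seq_len(n)),
    sequence = seqs,
    mass = masses,
    rt_true = rts,
    subfamily = fams,
    glycosylated = glyc
  )
}

#' Assign cyclotides to species
#'
#' Builds the species panel (genus blocks in fixed proportions) and plants
#' the pool: a `shared_fraction` of cyclotides goes to two or more species
#' (the first few being the widespread "common pool" members occupying
#' 50-70% of the `common_genus` block), the rest are placed in exactly one
#' species. Every species receives at least one species-unique cyclotide;
#' species attract detections proportionally to a gamma-distributed
#' expression weight, giving the overdispersed 1-25 per-species counts
#' seen in real screens, capped at `max_per_species`.
#'
#' @param pool Output of [generate_sequences()].
#' @param config A [sim_config()].
#' @return A list with `assignments` (tibble `species`, `cyclotide_id`),
#'   `metadata` (tibble `sample_id`, `species`, `genus`), and
#'   `planted_shared_fraction`.
#' @export
assign_species <- function(pool, config = sim_config()) {
  set.seed(substream_seed(config$seed, "assign"))
  n_sp <- config$n_species
  D <- nrow(pool)
  stopifnot(D >= config$n_species)

  counts <- floor(genus_proportions * n_sp)
  rem <- n_sp - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  genus <- rep(names(counts), counts)
  metadata <- tibble::tibble(
    sample_id = sprintf("smp%03d", seq_len(n_sp)),
    species = sprintf("%s_sp%03d", genus, seq_len(n_sp)),
    genus = genus
  )

  S <- round(config$shared_fraction * D)
  n_common <- min(config$n_common, S)
  U <- D - S
  shared_ids <- pool$cyclotide_id[seq_len(S)]
  unique_ids <- pool$cyclotide_id[S + seq_len(U)]

  w <- stats::rgamma(n_sp, shape = 2.2, rate = 2.2)
  assign <- list()

  # widespread cyclotides in the common-genus block
  block <- which(metadata$genus == config$common_genus)
  if (length(block) == 0L) block <- seq_len(n_sp)
  for (i in seq_len(n_common)) {
    k <- max(2L, round(config$common_prevalence[i] * length(block)))
    sp <- sample(block, min(k, length(block)))
    assign[[length(assign) + 1L]] <-
      tibble::tibble(species_idx = sp, cyclotide_id = shared_ids[i])
  }

  # remaining shared cyclotides: 2 + Poisson extra species each
  if (S > n_common) {
    for (i in (n_common + 1L):S) {
      k <- min(2L + stats::rpois(1, config$extra_share_rate), n_sp)
      sp <- sample.int(n_sp, k, prob = w)
      assign[[length(assign) + 1L]] <-
        tibble::tibble(species_idx = sp, cyclotide_id = shared_ids[i])
    }
  }

  # unique cyclotides: one guaranteed per species, remainder by weight
  u_shuffled <- sample(unique_ids)
  first <- u_shuffled[seq_len(min(n_sp, U))]
  assign[[length(assign) + 1L]] <-
    tibble::tibble(species_idx = seq_along(first), cyclotide_id = first)
  if (U > n_sp) {
    rest <- u_shuffled[(n_sp + 1L):U]
    assign[[length(assign) + 1L]] <- tibble::tibble(
      species_idx = sample.int(n_sp, length(rest), replace = TRUE, prob = w),
      cyclotide_id = rest
    )
  }

  a <- dplyr::bind_rows(assign)

  # cap per-species load by moving surplus unique cyclotides to the
  # least-loaded species
  repeat {
    load <- tabulate(a$species_idx, n_sp)
    over <- which(load > config$max_per_species)
    if (length(over) == 0L) break
    sp <- over[1]
    movable <- which(a$species_idx == sp & a$cyclotide_id %in% unique_ids)
    if (length(movable) == 0L) break
    a$species_idx[movable[1]] <- which.min(load)
  }

  assignments <- tibble::tibble(
    species = metadata$species[a$species_idx],
    cyclotide_id = a$cyclotide_id
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$species, .data$cyclotide_id)

  n_sp_per_cy <- assignments |>
    dplyr::count(.data$cyclotide_id)
  list(
    assignments = assignments,
    metadata = metadata,
    planted_shared_fraction = mean(n_sp_per_cy$n > 1)
  )
}

#' Emit synthetic LC-MS feature tables
#'
#' For every planted species-cyclotide pair, emits one feature per charge
#' state at `m/z = (M + noise + z * 1.00728) / z` (per-feature Gaussian
#' mass noise), a shared retention time (true RT plus one per-detection
#' Gaussian shift), and log-normal intensities. Glycosylated cyclotides
#' additionally emit a hexose satellite (+162.0528 Da) co-eluting with the
#' parent at reduced intensity. Features outside the instrument scan range
#' are dropped; optional uniform noise features are labelled as such in
#' the ground truth.
#'
#' @param assignment Output of [assign_species()].
#' @param pool Output of [generate_sequences()].
#' @param config A [sim_config()].
#' @return A list with `features` (tibble `sample_id`, `mz`, `charge`,
#'   `rt_min`, `intensity`) and `truth_features` (the same rows plus
#'   `cyclotide_id`, `kind` = detection/glycoform/noise, `true_mass`).
#' @export
emit_features <- function(assignment, pool, config = sim_config()) {
  set.seed(substream_seed(config$seed, "emit"))
  pairs <- assignment$assignments |>
    dplyr::left_join(pool, by = "cyclotide_id") |>
    dplyr::left_join(assignment$metadata, by = "species")

  emit_pair <- function(sample_id, cyclotide_id, mass, rt, kind, base_int) {
    z <- config$charge_states
    mz <- (mass + rnorm(length(z), 0, config$mass_noise_sd) +
             z * PROTON_MASS) / z
    tibble::tibble(
      sample_id = sample_id,
      mz = mz,
      charge = as.integer(z),
      rt_min = rt,
      intensity = base_int * exp(rnorm(length(z), 0, 0.3)),
      cyclotide_id = cyclotide_id,
      kind = kind,
      true_mass = mass
    )
  }

  rows <- vector("list", nrow(pairs) * 2L)
  ri <- 0L
  for (i in seq_len(nrow(pairs))) {
    rt_det <- pairs$rt_true[i] + rnorm(1, 0, config$rt_noise_sd)
    base_int <- rlnorm(1, meanlog = log(1e6), sdlog = 1)
    ri <- ri + 1L
    rows[[ri]] <- emit_pair(pairs$sample_id[i], pairs$cyclotide_id[i],
                            pairs$mass[i], rt_det, "detection", base_int)
    if (pairs$glycosylated[i]) {
      ri <- ri + 1L
      rows[[ri]] <- emit_pair(pairs$sample_id[i], pairs$cyclotide_id[i],
                              pairs$mass[i] + HEXOSE_DELTA, rt_det,
                              "glycoform", base_int * config$glyco_intensity)
    }
  }
  truth <- dplyr::bind_rows(rows[seq_len(ri)])

  if (config$noise_features > 0) {
    n_noise <- stats::rpois(nrow(assignment$metadata), config$noise_features)
    noise <- purrr::map_dfr(seq_along(n_noise), function(s) {
      k <- n_noise[s]
      if (k == 0L) return(tibble::tibble())
      tibble::tibble(
        sample_id = assignment$metadata$sample_id[s],
        mz = runif(k, config$mz_range[1], config$mz_range[2]),
        charge = NA_integer_,
        rt_min = runif(k, 5, 65),
        intensity = rlnorm(k, log(1e5), 1),
        cyclotide_id = NA_character_,
        kind = "noise",
        true_mass = NA_real_
      )
    })
    truth <- dplyr::bind_rows(truth, noise)
  }

  truth <- truth |>
    dplyr::filter(.data$mz >= config$mz_range[1],
                  .data$mz <= config$mz_range[2]) |>
    dplyr::arrange(.data$sample_id, .data$rt_min, .data$mz)

  list(
    features = truth[, c("sample_id", "mz", "charge", "rt_min", "intensity")],
    truth_features = truth
  )
}

#' Simulate a complete screen panel
#'
#' Runs [generate_sequences()], [assign_species()] and [emit_features()]
#' under one master seed and bundles features, metadata and ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_panel`: `features`, `metadata`,
#'   `truth_cyclotides`, `truth_assignments`, `truth_features`,
#'   `planted_shared_fraction`, `config`.
#' @export
#' @examples
#' \donttest{
#' panel <- simulate_panel(sim_config(seed = 1, n_species = 20,
#'                                    n_distinct = 80))
#' }
simulate_panel <- function(config = sim_config()) {
  pool <- generate_sequences(config)
  assignment <- assign_species(pool, config)
  emitted <- emit_features(assignment, pool, config)
  structure(list(
    features = emitted$features,
    metadata = assignment$metadata,
    truth_cyclotides = pool,
    truth_assignments = assignment$assignments,
    truth_features = emitted$truth_features,
    planted_shared_fraction = assignment$planted_shared_fraction,
    config = config
  ), class = "simulated_panel")
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf(
    "Simulated screen: %d species, %d planted cyclotides (%.2f shared), %d features\n",
    nrow(x$metadata), nrow(x$truth_cyclotides),
    x$planted_shared_fraction, nrow(x$features)
  ))
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Writes `features.csv`, `metadata.csv`, `truth_cyclotides.csv`,
#' `truth_assignments.csv` and a JSON echo of the configuration.
#'
#' @param panel A `simulated_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(panel$features, file.path(dir, "features.csv"))
  readr::write_csv(panel$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(panel$truth_cyclotides,
                   file.path(dir, "truth_cyclotides.csv"))
  readr::write_csv(panel$truth_assignments,
                   file.path(dir, "truth_assignments.csv"))
  cfg <- panel$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
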