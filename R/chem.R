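# Mass chemistry for cyclic cystine-knot peptides.

# Monoisotopic / average residue masses (Da) and Kyte-Doolittle hydropathy
# for the 20 standard amino acids. Ile and Leu are mass-degenerate; MS
# sequencing cannot distinguish them, so both are accepted on input and
# reported as "L" where a canonical symbol is needed.
.residues <- data.frame(
  code = c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
           "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
  mono_mass = c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841,
                101.04768, 103.00919, 113.08406, 113.08406, 114.04293,
                115.02694, 128.05858, 128.09496, 129.04259, 131.04049,
                137.05891, 147.06841, 156.10111, 163.06333, 186.07931),
  avg_mass = c(57.0519, 71.0788, 87.0782, 97.1167, 99.1326,
               101.1051, 103.1388, 113.1594, 113.1594, 114.1038,
               115.0886, 128.1307, 128.1741, 129.1155, 131.1926,
               137.1411, 147.1766, 156.1875, 163.1760, 186.2132),
  hydropathy = c(-0.4, 1.8, -0.8, -1.6, 4.2, -0.7, 2.5, 3.8, 4.5, -3.5,
                 -3.5, -3.5, -3.9, -3.5, 1.9, -3.2, 2.8, -4.5, -1.3, -0.9),
  stringsAsFactors = FALSE
)

# Registered covalent modifications (monoisotopic delta per event).
.modifications <- data.frame(
  name = c("hexose", "reduction_alkylation", "acetyl", "oxidation",
           "deamidation"),
  mono_delta = c(162.05282, 58.02929, 42.01057, 15.99491, 0.98402),
  scope = c("per-molecule", "per-cysteine", "per-molecule", "per-molecule",
            "per-molecule"),
  typical_count = c(1L, 6L, 2L, 1L, 1L),
  stringsAsFactors = FALSE
)

#' Residue mass and hydropathy table
#'
#' Monoisotopic and average residue (i.e. dehydrated) masses in daltons and
#' Kyte-Doolittle hydropathy indices for the 20 standard amino acids.
#' Leucine and isoleucine are mass-degenerate and share one mass.
#'
#' @return A tibble with columns `code`, `mono_mass`, `avg_mass`,
#'   `hydropathy`.
#' @export
#' @examples
#' residue_masses()
residue_masses <- function() {
  tibble::as_tibble(.residues)
}

#' Registered covalent modifications
#'
#' The modification registry used by [modification_delta()] and
#' [cyclic_mass()]: hexose glycosylation (+162.05 Da), reduction plus
#' carbamidomethylation of cysteine (+58.03 Da per Cys), acetylation
#' (+42.01 Da), methionine/tryptophan oxidation (+15.99 Da) and
#' asparagine/glutamine deamidation (+0.984 Da).
#'
#' @return A tibble with columns `name`, `mono_delta`, `scope`,
#'   `typical_count`.
#' @export
modification_registry <- function() {
  tibble::as_tibble(.modifications)
}

# Strip alignment gaps (ASCII and typographic dashes), fold case, and
# validate residue symbols. Errors name the offending symbol and position.
clean_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(gsub("[-–— ]", "", sequence))
  if (!nzchar(s)) {
    abort("empty peptide sequence", class = "cycloscreen_invalid_sequence")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .residues$code)
  if (length(bad) > 0L) {
    abort(
      sprintf("invalid residue symbol '%s' at position %d", chars[bad[1]], bad[1]),
      class = "cycloscreen_invalid_sequence"
    )
  }
  s
}

residue_mass_sum <- function(sequence, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  col <- if (kind == "mono") "mono_mass" else "avg_mass"
  masses <- setNames(.residues[[col]], .residues$code)
  vapply(strsplit(sequence, "", fixed = TRUE),
         function(ch) sum(masses[ch]), numeric(1))
}

sum_modification_deltas <- function(modifications) {
  if (is.null(modifications) || length(modifications) == 0L) return(0)
  stopifnot(!is.null(names(modifications)))
  sum(vapply(names(modifications),
             function(nm) modification_delta(nm, modifications[[nm]]),
             numeric(1)))
}

#' Monoisotopic or average mass of a head-to-tail cyclic peptide
#'
#' The neutral mass of a backbone-cyclized peptide is the sum of its
#' residue masses (no water term, since the head-to-tail amide bond
#' condenses the terminal water out) minus two hydrogen atoms per
#' disulfide bond, plus any modification deltas. For a canonical cyclotide
#' (six Cys, three disulfides) the disulfide correction is -6.047 Da.
#'
#' @param sequence Character vector of one-letter sequences; alignment
#'   dashes are stripped, case is folded, and `I` is accepted as the mass
#'   equivalent of `L`.
#' @param n_disulfides Number of disulfide bonds (default 3, the cystine
#'   knot). Must satisfy `2 * n_disulfides <= number of Cys`.
#' @param kind `"mono"` (default) or `"avg"`.
#' @param modifications Optional named numeric vector of modification
#'   counts, e.g. `c(hexose = 1)`; names must be in
#'   [modification_registry()].
#' @return Numeric vector of neutral masses in daltons.
#' @seealso [linear_mass()], [modification_delta()]
#' @export
#' @examples
#' # a 30-residue Viola cyclotide with three disulfide bonds
#' cyclic_mass("SCVFLPCLTSALGCSCKSKVCYRNGLPCGE")
cyclic_mass <- function(sequence, n_disulfides = 3L, kind = c("mono", "avg"),
                        modifications = NULL) {
  kind <- match.arg(kind)
  vapply(sequence, function(s) {
    s <- clean_sequence(s)
    n_cys <- stringr::str_count(s, "C")
    if (2L * n_disulfides > n_cys) {
      abort(sprintf(
        "%d disulfides require %d cysteines; sequence has %d",
        n_disulfides, 2L * n_disulfides, n_cys
      ), class = "cycloscreen_invalid_sequence")
    }
    residue_mass_sum(s, kind) -
      2 * n_disulfides * HYDROGEN_MASS +
      sum_modification_deltas(modifications)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mass of a linear peptide
#'
#' Sum of residue masses plus one water (18.01056 Da) for the free
#' termini. Used for protease digestion products of linearized cyclotides.
#'
#' @inheritParams cyclic_mass
#' @return Numeric vector of neutral masses in daltons.
#' @export
#' @examples
#' linear_mass("G") # 75.032
linear_mass <- function(sequence, kind = c("mono", "avg"),
                        modifications = NULL) {
  kind <- match.arg(kind)
  vapply(sequence, function(s) {
    s <- clean_sequence(s)
    residue_mass_sum(s, kind) + WATER_MASS + sum_modification_deltas(modifications)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mass delta of a registered modification
#'
#' @param name Modification name; one of [modification_registry()]`$name`.
#' @param count Number of events (e.g. 6 for alkylation of all six
#'   cyclotide cysteines).
#' @param nominal If `TRUE`, return the nominal (integer, half-up rounded)
#'   delta instead of the exact monoisotopic one, matching how such shifts
#'   are conventionally quoted (348, 162, 84 Da).
#' @return Mass delta in daltons.
#' @export
#' @examples
#' modification_delta("reduction_alkylation", 6) # 348.18
#' modification_delta("hexose", 1, nominal = TRUE) # 162
modification_delta <- function(name, count = 1L, nominal = FALSE) {
  stopifnot(length(name) == 1L, length(count) == 1L, count >= 0)
  i <- match(name, .modifications$name)
  if (is.na(i)) {
    abort(sprintf(
      "unknown modification '%s'; registered: %s",
      name, paste(.modifications$name, collapse = ", ")
    ), class = "cycloscreen_unknown_modification")
  }
  delta <- count * .modifications$mono_delta[i]
  if (nominal) floor(delta + 0.5) else delta
}

#' Convert between neutral mass and m/z
#'
#' Uses the electrospray positive-ion convention \[M + zH\]^z+ with a
#' proton mass of 1.00728 Da.
#'
#' @param mass Neutral monoisotopic mass(es), Da.
#' @param mz Observed mass-to-charge value(s), Th.
#' @param charge Positive integer charge state(s).
#' @return `mz_from_mass()` returns m/z in thomson; `mass_from_mz()` the
#'   neutral mass in daltons.
#' @export
#' @examples
#' mz_from_mass(3307.43, 3) # 1103.48
#' mass_from_mz(1103.48, 3)
mz_from_mass <- function(mass, charge) {
  check_charge(charge)
  stopifnot(all(mass > 0))
  (mass + charge * PROTON_MASS) / charge
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, charge) {
  check_charge(charge)
  stopifnot(all(mz > 0))
  mz * charge - charge * PROTON_MASS
}

check_charge <- function(charge) {
  if (any(!is.finite(charge)) || any(charge < 1) || any(charge != floor(charge))) {
    abort("charge must be a positive integer", class = "cycloscreen_domain_error")
  }
  invisible(charge)
}

#' Canonical rotation of a cyclic sequence
#'
#' Two sequences denote the same head-to-tail cyclic peptide iff one is a
#' rotation of the other. The canonical form is the lexicographically
#' smallest rotation; it is used for identity comparisons only, display
#' keeps the input rotation.
#'
#' @param sequence One-letter sequence(s).
#' @return Character vector of canonical rotations.
#' @export
#' @examples
#' canonical_rotation("GES") == canonical_rotation("ESG")
canonical_rotation <- function(sequence) {
  vapply(sequence, function(s) {
    s <- clean_sequence(s)
    n <- nchar(s)
    rots <- vapply(seq_len(n), function(i) {
      paste0(substr(s, i, n), substr(s, 1, i - 1))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Read peptide sequences from FASTA or CSV
#'
#' FASTA input (requires Biostrings) has alignment dashes stripped and
#' case folded; CSV input must have columns `name`, `sequence` and
#' optionally `species`.
#'
#' @param path Path to a `.fasta`/`.fa` or `.csv` file.
#' @return A tibble with columns `name`, `sequence`, and `species` (NA if
#'   absent).
#' @export
read_peptides <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Biostrings is required to read FASTA input")
    }
    set <- Biostrings::readAAStringSet(path)
    tibble::tibble(
      name = names(set),
      sequence = vapply(as.character(set), clean_sequence, character(1),
                        USE.NAMES = FALSE),
      species = NA_character_
    )
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    missing <- setdiff(c("name", "sequence"), names(df))
    if (length(missing) > 0L) {
      abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            class = "cycloscreen_format_error")
    }
    tibble::tibble(
      name = as.character(df$name),
      sequence = vapply(df$sequence, clean_sequence, character(1),
                        USE.NAMES = FALSE),
      species = if ("species" %in% names(df)) as.character(df$species)
                else NA_character_
    )
  }
}
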