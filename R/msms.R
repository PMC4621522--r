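# In-silico linearization of cyclic peptides, b/y fragment ladders,
# fragment matching, loop decomposition and subfamily classification.

.digest_rules <- list(
  gluc = list(enzyme = "gluc", cleave_after = "E", no_cleave_before = character(0)),
  trypsin = list(enzyme = "trypsin", cleave_after = c("K", "R"),
                 no_cleave_before = "P")
)

#' Protease digestion rule
#'
#' @param enzyme `"gluc"` (cleaves C-terminal to Glu only; the
#'   bicarbonate-buffer specificity used to linearize cyclotides at the
#'   conserved Glu) or `"trypsin"` (after Lys/Arg, not before Pro).
#' @return A list with `enzyme`, `cleave_after`, `no_cleave_before`.
#' @export
digest_rule <- function(enzyme = c("gluc", "trypsin")) {
  .digest_rules[[match.arg(enzyme)]]
}

residue_chars <- function(sequence) strsplit(clean_sequence(sequence), "")[[1]]

# Cys monoisotopic mass adjustment for the reduced + carbamidomethylated
# form on which digestion is computed (the peptide is alkylated before
# digestion; disulfides no longer exist).
alkylation_extra <- function(chars, alkylated) {
  if (alkylated) sum(chars == "C") * ALKYLATION_DELTA else 0
}

#' Digest a cyclic peptide in silico
#'
#' Applies a protease rule to the cyclic sequence: k cleavage sites yield
#' k linear fragments (each gains one water), so the fragment masses sum
#' to the open-chain mass plus k waters. By default masses are computed on
#' the reduced and carbamidomethylated form (each Cys +58.0293 Da),
#' matching how cyclotides are prepared before digestion; set
#' `alkylated = FALSE` for native cysteine masses. Digestion of any
#' rotation of the same cyclic peptide yields the same fragment multiset.
#'
#' @param sequence Cyclic peptide sequence (one-letter codes; dashes
#'   stripped).
#' @param enzyme `"gluc"` or `"trypsin"`, or a rule from [digest_rule()].
#' @param alkylated Compute Cys as carbamidomethyl-Cys (default `TRUE`).
#' @return A tibble with `fragment`, `start` (1-based position in the
#'   input rotation), `length`, `mass` (linear monoisotopic, Da). Zero
#'   cleavage sites return an empty tibble with attribute `uncut = TRUE`.
#' @export
#' @examples
#' digest("SCVFLPCLTSALGCSCKSKVCYRNGLPCGE", "gluc")
digest <- function(sequence, enzyme = "gluc", alkylated = TRUE) {
  rule <- if (is.list(enzyme)) enzyme else digest_rule(enzyme)
  chars <- residue_chars(sequence)
  n <- length(chars)
  nxt <- c(2:n, 1L) # cyclic successor
  sites <- which(chars %in% rule$cleave_after &
                   !chars[nxt] %in% rule$no_cleave_before)
  if (length(sites) == 0L) {
    out <- tibble::tibble(fragment = character(), start = integer(),
                          length = integer(), mass = numeric())
    attr(out, "uncut") <- TRUE
    return(out)
  }
  sites <- sort(sites)
  k <- length(sites)
  frags <- purrr::map_dfr(seq_len(k), function(i) {
    from <- sites[i] %% n + 1L # first residue after the cut
    to <- sites[i %% k + 1L]   # next cut position (inclusive end)
    idx <- if (from <= to) from:to else c(from:n, 1:to)
    fchars <- chars[idx]
    tibble::tibble(
      fragment = paste(fchars, collapse = ""),
      start = from,
      length = length(idx),
      mass = sum(residue_mass_by_code(fchars)) + WATER_MASS +
        alkylation_extra(fchars, alkylated)
    )
  })
  attr(frags, "uncut") <- FALSE
  frags
}

residue_mass_by_code <- function(chars) {
  masses <- setNames(.residues$mono_mass, .residues$code)
  masses[chars]
}

#' Theoretical b/y fragment-ion ladder of a linear peptide
#'
#' Generates the full b and y series for a linear fragment: the neutral b_i
#' mass is the sum of the first i residue masses, the neutral y_j mass the
#' sum of the last j residues plus one water, so that
#' b_i + y_(n-i) equals the linear neutral mass for every i.
#'
#' @param sequence Linear peptide sequence.
#' @param max_charge Highest charge state generated (default 2).
#' @param alkylated Use carbamidomethyl-Cys masses (default `TRUE`).
#' @return A tibble with `series`, `index`, `neutral_mass`, `charge`, `mz`.
#' @export
#' @examples
#' fragment_ladder("GAS", max_charge = 1)
fragment_ladder <- function(sequence, max_charge = 2L, alkylated = TRUE) {
  chars <- residue_chars(sequence)
  n <- length(chars)
  stopifnot(n >= 2L)
  rm <- unname(residue_mass_by_code(chars)) +
    (chars == "C") * (if (alkylated) ALKYLATION_DELTA else 0)
  b <- cumsum(rm)[-n]
  y <- rev(cumsum(rev(rm)))[-1] + WATER_MASS
  ions <- dplyr::bind_rows(
    tibble::tibble(series = "b", index = seq_len(n - 1L), neutral_mass = b),
    tibble::tibble(series = "y", index = rev(seq_len(n - 1L)), neutral_mass = y)
  )
  tidyr::expand_grid(ions, charge = seq_len(max_charge)) |>
    dplyr::mutate(mz = mz_from_mass(.data$neutral_mass, .data$charge)) |>
    dplyr::arrange(.data$series, .data$index, .data$charge)
}

#' Match observed peaks to a candidate sequence's fragment ladder
#'
#' Each observed m/z is matched to the nearest theoretical b/y ion within
#' `tol`. Coverage is the fraction of inter-residue bonds supported by at
#' least one matched ion (bond i is supported by b_i or y_(n-i));
#' unsupported spans are reported, mirroring how poorly fragmenting
#' regions (e.g. a glycosylated loop 5) show up as sequence gaps.
#'
#' @param observed_mz Numeric vector of observed peak m/z values.
#' @param sequence Candidate linear sequence.
#' @param tol Match tolerance, Da (default 0.5).
#' @param max_charge Highest charge considered (default 2).
#' @param alkylated Use carbamidomethyl-Cys masses (default `TRUE`).
#' @return A list of class `fragment_match`: `matches` (tibble of matched
#'   ions), `coverage` (0-1), `n_bonds`, `unsupported` (tibble of
#'   unsupported bond spans).
#' @export
match_fragments <- function(observed_mz, sequence, tol = 0.5,
                            max_charge = 2L, alkylated = TRUE) {
  stopifnot(tol > 0)
  ladder <- fragment_ladder(sequence, max_charge, alkylated)
  n <- nchar(clean_sequence(sequence))
  matches <- purrr::map_dfr(observed_mz, function(mz) {
    d <- abs(ladder$mz - mz)
    k <- which.min(d)
    if (length(k) == 1L && d[k] <= tol) {
      dplyr::mutate(ladder[k, ], observed_mz = mz, error = mz - ladder$mz[k])
    } else {
      tibble::tibble()
    }
  })
  supported <- rep(FALSE, n - 1L)
  if (nrow(matches) > 0L) {
    bond <- ifelse(matches$series == "b", matches$index, n - matches$index)
    supported[unique(bond)] <- TRUE
  }
  runs <- rle(supported)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  unsupported <- tibble::tibble(
    from_bond = starts[!runs$values],
    to_bond = ends[!runs$values]
  )
  structure(list(matches = matches,
                 coverage = mean(supported),
                 n_bonds = n - 1L,
                 unsupported = unsupported),
            class = "fragment_match")
}

#' @export
print.fragment_match <- function(x, ...) {
  cat(sprintf("Fragment match: %.1f%% of %d bonds supported (%d ions)\n",
              100 * x$coverage, x$n_bonds, nrow(x$matches)))
  invisible(x)
}

#' Decompose a cyclotide into its six inter-cysteine loops
#'
#' Cyclotides carry exactly six cysteines; the backbone segments between
#' consecutive cysteines (in cyclic order) are the loops, numbered so that
#' loop 1 is the segment containing the conserved Glu. An anchor Cys can
#' be supplied when the Glu is absent or duplicated.
#'
#' @param sequence Cyclotide sequence (exactly 6 Cys; dashes stripped).
#' @param anchor Optional integer in 1..6: which inter-cysteine segment
#'   (in input order) is loop 1, overriding the Glu rule.
#' @return A tibble with columns `loop` (1-6), `sequence`, `after_cys`
#'   (index of the Cys opening the loop in the input rotation), plus
#'   attribute `cys_positions`.
#' @export
#' @examples
#' parse_loops("SCVFLPCLTSALGCSCKSKVCYRNGLPCGE")
parse_loops <- function(sequence, anchor = NULL) {
  chars <- residue_chars(sequence)
  n <- length(chars)
  cys <- which(chars == "C")
  if (length(cys) != 6L) {
    abort(sprintf("cyclotide must have exactly 6 Cys (found %d)", length(cys)),
          class = "cycloscreen_invalid_sequence")
  }
  segs <- purrr::map(seq_len(6L), function(i) {
    from <- cys[i]
    to <- cys[i %% 6L + 1L]
    idx <- if (from < to) {
      if (to - from > 1L) (from + 1L):(to - 1L) else integer(0)
    } else {
      c(if (from < n) (from + 1L):n else integer(0),
        if (to > 1L) 1L:(to - 1L) else integer(0))
    }
    list(seq = paste(chars[idx], collapse = ""), after_cys = from)
  })
  seq_txt <- vapply(segs, `[[`, character(1), "seq")
  if (is.null(anchor)) {
    has_glu <- grepl("E", seq_txt, fixed = TRUE)
    if (sum(has_glu) != 1L) {
      abort(sprintf(
        "%d loops contain Glu; cannot anchor loop 1 (supply `anchor`)",
        sum(has_glu)
      ), class = "cycloscreen_ambiguous_anchor")
    }
    anchor <- which(has_glu)
  }
  stopifnot(anchor %in% 1:6)
  order6 <- ((anchor - 1L) + 0:5) %% 6L + 1L
  out <- tibble::tibble(
    loop = 1:6,
    sequence = seq_txt[order6],
    after_cys = vapply(segs, `[[`, numeric(1), "after_cys")[order6]
  )
  attr(out, "cys_positions") <- cys
  attr(out, "input_sequence") <- paste(chars, collapse = "")
  out
}

#' Reassemble a cyclotide sequence from its loop decomposition
#'
#' Inverse of [parse_loops()] up to rotation: the cyclic sequence
#' `C + loop2 + C + loop3 + ... + C + loop1` is returned starting at the
#' Cys that opens loop 2, and equals the input sequence as a cyclic word.
#'
#' @param loops A tibble from [parse_loops()].
#' @return A single sequence string.
#' @export
reassemble_loops <- function(loops) {
  stopifnot(nrow(loops) == 6L)
  ord <- c(2:6, 1)
  paste0(paste0("C", loops$sequence[match(ord, loops$loop)], collapse = ""))
}

#' Classify a cyclotide subfamily from its loop 5
#'
#' The Mobius subfamily carries a conserved cis-Pro in loop 5 immediately
#' preceded by an aromatic residue (W/F/Y); bracelet cyclotides carry no
#' Pro in loop 5; everything else (e.g. a Pro without a preceding
#' aromatic) is atypical.
#'
#' @param x A sequence string or a loop decomposition from [parse_loops()].
#' @return `"mobius"`, `"bracelet"`, or `"atypical"`.
#' @export
#' @examples
#' classify_subfamily("TCTLGTCNTPGCTCSWPLCTKNGLPTCGE") # mobius (SWPL loop 5)
classify_subfamily <- function(x) {
  loops <- if (is.character(x)) parse_loops(x) else x
  loop5 <- loops$sequence[loops$loop == 5L]
  if (!grepl("P", loop5, fixed = TRUE)) return("bracelet")
  if (grepl("[WFY]P", loop5)) return("mobius")
  "atypical"
}
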