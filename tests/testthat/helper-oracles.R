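# Independent oracles used across the suite.

# Per-residue monoisotopic masses re-stated independently of the package's
# internal table (values from the standard amino-acid residue mass list).
oracle_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

oracle_cyclic_mass <- function(s, n_ss = 3) {
  sum(oracle_mono[strsplit(gsub("-", "", s), "")[[1]]]) - n_ss * 2 * 1.00783
}

random_sequence <- function(len, alphabet = names(oracle_mono)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- ((k - 1) %% n) + 1
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# Brute-force connected components over the pairwise dedup criterion
# (|dmass| <= mass_tol AND |drt| <= rt_tol), via boolean transitive closure.
oracle_components <- function(mass, rt, mass_tol, rt_tol) {
  n <- length(mass)
  adj <- outer(mass, mass, function(a, b) abs(a - b) <= mass_tol) &
    outer(rt, rt, function(a, b) abs(a - b) <= rt_tol)
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
    }
  }
  comp
}

# Naive UPGMA (direct matrix agglomeration) as an independent oracle;
# returns the ultrametric cophenetic matrix it implies.
oracle_upgma_cophenetic <- function(d) {
  dm <- as.matrix(d)
  labs <- rownames(dm)
  n <- length(labs)
  members <- as.list(labs)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- seq_len(n)
  sizes <- rep(1, n)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          dd <- dm[active[a], active[b]]
          if (dd < bestd - 1e-12) {
            bestd <- dd
            best <- c(a, b)
          }
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    for (x in members[[i]]) for (y in members[[j]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    # average-linkage update into slot i
    for (k in active) {
      if (k != i && k != j) {
        dm[i, k] <- dm[k, i] <-
          (dm[i, k] * sizes[i] + dm[j, k] * sizes[j]) / (sizes[i] + sizes[j])
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, active[best[2]])
  }
  coph
}

# Patristic (tip-to-tip) distances implied by a 4-taxon unrooted tree with
# a given split and branch lengths; used to build additive test matrices.
additive_matrix_4taxa <- function(labels, ext, internal) {
  stopifnot(length(labels) == 4, length(ext) == 4)
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d[1, 2] <- ext[1] + ext[2]
  d[3, 4] <- ext[3] + ext[4]
  for (i in 1:2) for (j in 3:4) d[i, j] <- ext[i] + ext[j] + internal
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

small_panel_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_species = 25L, n_distinct = 120L, ...)
}
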