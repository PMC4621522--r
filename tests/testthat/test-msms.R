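vide_a <- "SCVFLPCLTSALGCSCKSKVCYRNGLPCGE"

test_that("GluC linearizes a one-Glu cyclotide into a single fragment", {
  d <- digest(vide_a, "gluc")
  expect_equal(nrow(d), 1)
  # fragment starts immediately after the Glu
  expect_true(startsWith(d$fragment, "SCVFL"))
  expect_equal(nchar(d$fragment), nchar(vide_a))
  # mass = open-chain alkylated mass + one water
  expected <- cyclic_mass(vide_a, 0) +
    modification_delta("reduction_alkylation", 6) + 18.01056
  expect_equal(d$mass, expected, tolerance = 1e-9)
})

test_that("trypsin cleaves after K/R except before Pro", {
  d <- digest(vide_a, "trypsin")
  expect_equal(nrow(d), 3) # K17, K19, R23 cut; R in YRNGLP? R24 -> before N cuts
  expect_setequal(d$fragment, c("SK", "VCYR", "NGLPCGESCVFLPCLTSALGCSCK"))
  # no cleavage of K/R-P bonds: only the R cuts, K precedes Pro
  d2 <- digest("GKPGGRG", "trypsin", alkylated = FALSE)
  expect_setequal(d2$fragment, "GGKPGGR")
})

test_that("a Glu-free peptide is uncut by GluC", {
  d <- digest("GGCGGCGGCGGCGGCGGC", "gluc")
  expect_equal(nrow(d), 0)
  expect_true(attr(d, "uncut"))
})

test_that("digestion conserves mass for random cyclic peptides", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_sequence(sample(8:40, 1))
    rule <- sample(c("gluc", "trypsin"), 1)
    d <- digest(s, rule)
    k <- nrow(d)
    if (k == 0) next
    n_cys <- sum(strsplit(s, "")[[1]] == "C")
    parent <- cyclic_mass(s, 0) + modification_delta("reduction_alkylation", n_cys)
    expect_equal(sum(d$mass) - k * 18.01056, parent, tolerance = 1e-9)
  }
})

test_that("digestion is invariant under rotation of the cyclic peptide", {
  set.seed(32)
  for (i in 1:25) {
    s <- random_sequence(25)
    d0 <- digest(s, "trypsin")
    if (nrow(d0) == 0) next
    for (k in sample(24, 3)) {
      dk <- digest(rotate_seq(s, k), "trypsin")
      expect_setequal(dk$fragment, d0$fragment)
      expect_equal(sort(dk$mass), sort(d0$mass), tolerance = 1e-9)
    }
  }
})

test_that("b/y ladders are complementary and match hand-derived ions", {
  # b1 of G... at 1+ and y1 of ...E at 1+
  lad <- fragment_ladder("GASE", max_charge = 1, alkylated = FALSE)
  b1 <- lad$mz[lad$series == "b" & lad$index == 1 & lad$charge == 1]
  y1 <- lad$mz[lad$series == "y" & lad$index == 1 & lad$charge == 1]
  expect_equal(b1, 57.02146 + 1.00728, tolerance = 1e-5)
  expect_equal(y1, 129.04259 + 18.01056 + 1.00728, tolerance = 1e-5)
  # complementarity for random peptides: b_i + y_(n-i) = linear mass
  set.seed(33)
  for (i in 1:50) {
    s <- random_sequence(sample(4:25, 1))
    lad <- fragment_ladder(s, max_charge = 2)
    n <- nchar(s)
    M <- linear_mass(s) +
      modification_delta("reduction_alkylation",
                         sum(strsplit(s, "")[[1]] == "C"))
    b <- lad[lad$series == "b" & lad$charge == 1, ]
    y <- lad[lad$series == "y" & lad$charge == 1, ]
    for (j in seq_len(n - 1)) {
      expect_equal(b$neutral_mass[b$index == j] +
                     y$neutral_mass[y$index == n - j],
                   M, tolerance = 1e-9)
    }
  }
})

test_that("fragment matching reports coverage and unsupported spans", {
  s <- "GASELVK"
  lad <- fragment_ladder(s, max_charge = 2)
  full <- match_fragments(lad$mz, s, tol = 0.01)
  expect_equal(full$coverage, 1)
  empty <- match_fragments(numeric(0), s)
  expect_equal(empty$coverage, 0)
  expect_equal(empty$unsupported$from_bond, 1)
  expect_equal(empty$unsupported$to_bond, nchar(s) - 1)
  # b-ions for the first half only -> coverage = bonds 1..3 of 6
  half <- lad[lad$series == "b" & lad$index <= 3 & lad$charge == 1, ]
  res <- match_fragments(half$mz, s, tol = 0.01, max_charge = 1)
  expect_equal(res$coverage, 3 / 6)
  expect_equal(res$unsupported$from_bond, 4)
})

test_that("loop parsing anchors loop 1 at the conserved Glu", {
  ref <- violaceae_cyclotides()
  get_loop5 <- function(nm) {
    loops <- parse_loops(ref$sequence[ref$name == nm])
    loops$sequence[loops$loop == 5]
  }
  expect_equal(get_loop5("vide A"), "KSKV")
  expect_equal(get_loop5("mema A"), "KDKV")
  expect_equal(get_loop5("hyde A"), "GSTVPL")
  expect_error(parse_loops("GGCGGCGGCGGCGGCGGC"),
               class = "cycloscreen_ambiguous_anchor")
  # explicit anchor overrides
  loops <- parse_loops("GGCGGCGGCGGCGGCGGC", anchor = 1)
  expect_equal(nrow(loops), 6)
})

test_that("parse then reassemble is the identity up to rotation", {
  ref <- violaceae_cyclotides()
  # rigra A carries a Glu in an inner loop as well as the conserved one:
  # anchoring is genuinely ambiguous and needs an explicit anchor
  rigra <- ref$sequence[ref$name == "rigra A"]
  expect_error(parse_loops(rigra), class = "cycloscreen_ambiguous_anchor")
  s2 <- reassemble_loops(parse_loops(rigra, anchor = 6))
  expect_equal(canonical_rotation(s2), canonical_rotation(gsub("-", "", rigra)))
  for (s in ref$sequence[ref$name != "rigra A"]) {
    s2 <- reassemble_loops(parse_loops(s))
    expect_equal(canonical_rotation(s2),
                 canonical_rotation(gsub("-", "", s)))
  }
})

test_that("subfamily classification follows the loop-5 rule", {
  ref <- violaceae_cyclotides()
  cls <- function(nm) classify_subfamily(ref$sequence[ref$name == nm])
  expect_equal(cls("hobo A"), "mobius")    # SWPL
  expect_equal(cls("glopa F"), "bracelet") # KNKV
  expect_equal(cls("hyde A"), "atypical")  # GSTVPL: Pro without aromatic
})
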