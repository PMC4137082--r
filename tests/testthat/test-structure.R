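test_that("progressive alignment of identical sequences is gapless", {
  aln <- progressive_align(c(a = "ACGUACGUAA", b = "ACGUACGUAA"))
  expect_equal(unname(aln$rows), rep("ACGUACGUAA", 2))
  expect_s3_class(aln$guide_tree, "phylo")
  expect_error(progressive_align(c(a = "", b = "ACGU")), "zero-length")
  expect_warning(progressive_align(c(a = "ACGU")), "single sequence")
})

test_that("low-divergence families realign to their true columns", {
  fam <- evolve_family(family_spec(n_taxa = 10, sub_rate = 0.15, seed = 21))
  aln <- progressive_align(fam$sequences)
  # map each true column through two different rows; homologous
  # positions must land in the same alignment column
  leaves <- names(fam$sequences)[1:2]
  agree <- 0L; total <- 0L
  for (root_col in seq(1, 136, by = 3)) {
    cols <- vapply(leaves, function(lf) {
      k <- match(root_col, fam$truth$column_map[[lf]])
      if (is.na(k)) return(NA_integer_)
      as.integer(column_of_position(aln, lf, k))
    }, integer(1))
    if (any(is.na(cols))) next
    total <- total + 1L
    agree <- agree + (length(unique(cols)) == 1L)
  }
  expect_gte(agree / total, 0.9)
})

test_that("GSC weights match the hand-computed caterpillar example", {
  tree <- ape::read.tree(text = "((A:2,B:2):1,C:3);")
  aln <- rna_alignment(c(A = "ACGUA", B = "ACGUA", C = "ACGUA"))
  wa <- gsc_weights(aln, tree)
  # A = B = 2 + 1/2 = 2.5, C = 3; total 8
  expect_equal(unname(wa$weights[c("A", "B", "C")]),
               c(0.3125, 0.3125, 0.375))
  expect_equal(sum(wa$weights), 1)
})

test_that("GSC degenerate cases: star symmetry and zero-length trees", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  aln <- rna_alignment(setNames(rep("ACGUA", 4), c("A", "B", "C", "D")))
  wa <- gsc_weights(aln, star)
  expect_equal(unname(wa$weights), rep(0.25, 4))
  # zero total length -> uniform
  zero <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  aln3 <- rna_alignment(setNames(rep("ACGUA", 3), c("A", "B", "C")))
  expect_equal(unname(gsc_weights(aln3, zero)$weights), rep(1 / 3, 3))
  # duplicate rows as a zero-length cherry get equal weights
  cherry <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  wch <- gsc_weights(aln3, cherry)$weights
  expect_equal(wch[["A"]], wch[["B"]])
})

test_that("lengthening a pendant branch never decreases its leaf weight", {
  aln <- rna_alignment(setNames(rep("ACGUA", 3), c("A", "B", "C")))
  prev <- -Inf
  for (len in c(0.5, 1, 2, 4, 8)) {
    tree <- ape::read.tree(
      text = sprintf("((A:%g,B:1):1,C:2);", len))
    w <- gsc_weights(aln, tree)$weights[["A"]]
    expect_gte(w, prev)
    prev <- w
  }
})

test_that("pair_score reproduces the analytic extremes", {
  # perfectly anticorrelated canonical pairs, uniform: MI = 2 bits
  rows <- c(r1 = "GAAAC", r2 = "CAAAG", r3 = "AAAAU", r4 = "UAAAA")
  wa <- weighted_alignment(rna_alignment(rows))
  ev <- pair_score(wa, 1, 5)
  expect_equal(ev$mi, 2)
  expect_equal(ev$class, "covarying")
  expect_equal(ev$canonical_fraction, 1)
  # constant complementary columns: MI = 0, conserved
  rows2 <- c(r1 = "GAAAC", r2 = "GAAAC", r3 = "GAAAC")
  wa2 <- weighted_alignment(rna_alignment(rows2))
  ev2 <- pair_score(wa2, 1, 5)
  expect_equal(ev2$mi, 0)
  expect_equal(ev2$class, "conserved")
  # all-gap column is rejected with a -Inf sentinel
  rows3 <- c(r1 = "-AAAC", r2 = "-AAAG", r3 = "-AAAU")
  wa3 <- weighted_alignment(rna_alignment(rows3))
  ev3 <- pair_score(wa3, 1, 5)
  expect_equal(ev3$class, "rejected")
  expect_equal(ev3$score, -Inf)
  # hairpin constraint enforced
  expect_error(pair_score(wa, 1, 4), "hairpin")
})

test_that("pair_score equals brute-force row-pair enumeration", {
  rows <- c(r1 = "GAAAAC", r2 = "CAAAAG", r3 = "GAAAAU",
            r4 = "AAAAAU", r5 = "G-AAAC", r6 = "CAAAAC")
  w <- c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1)
  wa <- weighted_alignment(rna_alignment(rows), weights = w)
  ev <- pair_score(wa, 1, 6, phi = 1.0)

  # independent enumeration over ordered row pairs
  canon <- c(AU = "14", UA = "41", CG = "23", GC = "32", GU = "34",
             UG = "43")
  code <- function(ch) match(ch, c("A", "C", "G", "U", "-"))
  ci <- vapply(rows, function(r) code(substr(r, 1, 1)), 1L)
  cj <- vapply(rows, function(r) code(substr(r, 6, 6)), 1L)
  key <- paste0(ci, cj)
  types <- match(key, canon)
  cov <- 0
  for (a in 1:6) for (b in 1:6) {
    if (is.na(types[a]) || is.na(types[b])) next
    ta <- strsplit(names(canon)[types[a]], "")[[1]]
    tb <- strsplit(names(canon)[types[b]], "")[[1]]
    cov <- cov + w[a] * w[b] * sum(ta != tb)
  }
  inc <- sum(w[is.na(types)])
  expect_equal(ev$score, cov - inc, tolerance = 1e-12)
  expect_equal(ev$canonical_fraction, 1 - inc, tolerance = 1e-12)
})

test_that("MI is non-negative and zero for constant columns", {
  set.seed(31)
  for (rep in 1:20) {
    wa <- weighted_alignment(random_alignment(6, 8))
    ev <- pair_score(wa, sample(1:3, 1), sample(7:8, 1))
    expect_gte(ev$mi, 0)
  }
  rows <- c(r1 = "AAAAAC", r2 = "AAAAAG", r3 = "AAAAAU")
  wa <- weighted_alignment(rna_alignment(rows))
  expect_equal(pair_score(wa, 1, 6)$mi, 0)
})

test_that("folding equals exhaustive enumeration on small alignments", {
  set.seed(32)
  for (rep in 1:60) {
    n_rows <- sample(3:6, 1)
    n_cols <- sample(5:12, 1)
    wa <- weighted_alignment(random_alignment(n_rows, n_cols))
    st <- fold_alignment(wa, tau = 0.05, min_helix = 1L)
    S <- score_matrix(wa, tau = 0.05)
    expect_equal(structure_score(st), brute_force_fold(S, 0.05),
                 tolerance = 1e-9,
                 label = sprintf("rep %d (%dx%d)", rep, n_rows, n_cols))
  }
})

test_that("degenerate alignments fold to valid empty structures", {
  wa <- weighted_alignment(rna_alignment(
    c(r1 = "AAAAAAAAAA", r2 = "AAAAAAAAAA")))
  st <- fold_alignment(wa)
  expect_equal(nrow(st$pairs), 0L)
  expect_equal(nrow(st$helices), 0L)
  expect_equal(structure_score(st), 0)
})

test_that("planted covarying stems are recovered from synthetic families", {
  fam <- evolve_family(family_spec(n_taxa = 14, seed = 33))
  aln <- progressive_align(fam$sequences)
  wa <- gsc_weights(aln)
  st <- fold_alignment(wa)
  leaf <- names(fam$sequences)[1]
  cmap <- fam$truth$column_map[[leaf]]
  pi <- column_of_position(aln, leaf, match(fam$truth$pairs$i, cmap))
  pj <- column_of_position(aln, leaf, match(fam$truth$pairs$j, cmap))
  found <- paste(st$pairs$i, st$pairs$j)
  expect_gte(mean(paste(pi, pj) %in% found), 0.8)
  expect_gte(nrow(st$helices), 3L)
})

test_that("folded score is invariant to row permutation and duplication", {
  fam <- evolve_family(family_spec(n_taxa = 8, seed = 34))
  aln <- progressive_align(fam$sequences)
  wa <- gsc_weights(aln)
  total <- structure_score(fold_alignment(wa))
  # permutation
  set.seed(35)
  perm <- sample(length(aln$rows))
  aln_p <- rna_alignment(aln$rows[perm])
  wa_p <- weighted_alignment(aln_p, weights = unname(wa$weights[perm]))
  expect_equal(structure_score(fold_alignment(wa_p)), total,
               tolerance = 1e-9)
  # duplicating a row with its weight split in half
  rows_d <- c(aln$rows, dup = unname(aln$rows[1]))
  w_d <- unname(c(wa$weights, wa$weights[1] / 2))
  w_d[1] <- w_d[1] / 2
  wa_d <- weighted_alignment(rna_alignment(rows_d), weights = w_d)
  expect_equal(structure_score(fold_alignment(wa_d)), total,
               tolerance = 1e-9)
})

test_that("pseudoknot merging keeps crossing pairs on a second tier", {
  mk_struct <- function(pairs_ij, L = 30L) {
    S <- matrix(-Inf, L, L)
    info <- list()
    for (k in seq_len(nrow(pairs_ij))) {
      info[[paste(pairs_ij[k, 1], pairs_ij[k, 2])]] <-
        list(score = 1, mi = 0.5, class = "covarying",
             canonical_fraction = 1)
    }
    leaderscout:::structure_from_pairs(pairs_ij, info, L, min_helix = 1L)
  }
  # kissing-loop topology: hairpin (5..15) and loop-loop helix (9..22)
  a <- mk_struct(cbind(i = c(5L, 6L), j = c(15L, 14L)))
  b <- mk_struct(cbind(i = c(9L, 10L), j = c(22L, 21L)))
  m1 <- merge_pseudoknot(a, b)
  expect_setequal(m1$pairs$tier, c(1L, 2L))
  expect_equal(sum(m1$pairs$tier == 2L), 2L)
  expect_equal(nrow(m1$pairs), 4L)      # no pair deleted
  # stable under argument swap
  m2 <- merge_pseudoknot(b, a)
  expect_equal(m1$pairs[order(m1$pairs$i), ],
               m2$pairs[order(m2$pairs$i), ])
  # non-crossing union stays single-tier
  c1 <- mk_struct(cbind(i = c(5L, 6L), j = c(15L, 14L)))
  c2 <- mk_struct(cbind(i = c(18L, 19L), j = c(28L, 27L)))
  expect_true(all(merge_pseudoknot(c1, c2)$pairs$tier == 1L))
  # same column in both structures is a conflict
  d <- mk_struct(cbind(i = 5L, j = 15L))
  expect_error(merge_pseudoknot(a, d), "conflict")
})
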