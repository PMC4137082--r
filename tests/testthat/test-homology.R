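test_that("profile frequencies follow the Laplace pseudocount arithmetic", {
  wa <- weighted_alignment(rna_alignment(c(r1 = "ACGUU")))
  prof <- build_profile(wa, alpha = 0.5)
  # single row: column A frequency (1 + 0.5) / (1 + 2) = 0.5
  expect_equal(unname(prof$p["A", 1]), 0.5)
  expect_equal(unname(prof$p["C", 1]), 0.5 / 3)
  expect_equal(colSums(prof$p), rep(1, 5), ignore_attr = TRUE)
  # alpha = 0 with a unanimous column gives frequency 1
  wa2 <- weighted_alignment(rna_alignment(c(r1 = "ACGUU", r2 = "ACGUU")))
  prof2 <- build_profile(wa2, alpha = 0)
  expect_equal(unname(prof2$p["A", 1]), 1)
  # an empty alignment cannot be profiled
  expect_error(rna_alignment(character(0)))
})

test_that("uniform random alignments converge to background frequencies", {
  set.seed(41)
  wa <- weighted_alignment(random_alignment(200, 30))
  prof <- build_profile(wa, alpha = 0.5)
  # per-nucleotide mean over columns settles on the background; single
  # cells still carry binomial noise (sd ~ 0.031 at 200 rows)
  expect_true(all(abs(rowMeans(prof$p) - 0.25) < 0.02))
  expect_true(all(abs(prof$p - 0.25) < 5 * sqrt(0.25 * 0.75 / 200)))
})

test_that("scanning finds a planted motif on either strand", {
  fam <- evolve_family(family_spec(n_taxa = 8, seed = 42))
  aln <- progressive_align(fam$sequences[1:5])
  wa <- gsc_weights(aln)
  prof <- build_profile(wa, fold_alignment(wa))
  set.seed(43)
  bg <- random_seq(1500)
  planted <- leaderscout:::rna_to_dna(fam$sequences[[7]])
  genome <- paste0(substr(bg, 1, 800), planted, substr(bg, 801, 1500))
  hits <- scan_genome(prof, genome)
  expect_gt(nrow(hits), 0L)
  expect_equal(hits$strand[1], "+")
  expect_lt(abs(hits$start0[1] - 800), 5)
  # reverse complement: same top score on the minus strand
  hits_rc <- scan_genome(prof, leaderscout:::revcomp_chr(genome))
  expect_equal(hits_rc$raw_score[1], hits$raw_score[1], tolerance = 1e-9)
  expect_equal(hits_rc$strand[1], "-")
  # an all-N genome yields no hits
  expect_equal(nrow(scan_genome(prof, strrep("N", 1000))), 0L)
})

test_that("the profile consensus is locally optimal under the scan score", {
  fam <- evolve_family(family_spec(n_taxa = 8, seed = 44))
  aln <- progressive_align(fam$sequences[1:5])
  wa <- gsc_weights(aln)
  prof <- build_profile(wa, fold_alignment(wa))
  cons <- leaderscout:::rna_to_dna(prof$consensus)
  base_score <- scan_genome(prof, cons, both_strands = FALSE)$raw_score[1]
  set.seed(45)
  for (rep in 1:10) {
    pos <- sample(nchar(cons), 1)
    orig <- substr(cons, pos, pos)
    sub <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
    mutant <- paste0(substr(cons, 1, pos - 1), sub,
                     substr(cons, pos + 1, nchar(cons)))
    ms <- scan_genome(prof, mutant, both_strands = FALSE)$raw_score[1]
    expect_lte(ms, base_score + 1e-9)
  }
})

test_that("method-of-moments recovers known Gumbel parameters", {
  set.seed(46)
  scores <- rgumbel(2000, mu = 5, lambda = 0.7)
  fit <- fit_gumbel(scores)
  expect_lt(abs(fit$mu - 5), 0.2)
  expect_lt(abs(fit$lambda - 0.7), 0.05)
  # invariant to sample order
  fit2 <- fit_gumbel(sample(scores))
  expect_equal(fit2$mu, fit$mu)
  expect_equal(fit2$lambda, fit$lambda)
  # degenerate variance is an error
  expect_error(fit_gumbel(rep(3, 100)), "degenerate")
})

test_that("E-values are monotone decreasing in score, E(mu) = N_eff", {
  cal <- list(mu = 10, lambda = 0.5, n_eff = 40)
  hits <- data.frame(genome_id = "g", start0 = c(0, 10, 20),
                     end0 = c(5, 15, 25), strand = "+",
                     raw_score = c(12, 10, 8), evalue = NA_real_,
                     aligned = "AC")
  ann <- assign_evalues(hits, cal)
  expect_true(all(diff(ann$evalue[order(-ann$raw_score)]) > 0))
  expect_equal(ann$evalue[ann$raw_score == 10], 40)
})

test_that("calibrated planted hits get E << 1, decoys E around 1", {
  fam <- evolve_family(family_spec(n_taxa = 8, seed = 47))
  aln <- progressive_align(fam$sequences[1:5])
  wa <- gsc_weights(aln)
  prof <- build_profile(wa, fold_alignment(wa))
  set.seed(48)
  bg <- random_seq(1200)
  genome <- paste0(substr(bg, 1, 600),
                   leaderscout:::rna_to_dna(fam$sequences[[8]]),
                   substr(bg, 601, 1200))
  cal <- calibrate_evalues(prof, list(genome), n_shuffles = 8, seed = 49)
  expect_lt(cal$hits$evalue[1], 1e-4)
  if (nrow(cal$hits) > 1L) {
    expect_gt(cal$hits$evalue[2], 0.01)
  }
})

test_that("dinucleotide shuffles preserve dinucleotide counts", {
  set.seed(50)
  x <- random_seq(400)
  dinuc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(table(paste0(ch[-length(ch)], ch[-1])))
  }
  y <- dinucleotide_shuffle(x)
  expect_equal(dinuc(y), dinuc(x))
  expect_equal(nchar(y), nchar(x))
  expect_false(y == x)   # astronomically unlikely to be identical
})

test_that("iterative expansion recruits a held-out subfamily", {
  fam <- evolve_family(family_spec(n_taxa = 12, seed = 5))
  pl <- plant_genomes(fam, seed = 6)
  aln <- progressive_align(fam$sequences[1:6])
  wa <- gsc_weights(aln)
  st <- fold_alignment(wa)
  grown <- expand_iterate(wa, st, pl$genomes[7:12], rounds = 3,
                          n_shuffles = 6, seed = 11)
  expect_gte(sum(grown$provenance > 0), 5L)
  expect_equal(sum(grown$provenance == 0), 6L)   # seed rows kept
  # an impossible cutoff leaves the alignment unchanged
  same <- expand_iterate(wa, st, pl$genomes[7:8], e_cutoff = 0,
                         rounds = 1, n_shuffles = 4, seed = 12)
  expect_equal(length(same$alignment$rows), 6L)
  # convergence is a fixed point: re-searching the same genomes adds
  # nothing new
  again <- expand_iterate(grown, st, pl$genomes[7:12], rounds = 1,
                          n_shuffles = 6, seed = 11)
  expect_equal(length(again$alignment$rows),
               length(grown$alignment$rows))
})
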