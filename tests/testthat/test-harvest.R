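test_that("locate_gene finds annotated genes and reports ambiguity", {
  set.seed(4)
  paths <- write_toy_genome(random_seq(1000), toy_features(
    list("rpsO", 601, 900, "+"),
    list("yabA", 101, 300, "+")
  ))
  g <- read_genome(paths$fasta, paths$gff)
  hit <- locate_gene(g, "rpsO")
  expect_equal(hit$start, 601L)
  expect_equal(hit$end, 900L)
  # duplicate name at different loci is ambiguous
  paths2 <- write_toy_genome(random_seq(1000), toy_features(
    list("rpsO", 101, 200, "+"),
    list("rpsO", 501, 600, "+")
  ), id = "TOY2")
  g2 <- read_genome(paths2$fasta, paths2$gff)
  expect_error(locate_gene(g2, "rpsO"), "ambiguous")
  expect_error(locate_gene(g2, "missing"), "not found")
})

test_that("translated six-frame fallback recovers a planted ORF", {
  fam <- evolve_family(family_spec(n_taxa = 3, seed = 6))
  pl <- plant_genomes(fam, seed = 7)
  g <- pl$genomes[[1]]
  cds_feat <- g$features[g$features$name == "rpsO", ]
  # strip the annotation, query with the translated planted protein
  cds_dna <- if (cds_feat$strand == "+") {
    substr(g$record$sequence, cds_feat$start, cds_feat$end)
  } else {
    leaderscout:::revcomp_chr(substr(g$record$sequence, cds_feat$start,
                                     cds_feat$end))
  }
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_dna, 1, nchar(cds_dna) - 3))
  ))
  g_un <- g
  g_un$features <- g$features[0, ]
  hit <- locate_gene(g_un, "rpsO", query_protein = protein)
  expect_equal(hit$start, cds_feat$start)
  expect_equal(hit$end, cds_feat$end)
  expect_equal(hit$strand, cds_feat$strand)
  # an all-N genome has no translated hit
  g_n <- g_un
  g_n$record$sequence <- strrep("N", 2000)
  expect_error(locate_gene(g_n, "rpsO", query_protein = protein),
               "no translated hit")
})

test_that("leader length is min(gap, upstream_max) + coding tail", {
  set.seed(8)
  seq <- random_seq(2000)
  # previous gene ends 300 nt upstream of the start at 1001
  paths <- write_toy_genome(seq, toy_features(
    list("prev", 501, 700, "+"),
    list("rpsO", 1001, 1600, "+")
  ))
  g <- read_genome(paths$fasta, paths$gff)
  ld <- extract_leader(g, locate_gene(g, "rpsO"))
  expect_equal(nchar(ld$sequence), 300L + 25L)
  expect_false(ld$truncated)
  # no previous gene within 500 -> capped at 500 + 25
  paths2 <- write_toy_genome(seq, toy_features(
    list("rpsO", 1001, 1600, "+")
  ), id = "TOY2")
  g2 <- read_genome(paths2$fasta, paths2$gff)
  ld2 <- extract_leader(g2, locate_gene(g2, "rpsO"))
  expect_equal(nchar(ld2$sequence), 525L)
  # abutting previous gene -> coding tail only, flagged
  paths3 <- write_toy_genome(seq, toy_features(
    list("prev", 501, 1000, "+"),
    list("rpsO", 1001, 1600, "+")
  ), id = "TOY3")
  g3 <- read_genome(paths3$fasta, paths3$gff)
  ld3 <- extract_leader(g3, locate_gene(g3, "rpsO"))
  expect_equal(nchar(ld3$sequence), 25L)
  expect_true(ld3$truncated)
  expect_equal(ld3$offset_of_start_codon, 0L)
})

test_that("the upstream boundary is strand-agnostic", {
  set.seed(9)
  seq <- random_seq(2000)
  # minus-strand neighbour still bounds the upstream window
  paths <- write_toy_genome(seq, toy_features(
    list("prev", 501, 850, "-"),
    list("rpsO", 1001, 1600, "+")
  ))
  g <- read_genome(paths$fasta, paths$gff)
  ld <- extract_leader(g, locate_gene(g, "rpsO"))
  expect_equal(nchar(ld$sequence), 150L + 25L)
})

test_that("extracted leaders map back to genome coordinates", {
  fam <- evolve_family(family_spec(n_taxa = 6, seed = 10))
  pl <- plant_genomes(fam, seed = 11)
  for (k in seq_along(pl$genomes)) {
    g <- pl$genomes[[k]]
    ld <- extract_leader(g, locate_gene(g, "rpsO"))
    sub <- substr(g$record$sequence, ld$region[1] + 1L, ld$region[2])
    mrna <- if (ld$strand == "+") sub else leaderscout:::revcomp_chr(sub)
    expect_equal(chartr("T", "U", mrna), ld$sequence)
    # and the harvested leader equals the planted one
    expect_equal(ld$sequence, unname(fam$sequences[pl$truth$leaf[k]]))
  }
})

test_that("pair_identity agrees with a brute-force free-end-gap oracle", {
  # exhaustive alignment by recursion over tiny strings
  oracle <- function(a, b) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    best <- list(score = -Inf, id = 0)
    rec <- function(i, j, score, matches, cols, started_i, started_j) {
      if (i > n || j > m) {
        # end gaps free: stop anywhere once a sequence is exhausted
        if (cols > 0 && score > best$score) {
          best <<- list(score = score, id = matches / cols)
        }
        return(invisible())
      }
      # free leading gaps
      if (cols == 0) {
        rec(i + 1, j, score, matches, cols, started_i, started_j)
        rec(i, j + 1, score, matches, cols, started_i, started_j)
      } else {
        rec(i + 1, j, score - 2, matches, cols + 1, TRUE, started_j)
        rec(i, j + 1, score - 2, matches, cols + 1, started_i, TRUE)
      }
      s <- if (A[i] == B[j]) 1 else -1
      rec(i + 1, j + 1, score + s, matches + (A[i] == B[j]), cols + 1,
          TRUE, TRUE)
      # free trailing gaps: accept ending here
      if (cols > 0 && score > best$score) {
        best <<- list(score = score, id = matches / cols)
      }
    }
    rec(1, 1, 0, 0, 0, FALSE, FALSE)
    best
  }
  for (pair in list(c("ACGUACGU", "ACGUACGU"),
                    c("ACGUACGU", "ACGAACGU"),
                    c("GGGACGUA", "ACGUACCC"))) {
    got <- pair_identity(pair[1], pair[2])
    exp <- oracle(pair[1], pair[2])
    expect_equal(got$identity, exp$id, tolerance = 1e-9,
                 label = paste("identity for", pair[1], "vs", pair[2]))
  }
})

test_that("dedupe removes planted near-duplicates and keeps random pairs", {
  set.seed(12)
  x <- random_seq(300, c("A", "C", "G", "U"))
  mut <- strsplit(x, "")[[1]]
  idx <- sample(300, 15)   # 5% substitutions -> ~95% identity
  for (i in idx) mut[i] <- sample(setdiff(c("A", "C", "G", "U"), mut[i]), 1)
  y <- paste(mut, collapse = "")
  expect_length(dedupe(c(x, y)), 1L)
  # order-stable: the first occurrence is the one kept
  expect_equal(dedupe(c(x, y))[[1]], x)
  expect_equal(dedupe(c(y, x))[[1]], y)
  # two unrelated random 300-mers are both kept
  r1 <- random_seq(300, c("A", "C", "G", "U"))
  r2 <- random_seq(300, c("A", "C", "G", "U"))
  expect_length(dedupe(c(r1, r2)), 2L)
  # identical sequences collapse
  expect_length(dedupe(c(x, x, x)), 1L)
  # idempotence
  pool <- c(x, y, r1, r2)
  once <- dedupe(pool)
  expect_equal(dedupe(once), once)
  # empty input passes through
  expect_length(dedupe(character(0)), 0L)
})

test_that("taxonomic clustering splits oversized groups by rank", {
  mk <- function(n, order_name, phylum = "Proteobacteria") {
    lapply(seq_len(n), function(k) {
      make_leader(random_seq(30), genome_id = sprintf("%s%03d", order_name, k),
                  taxonomy = c("Bacteria", phylum, "SomeClass", order_name))
    })
  }
  set.seed(13)
  # 150 leaders sharing a phylum, two orders of 75 -> 2 clusters of 75
  leaders <- c(mk(75, "OrderA"), mk(75, "OrderB"))
  cl <- cluster_by_taxonomy(leaders)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, function(x) length(x$members), integer(1)),
                  c(75L, 75L))
  # mixed phyla, none oversized -> one cluster per phylum
  leaders2 <- c(mk(30, "OrderA", "Firmicutes"), mk(20, "OrderB", "Chlamydiae"))
  cl2 <- cluster_by_taxonomy(leaders2)
  expect_length(cl2, 2L)
  # 120 identical lineages -> forced chunks of 100 + 20
  leaders3 <- mk(120, "OrderC")
  cl3 <- cluster_by_taxonomy(leaders3)
  expect_setequal(vapply(cl3, function(x) length(x$members), integer(1)),
                  c(100L, 20L))
  # empty taxonomy goes to an unclassified group
  leaders4 <- list(make_leader(random_seq(30), genome_id = "X1"))
  cl4 <- cluster_by_taxonomy(leaders4)
  expect_match(cl4[[1]]$label, "unclassified")
})

test_that("clusters partition the input within the size bound", {
  set.seed(14)
  leaders <- lapply(1:137, function(k) {
    make_leader(random_seq(30), genome_id = sprintf("G%03d", k),
                taxonomy = c("Bacteria",
                             sample(c("P1", "P2"), 1),
                             sample(c("C1", "C2"), 1),
                             sample(c("O1", "O2", "O3"), 1)))
  })
  cl <- cluster_by_taxonomy(leaders, max_size = 20L)
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  expect_true(all(sizes >= 1L & sizes <= 20L))
  ids <- unlist(lapply(cl, function(x)
    vapply(x$members, function(l) l$genome_id, character(1))))
  expect_setequal(ids, vapply(leaders, function(l) l$genome_id,
                              character(1)))
  expect_equal(length(ids), length(leaders))   # disjoint
})
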