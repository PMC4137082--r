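# Synthetic-data generators: every input the pipeline consumes can be
# produced here with the statistical structure the analysis assumes --
# planted covarying-helix leader families upstream of a marked gene,
# step-shaped coverage with Poisson noise, and hyperbolic binding
# curves with Gaussian noise.  All generators are pure functions of
# (spec, seed).

#' Specify a synthetic leader family
#'
#' Defines the evolutionary simulation for a structured-leader family:
#' a root leader with designated helices, a random rooted guide tree,
#' a uniform (Jukes-Cantor-style) substitution process, and a single
#' compensation knob `pair_retention` -- the probability that a
#' substitution hitting a paired site is immediately complemented in
#' its partner, which controls the covariation signal.
#'
#' The default root leader is 111 nt of 5' region plus the first 25 nt
#' of a fixed coding sequence, carrying three planted helices:
#' `H0` (cols 10-34, 8 bp), a transcription start site at leader
#' position 40 (so H0 lies entirely 5' of the transcript), the
#' strongly covarying `H1` (cols 45-70, 8 bp) and `H2` (cols 79-101,
#' 6 bp) followed by a Shine-Dalgarno sequence.
#'
#' @param n_taxa number of leaves (default 20).
#' @param sub_rate expected substitutions per site per unit branch
#'   length (default 0.3 with tree depth 1).
#' @param pair_retention compensation probability `rho` in `[0, 1]`
#'   (default 0.9).
#' @param indel_rate per-site deletion rate per unit branch length
#'   (default 0; deletions only, so true column homology stays
#'   root-indexed).
#' @param depth mean root-to-leaf tree depth (default 1).
#' @param tss_offset 0-based leader position of the transcription
#'   start site (default 39, i.e. position 40).
#' @param seed RNG seed; the generator is a pure function of the spec
#'   including this seed.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(n_taxa = 20L, sub_rate = 0.3, pair_retention = 0.9,
                        indel_rate = 0, depth = 1, tss_offset = 39L,
                        seed = 1L) {
  stopifnot(pair_retention >= 0, pair_retention <= 1, n_taxa >= 2L)
  root <- default_root_leader()
  structure(list(
    n_taxa = as.integer(n_taxa), sub_rate = sub_rate,
    pair_retention = pair_retention, indel_rate = indel_rate,
    depth = depth, tss_offset = as.integer(tss_offset),
    root_leader = root$sequence, helices = root$helices,
    upstream_len = root$upstream_len, cds = root$cds,
    seed = as.integer(seed)
  ), class = "family_spec")
}

# fixed root leader: unpaired positions drawn once from a frozen RNG
# stream, helix partners set Watson-Crick complementary
#' @noRd
default_root_leader <- function() {
  helices <- list(
    H0 = cbind(i = 10:17, j = 34:27),
    H1 = cbind(i = 45:52, j = 70:63),
    H2 = cbind(i = 79:84, j = 101:96)
  )
  upstream_len <- 111L
  cds <- paste0("ATGGCTCTGACCCAAGAACGTAAAC",
                "GCGAAATCATCGAACAGTTCAAAGTTCACGAAAACGACACCGGTTCT",
                "CCGGAAGTTCAGGTTGCTATCCTGACCGAAGAAATCAACAAACTGAACGAA",
                "CACCTGAAAACCCACAAGAAAGACCACCACTCT", "TAA")
  set.seed(20140807L)
  up <- sample(c("A", "C", "G", "U"), upstream_len, replace = TRUE)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (h in helices) {
    for (r in seq_len(nrow(h))) up[h[r, "j"]] <- comp[[up[h[r, "i"]]]]
  }
  # Shine-Dalgarno just 3' of H2
  up[103:108] <- c("A", "G", "G", "A", "G", "G")
  # keep the H1 loop strongly conserved and recognisable
  up[53:62] <- c("C", "A", "A", "C", "C", "C", "U", "A", "A", "G")
  for (h in helices) {
    for (r in seq_len(nrow(h))) up[h[r, "j"]] <- comp[[up[h[r, "i"]]]]
  }
  leader <- paste0(paste(up, collapse = ""),
                   dna_to_rna(substr(cds, 1L, 25L)))
  list(sequence = leader, helices = helices, upstream_len = upstream_len,
       cds = cds)
}

#' Evolve a synthetic leader family down a random tree
#'
#' Sequences evolve along a random rooted tree (branch lengths scaled
#' to the spec's mean depth).  Unpaired sites substitute independently
#' and uniformly over the three alternative nucleotides; a
#' substitution at a paired site is, with probability
#' `pair_retention`, immediately complemented in its partner so the
#' canonical pair is preserved.  With `indel_rate > 0` sites can be
#' deleted (once lost, a site stays lost), so the true alignment is
#' always indexed by root positions.
#'
#' @param spec `family_spec`.
#' @return list with `sequences` (named ungapped RNA leaves, including
#'   the fixed 25 nt coding tail), `alignment` (the true
#'   `rna_alignment`, root-position columns, with the planted
#'   structure line), `tree` (`phylo`), and `truth` (list: `helices`,
#'   `pairs` data frame, `tss_offset`, `tss_column`, `column_map` per
#'   leaf from ungapped 0-based leaf position to 1-based column,
#'   `n_substitutions`, `expected_substitutions`, `spec`).
#' @export
evolve_family <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_taxa
  tree <- ape::rtree(n, rooted = TRUE)
  tree$tip.label <- sprintf("TAX%02d", seq_len(n))
  # scale to the requested mean root-to-leaf depth
  d <- ape::node.depth.edgelength(tree)[seq_len(n)]
  tree$edge.length <- tree$edge.length * spec$depth / mean(d)

  L <- nchar(spec$root_leader)
  up_len <- spec$upstream_len
  root_codes <- seq_to_codes(spec$root_leader)
  partner <- rep(NA_integer_, L)
  for (h in spec$helices) {
    partner[h[, "i"]] <- h[, "j"]
    partner[h[, "j"]] <- h[, "i"]
  }
  comp_code <- c(4L, 3L, 2L, 1L)  # WC complement by code

  n_sub <- 0L
  exp_sub <- 0
  nnode <- max(tree$edge)
  states <- vector("list", nnode)
  root_node <- n + 1L
  states[[root_node]] <- list(codes = root_codes, alive = rep(TRUE, L))
  po <- ape::reorder.phylo(tree, "postorder")
  # walk edges root-to-tip (reverse postorder)
  for (k in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[k, 1L]; chd <- po$edge[k, 2L]
    b <- po$edge.length[k]
    st <- states[[par]]
    codes <- st$codes; alive <- st$alive
    # only the 5' region evolves; the coding tail is conserved
    evolvable <- which(alive & seq_len(L) <= up_len)
    p_sub <- 1 - exp(-spec$sub_rate * b)
    exp_sub <- exp_sub + length(evolvable) * p_sub
    hit <- evolvable[runif(length(evolvable)) < p_sub]
    for (s in hit) {
      old <- codes[s]
      new <- sample(setdiff(1:4, old), 1L)
      codes[s] <- new
      n_sub <- n_sub + 1L
      pt <- partner[s]
      if (!is.na(pt) && alive[pt] &&
          runif(1L) < spec$pair_retention) {
        codes[pt] <- comp_code[new]
      }
    }
    if (spec$indel_rate > 0) {
      p_del <- 1 - exp(-spec$indel_rate * b)
      del <- evolvable[runif(length(evolvable)) < p_del]
      alive[del] <- FALSE
    }
    states[[chd]] <- list(codes = codes, alive = alive)
  }

  rows <- character(n)
  seqs <- character(n)
  column_map <- vector("list", n)
  for (t in seq_len(n)) {
    st <- states[[t]]
    gapped <- ifelse(st$alive, NT_LETTERS[st$codes], "-")
    rows[t] <- paste(gapped, collapse = "")
    seqs[t] <- gsub("-", "", rows[t], fixed = TRUE)
    column_map[[t]] <- which(st$alive)   # leaf pos (1-based) -> column
  }
  names(rows) <- names(seqs) <- names(column_map) <- tree$tip.label

  ss <- rep(".", L)
  for (h in spec$helices) { ss[h[, "i"]] <- "<"; ss[h[, "j"]] <- ">" }
  aln <- rna_alignment(rows, structure = paste(ss, collapse = ""))
  pairs <- do.call(rbind, lapply(names(spec$helices), function(nm) {
    data.frame(helix = nm, i = spec$helices[[nm]][, "i"],
               j = spec$helices[[nm]][, "j"])
  }))
  list(
    sequences = seqs,
    alignment = aln,
    tree = tree,
    truth = list(helices = spec$helices, pairs = pairs,
                 tss_offset = spec$tss_offset,
                 tss_column = spec$tss_offset + 1L,
                 column_map = column_map,
                 n_substitutions = n_sub,
                 expected_substitutions = exp_sub,
                 spec = spec)
  )
}

#' Plant a leader family into synthetic annotated genomes
#'
#' Embeds each leaf's leader immediately 5' of a fixed rpsO-like open
#' reading frame in an i.i.d.-uniform background genome, optionally
#' preceded by a decoy "previous gene" that bounds the upstream
#' harvest at a configurable gap, on a random strand per genome.
#'
#' @param family result of [evolve_family()].
#' @param background_length total genome length (default 3000).
#' @param seed RNG seed.
#' @param decoy plant the upstream decoy gene (default TRUE).
#' @param upstream_gap distance in nt from the decoy's 3' end to the
#'   rpsO translation start; defaults to the evolved 5'-region length
#'   of each leaf, so harvesting reproduces exactly the planted
#'   leader.
#' @param taxonomy_orders number of taxonomic orders the leaves are
#'   spread over (default 2).
#' @param dir optional directory; when given, per-genome FASTA + GFF3
#'   and a `taxonomy.tsv` are written there.
#' @return list with `genomes` (list of `annotated_genome`) and
#'   `truth` (per-genome data frame: `genome_id`, `strand`,
#'   `leader_start0`, `leader_end0`, `cds_start`, `cds_end`,
#'   `tss_pos0`, `taxonomy`), plus the `family` truth carried through.
#' @export
plant_genomes <- function(family, background_length = 3000L, seed = 1L,
                          decoy = TRUE, upstream_gap = NULL,
                          taxonomy_orders = 2L, dir = NULL) {
  set.seed(seed)
  spec <- family$truth$spec
  cds <- spec$cds
  decoy_cds <- decoy_gene_seq()
  leaves <- names(family$sequences)
  n <- length(leaves)
  genomes <- vector("list", n)
  truth <- NULL
  orders <- paste0("Order", LETTERS[1 + (seq_len(n) - 1) %%
                                      max(taxonomy_orders, 1L)])
  for (k in seq_len(n)) {
    leaf <- leaves[k]
    full <- rna_to_dna(family$sequences[[leaf]])
    # evolved 5' region of this leaf (deletions may shorten it)
    cmap <- family$truth$column_map[[leaf]]
    up_positions <- which(cmap <= spec$upstream_len)
    up_seq <- substr(full, 1L, length(up_positions))
    gap_extra <- if (is.null(upstream_gap)) 0L else
      upstream_gap - nchar(up_seq)
    if (gap_extra < 0L) {
      stop("upstream_gap smaller than the planted leader length (",
           nchar(up_seq), ")")
    }
    gid <- sprintf("SYN%02d", k)
    tax <- c("Bacteria", "Syntheticota", "Synthetia", orders[k],
             paste0("Genus", k))

    bg <- function(m) paste(sample(c("A", "C", "G", "T"), m,
                                   replace = TRUE), collapse = "")
    pre_len <- 400L
    cassette <- paste0(
      if (decoy) decoy_cds else "",
      if (gap_extra > 0L) bg(gap_extra) else "",
      up_seq, cds
    )
    post_len <- background_length - pre_len - nchar(cassette)
    if (post_len < 50L) stop("background_length too small for the cassette")
    gseq <- paste0(bg(pre_len), cassette, bg(post_len))

    # forward-strand layout (1-based)
    decoy_start <- pre_len + 1L
    decoy_end <- if (decoy) pre_len + nchar(decoy_cds) else NA_integer_
    leader_start <- pre_len + (if (decoy) nchar(decoy_cds) else 0L) +
      gap_extra + 1L
    cds_start <- leader_start + nchar(up_seq)
    cds_end <- cds_start + nchar(cds) - 1L
    # TSS: first transcribed base at leader offset tss_offset (root
    # coordinates mapped through this leaf's surviving positions)
    tss_leaf <- match(TRUE, cmap >= spec$tss_offset + 1L)
    tss_pos1 <- leader_start + tss_leaf - 1L

    strand <- sample(c("+", "-"), 1L)
    glen <- nchar(gseq)
    if (strand == "-") {
      flip1 <- function(p) glen - p + 1L
      gseq <- revcomp_chr(gseq)
      feats <- data.frame(
        genome_id = gid,
        name = c(if (decoy) "decoyA", "rpsO"),
        type = "CDS",
        start = c(if (decoy) flip1(decoy_end), flip1(cds_end)),
        end = c(if (decoy) flip1(decoy_start), flip1(cds_start)),
        strand = "-",
        product = c(if (decoy) "decoy protein",
                    "30S ribosomal protein S15"),
        stringsAsFactors = FALSE
      )
      leader0 <- c(flip1(leader_start + nchar(up_seq) + 24L) - 1L,
                   flip1(leader_start))
      tss0 <- flip1(tss_pos1) - 1L
      cds1 <- c(flip1(cds_end), flip1(cds_start))
    } else {
      feats <- data.frame(
        genome_id = gid,
        name = c(if (decoy) "decoyA", "rpsO"),
        type = "CDS",
        start = c(if (decoy) decoy_start, cds_start),
        end = c(if (decoy) decoy_end, cds_end),
        strand = "+",
        product = c(if (decoy) "decoy protein",
                    "30S ribosomal protein S15"),
        stringsAsFactors = FALSE
      )
      leader0 <- c(leader_start - 1L, leader_start + nchar(up_seq) + 24L)
      tss0 <- tss_pos1 - 1L
      cds1 <- c(cds_start, cds_end)
    }
    record <- structure(list(id = gid, sequence = gseq, taxonomy = tax),
                        class = "genome_record")
    genomes[[k]] <- structure(list(record = record, features = feats),
                              class = "annotated_genome")
    truth <- rbind(truth, data.frame(
      genome_id = gid, leaf = leaf, strand = strand,
      leader_start0 = leader0[1L], leader_end0 = leader0[2L],
      cds_start = cds1[1L], cds_end = cds1[2L],
      tss_pos0 = tss0,
      taxonomy = paste(tax, collapse = ";"),
      stringsAsFactors = FALSE
    ))
  }
  names(genomes) <- truth$genome_id

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (g in genomes) {
      write_genome(g, file.path(dir, paste0(g$record$id, ".fna")),
                   file.path(dir, paste0(g$record$id, ".gff3")))
    }
    write.table(
      data.frame(truth$genome_id, truth$taxonomy),
      file.path(dir, "taxonomy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  list(genomes = genomes, truth = truth, family_truth = family$truth)
}

#' @noRd
decoy_gene_seq <- function() {
  paste0("ATGAAACGTATCGCTGAAGTTCTGGGTCTGACCCCGGAAGAAGTTCAGGCT",
         "ATCGTTGAAGCTCTGAACAAACGTGGTATCGACTTCGAAGCTATGTCT",
         "GGTCGTGGTAAACCGTAA")
}

#' Simulate a step-shaped coverage window
#'
#' Poisson read depth with mean `means[1]` before the step and
#' `means[2]` from the step onward, emulating the read-depth evidence
#' used to place transcription starts.
#'
#' @param tss_offset 0-based index of the step within the window.
#' @param means length-2 vector `c(upstream, downstream)`; a
#'   downstream mean below the upstream one is allowed (negative
#'   controls).
#' @param length window length (default 200).
#' @param seed RNG seed.
#' @param genome_id,window,strand passed to [coverage_profile()];
#'   `window` defaults to `c(0, length)`.
#' @return `coverage_profile`.
#' @export
simulate_coverage <- function(tss_offset, means = c(2, 40), length = 200L,
                              seed = 1L, genome_id = "sim",
                              window = NULL, strand = "+") {
  stopifnot(tss_offset >= 0L, tss_offset <= length)
  set.seed(seed)
  depth <- c(rpois(tss_offset, means[1L]),
             rpois(length - tss_offset, means[2L]))
  coverage_profile(genome_id, window %||% c(0L, length), depth,
                   strand = strand)
}

#' Simulate filter-binding titrations
#'
#' Draws replicate titrations from the one-site model
#' `Fb = max_pct * c / (c + kd)` with additive Gaussian noise, clipped
#' to `[0, 1]`.  With `counts_total` given, count-space data are
#' emitted instead (`counts_nc = round(total * Fb)`).
#'
#' @param kd generating dissociation constant, nM.
#' @param max_pct generating plateau.
#' @param concs protein concentrations, nM (default 12 two-fold
#'   dilutions 0.5 to 1024).
#' @param noise_sd Gaussian noise SD on the fraction bound (default
#'   0.03).
#' @param n_reps number of replicate datasets.
#' @param seed RNG seed.
#' @param counts_total optional total counts per point for count-space
#'   emission.
#' @return list of `n_reps` data frames with columns `conc`, `fb`
#'   (and `counts_nc`, `counts_nylon` when `counts_total` is given).
#' @export
simulate_binding <- function(kd, max_pct, concs = 0.5 * 2^(0:11),
                             noise_sd = 0.03, n_reps = 1L, seed = 1L,
                             counts_total = NULL) {
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    fb <- binding_model(concs, kd, max_pct)
    if (noise_sd > 0) fb <- fb + rnorm(length(concs), 0, noise_sd)
    fb <- pmin(pmax(fb, 0), 1)
    out <- data.frame(conc = concs, fb = fb)
    if (!is.null(counts_total)) {
      out$counts_nc <- round(counts_total * fb)
      out$counts_nylon <- counts_total - out$counts_nc
    }
    out
  })
}
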