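#' Pipeline configuration
#'
#' All tunable parameters of the discovery pipeline in one validated
#' list.  Defaults follow the standard workflow: 500 nt upstream
#' windows with a 25 nt coding tail, redundancy removal at >90%
#' identity over >70% of the shorter sequence, taxonomic clusters of
#' at most 100 sequences, a lenient homology E-value cut-off of 1.0
#' with up to 4 search rounds, and a 3-fold / depth-5 acceptance rule
#' for coverage change-points.
#'
#' @param upstream_max,coding_tail leader harvesting (see
#'   [extract_leader()]).
#' @param id_threshold,cov_threshold redundancy removal (see
#'   [dedupe()]).
#' @param max_cluster taxonomic cluster bound.
#' @param tau,phi,min_helix covariation folding (see
#'   [fold_alignment()]).
#' @param e_cutoff,rounds,n_shuffles homology expansion (see
#'   [expand_iterate()]).
#' @param min_fold,min_depth TSS acceptance (see [call_tss()]).
#' @param seed global seed, fanned out per stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(upstream_max = 500L, coding_tail = 25L,
                            id_threshold = 0.90, cov_threshold = 0.70,
                            max_cluster = 100L, tau = 0.05, phi = 1.0,
                            min_helix = 2L, e_cutoff = 1.0, rounds = 4L,
                            n_shuffles = 20L, min_fold = 3.0,
                            min_depth = 5.0, seed = 1L) {
  stopifnot(upstream_max > 0L, coding_tail >= 0L,
            id_threshold > 0, id_threshold <= 1,
            cov_threshold > 0, cov_threshold <= 1,
            max_cluster >= 1L, tau >= 0, phi >= 0, min_helix >= 1L,
            e_cutoff >= 0, rounds >= 0L, n_shuffles >= 1L,
            min_fold >= 1, min_depth >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the leader-discovery pipeline
#'
#' End-to-end orchestration over a genome set: locate the target gene
#' in each genome, harvest its 5' leader, remove redundant sequences,
#' cluster by taxonomy, and per cluster align, weight, fold, and
#' (optionally) expand by homology search; when coverage evidence is
#' supplied, call the transcription start site and flag helices not
#' supported by the transcript.  Stage outputs (per-cluster annotated
#' Stockholm, TSS table, JSON summary) are written under `out_dir`
#' when given.
#'
#' @param genomes list of `annotated_genome` objects (>= 2), or a
#'   directory containing `*.fna` + `*.gff3` pairs and an optional
#'   `taxonomy.tsv`.
#' @param gene_name target gene (default `"rpsO"`).
#' @param coverage optional list of `coverage_profile` objects (one
#'   per genome with transcriptomic evidence).
#' @param config `pipeline_config`.
#' @param expand logical: run the homology-expansion stage (default
#'   FALSE; it is the most expensive stage).
#' @param out_dir optional run directory.
#' @return summary list (per cluster: sequence counts before/after
#'   dedup, helices found, TSS flags, expansion provenance), plus
#'   `clusters` with the full per-cluster result objects.
#' @export
run_pipeline <- function(genomes, gene_name = "rpsO", coverage = NULL,
                         config = pipeline_config(), expand = FALSE,
                         out_dir = NULL) {
  if (is.character(genomes)) genomes <- load_genome_dir(genomes)
  if (length(genomes) < 2L) stop("pipeline stage harvest: need >= 2 genomes")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  leaders <- lapply(genomes, function(g) {
    gene <- locate_gene(g, gene_name)
    extract_leader(g, gene, upstream_max = config$upstream_max,
                   coding_tail = config$coding_tail)
  })
  n_raw <- length(leaders)
  leaders <- dedupe(leaders, id_threshold = config$id_threshold,
                    cov_threshold = config$cov_threshold)
  clusters <- cluster_by_taxonomy(leaders, max_size = config$max_cluster)

  cluster_summaries <- list()
  cluster_results <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    if (length(cl$members) < 2L) {
      cluster_summaries[[cl$label]] <- list(
        label = cl$label, n_sequences = length(cl$members),
        skipped = "fewer than 2 sequences")
      next
    }
    aln <- progressive_align(cl)
    walign <- gsc_weights(aln)
    struct <- fold_alignment(walign, tau = config$tau,
                             min_helix = config$min_helix,
                             phi = config$phi)
    expansion_rounds <- 0L
    if (expand && config$rounds > 0L) {
      walign <- expand_iterate(walign, struct, genomes,
                               e_cutoff = config$e_cutoff,
                               rounds = config$rounds,
                               n_shuffles = config$n_shuffles,
                               seed = config$seed + 1000L * ci)
      expansion_rounds <- if (length(walign$provenance)) {
        max(walign$provenance)
      } else 0L
      struct <- fold_alignment(walign, tau = config$tau,
                               min_helix = config$min_helix,
                               phi = config$phi)
    }

    tss_info <- NULL
    if (!is.null(coverage)) {
      cov_ids <- vapply(coverage, function(p) p$genome_id, character(1L))
      member_ids <- vapply(cl$members, function(l) l$genome_id,
                           character(1L))
      usable <- which(cov_ids %in% member_ids)
      if (length(usable)) {
        prof <- coverage[[usable[1L]]]
        call <- call_tss(prof, min_fold = config$min_fold,
                         min_depth = config$min_depth)
        if (!is.null(call)) {
          ex <- cl$members[[match(prof$genome_id, member_ids)]]
          struct <- truncate_to_transcript(struct, walign$alignment,
                                           call, ex)
          tss_info <- list(genome_id = call$genome_id,
                           position = call$position,
                           confidence = call$confidence)
        }
      }
    }

    if (!is.null(out_dir)) {
      report_consensus(walign, struct,
                       path = file.path(out_dir,
                                        paste0("cluster", ci, ".sto")))
    }
    helix_flags <- if (nrow(struct$helices)) {
      setNames(as.list(struct$helices$tss_support), struct$helices$name)
    } else list()
    cluster_summaries[[cl$label]] <- list(
      label = cl$label,
      n_sequences = length(cl$members),
      n_rows_final = length(walign$alignment$rows),
      helices = struct$helices$name,
      helix_tss_support = helix_flags,
      expansion_rounds = expansion_rounds,
      tss = tss_info
    )
    cluster_results[[cl$label]] <- list(cluster = cl, walign = walign,
                                        structure = struct)
  }

  summary <- list(
    gene = gene_name,
    n_genomes = length(genomes),
    n_leaders = n_raw,
    n_after_dedup = length(leaders),
    n_clusters = length(clusters),
    clusters = cluster_summaries
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  c(summary, list(results = cluster_results))
}

#' @noRd
load_genome_dir <- function(dir) {
  fna <- sort(list.files(dir, pattern = "\\.(fna|fa|fasta)$",
                         full.names = TRUE))
  if (!length(fna)) stop("no FASTA files in ", dir)
  taxp <- file.path(dir, "taxonomy.tsv")
  if (!file.exists(taxp)) taxp <- NULL
  lapply(fna, function(f) {
    gff <- sub("\\.(fna|fa|fasta)$", ".gff3", f)
    if (!file.exists(gff)) stop("no GFF3 next to ", f)
    read_genome(f, gff, taxonomy_path = taxp)
  })
}

#' Synthetic end-to-end demonstration
#'
#' Generates a planted leader family (20 taxa, compensation 0.9),
#' embeds it in synthetic genomes with an upstream decoy gene,
#' simulates a read-coverage step at the planted transcription start
#' site of one example genome, and runs the full pipeline.  The
#' expected outcome mirrors the canonical curation story: the helix
#' planted 5' of the TSS is recovered by comparative folding but
#' flagged `unsupported` by the transcript boundary, while the
#' downstream helices are retained.
#'
#' @param seed integer seed controlling every stage.
#' @param out_dir optional run directory for stage outputs.
#' @param expand run the homology-expansion stage (default FALSE to
#'   keep the demo fast).
#' @return the pipeline summary, plus `truth` (planting record) and
#'   `flags` (named helix support flags of the first cluster).
#' @export
run_demo <- function(seed = 7L, out_dir = NULL, expand = FALSE) {
  spec <- family_spec(n_taxa = 20L, seed = seed)
  fam <- evolve_family(spec)
  planted <- plant_genomes(fam, seed = seed + 1L)

  # coverage evidence for the first genome, oriented along its gene
  tr <- planted$truth[1L, ]
  win_len <- 300L
  lead_len <- tr$leader_end0 - tr$leader_start0
  # oriented window starts 60 nt 5' of the leader start
  offset5 <- 60L
  tss_leader_pos <- if (tr$strand == "+") {
    tr$tss_pos0 - tr$leader_start0
  } else {
    tr$leader_end0 - 1L - tr$tss_pos0
  }
  window <- if (tr$strand == "+") {
    c(tr$leader_start0 - offset5, tr$leader_start0 - offset5 + win_len)
  } else {
    c(tr$leader_end0 + offset5 - win_len, tr$leader_end0 + offset5)
  }
  cov <- simulate_coverage(tss_offset = offset5 + tss_leader_pos,
                           means = c(2, 40), length = win_len,
                           seed = seed + 2L, genome_id = tr$genome_id,
                           window = window, strand = tr$strand)

  config <- pipeline_config(seed = seed)
  res <- run_pipeline(planted$genomes, gene_name = "rpsO",
                      coverage = list(cov), config = config,
                      expand = expand, out_dir = out_dir)
  first <- res$results[[1L]]
  flags <- if (!is.null(first) && nrow(first$structure$helices)) {
    setNames(first$structure$helices$tss_support,
             first$structure$helices$name)
  } else character(0)

  # map each planted helix onto the inferred structure: a planted helix
  # is represented by the inferred helix sharing most of its pairs
  planted_flags <- planted_recovery <- setNames(
    rep(NA_character_, length(spec$helices)), names(spec$helices))
  if (!is.null(first)) {
    aln <- first$walign$alignment
    member <- intersect(names(aln$rows), planted$truth$genome_id)[1L]
    leaf <- planted$truth$leaf[match(member, planted$truth$genome_id)]
    cmap <- fam$truth$column_map[[leaf]]
    st <- first$structure
    for (hn in names(spec$helices)) {
      h <- spec$helices[[hn]]
      pi <- column_of_position(aln, member, match(h[, "i"], cmap))
      pj <- column_of_position(aln, member, match(h[, "j"], cmap))
      hit <- match(paste(pi, pj), paste(st$pairs$i, st$pairs$j))
      planted_recovery[hn] <- sprintf("%d/%d", sum(!is.na(hit)), nrow(h))
      hel <- st$pairs$helix[hit[!is.na(hit)]]
      if (length(hel)) {
        top <- names(sort(table(hel), decreasing = TRUE))[1L]
        planted_flags[hn] <-
          st$helices$tss_support[st$helices$name == top]
      }
    }
  }
  c(res, list(truth = planted$truth, flags = flags,
              planted_flags = planted_flags,
              planted_recovery = planted_recovery))
}
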