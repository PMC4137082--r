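#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: the sequence is viewed as an Eulerian
#' walk on the dinucleotide multigraph; a random last-exit edge set
#' forming an arborescence toward the final letter is drawn, the
#' remaining out-edges are permuted, and the walk is rebuilt.  The
#' shuffled sequence has exactly the original dinucleotide counts.
#'
#' @param x nucleotide string (length >= 3).
#' @return shuffled string over the same alphabet.
#' @export
dinucleotide_shuffle <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) return(x)
  letters_used <- unique(ch)
  if (length(letters_used) == 1L) return(x)
  last <- ch[n]
  # out-edge target lists per source letter
  out <- split(ch[-1L], ch[-n])
  for (tries in 1:200) {
    # pick a random last-exit for every vertex except the final one
    last_exit <- vapply(letters_used, function(v) {
      if (v == last) return(NA_character_)
      tg <- out[[v]]
      if (is.null(tg)) return(NA_character_)
      tg[sample.int(length(tg), 1L)]
    }, character(1L))
    names(last_exit) <- letters_used
    # check: following last-exits from every vertex must reach `last`
    ok <- TRUE
    for (v in letters_used) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.na(last_exit[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_exit[cur]
      }
      if (!ok) break
    }
    if (!ok) next
    # permute the non-last-exit edges, append the last exit
    pool <- out
    for (v in names(pool)) {
      tg <- pool[[v]]
      if (!is.na(last_exit[v])) {
        drop1 <- match(last_exit[v], tg)
        tg <- tg[-drop1]
      }
      tg <- if (length(tg)) tg[sample.int(length(tg))] else character(0)
      if (!is.na(last_exit[v])) tg <- c(tg, last_exit[v])
      pool[[v]] <- tg
    }
    ptr <- setNames(rep(1L, length(pool)), names(pool))
    res <- character(n)
    res[1L] <- ch[1L]
    cur <- ch[1L]
    for (k in 2:n) {
      nxt <- pool[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      res[k] <- nxt
      cur <- nxt
    }
    return(paste(res, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find a valid arborescence")
}

#' Fit a Gumbel distribution by the method of moments
#'
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda`
#' (Euler-Mascheroni gamma).  Closed-form and deterministic.
#'
#' @param scores numeric vector of null scores.
#' @return list with `mu`, `lambda`, `n`.
#' @export
fit_gumbel <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) stop("need at least 2 finite null scores")
  s <- sd(scores)
  if (s == 0) stop("degenerate null score variance (sd = 0)")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.57721566490153286 / lambda
  list(mu = mu, lambda = lambda, n = length(scores))
}

#' Calibrate empirical E-values for a motif profile
#'
#' Builds a null score distribution by scanning dinucleotide-preserving
#' shuffles of each genome, fits a Gumbel by the method of moments, and
#' annotates the real-genome hits with
#' `E(s) = N_eff * exp(-lambda * (s - mu))`, where `N_eff` is the total
#' number of searched positions divided by the profile length.
#'
#' @param profile `motif_profile`.
#' @param genomes list of `annotated_genome` / `genome_record` objects
#'   (or nucleotide strings).
#' @param n_shuffles shuffles per genome (default 20).
#' @param seed RNG seed for the shuffles.
#' @param both_strands passed to [scan_genome()].
#' @return list with `calibration` (list `mu`, `lambda`, `n_eff`,
#'   `null_scores`) and `hits` (annotated hit data frame across all
#'   genomes, sorted by E-value).
#' @export
calibrate_evalues <- function(profile, genomes, n_shuffles = 20L,
                              seed = 1L, both_strands = TRUE) {
  if (!length(genomes)) stop("need at least one genome")
  set.seed(seed)
  null_scores <- numeric(0)
  total_pos <- 0
  real_hits <- empty_hits()
  for (g in genomes) {
    rec <- if (inherits(g, "annotated_genome")) g$record else g
    seqchr <- if (inherits(rec, "genome_record")) rec$sequence else
      toupper(as.character(rec))
    total_pos <- total_pos + nchar(seqchr) * (1L + both_strands)
    for (r in seq_len(n_shuffles)) {
      shuf <- dinucleotide_shuffle(seqchr)
      hs <- scan_genome(profile, shuf, both_strands = both_strands)
      null_scores <- c(null_scores, hs$raw_score)
    }
    real_hits <- rbind(real_hits, scan_genome(profile, g,
                                              both_strands = both_strands))
  }
  fit <- fit_gumbel(null_scores)
  n_eff <- total_pos / profile$length
  calibration <- list(mu = fit$mu, lambda = fit$lambda, n_eff = n_eff,
                      null_scores = null_scores)
  hits <- assign_evalues(real_hits, calibration)
  list(calibration = calibration, hits = hits)
}

#' Annotate hits with E-values under a calibration
#'
#' @param hits hit data frame from [scan_genome()].
#' @param calibration list with `mu`, `lambda`, `n_eff` (from
#'   [calibrate_evalues()]).
#' @return `hits` with the `evalue` column filled, sorted by E-value.
#' @export
assign_evalues <- function(hits, calibration) {
  if (nrow(hits)) {
    hits$evalue <- calibration$n_eff *
      exp(-calibration$lambda * (hits$raw_score - calibration$mu))
    hits <- hits[order(hits$evalue), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Iteratively expand a structured alignment across genomes
#'
#' The homology-search loop: per round, build a profile from the
#' current weighted alignment, scan and calibrate across the genome
#' set, accept hits with `evalue <= e_cutoff` that are not already
#' members (by interval overlap or identical ungapped sequence), map
#' each accepted hit onto the profile columns via the scan traceback,
#' and rebuild the alignment.  Stops early when a round adds nothing.
#' Membership grows monotonically and the result is deterministic
#' given `seed`.
#'
#' @param walign seed `weighted_alignment`.
#' @param structure `consensus_structure` for the seed alignment.
#' @param genomes list of genomes to search.
#' @param e_cutoff E-value acceptance threshold (default 1.0, a
#'   deliberately lenient cut).
#' @param rounds maximum search rounds (default 4).
#' @param n_shuffles shuffles per genome per round for the null.
#' @param seed RNG seed (fanned out per round).
#' @param alpha profile pseudocount.
#' @return `weighted_alignment` with added rows; each row's recruiting
#'   round is recorded in `$provenance` (0 = seed row).
#' @export
expand_iterate <- function(walign, structure, genomes, e_cutoff = 1.0,
                           rounds = 4L, n_shuffles = 20L, seed = 1L,
                           alpha = 0.5) {
  stopifnot(rounds >= 1L)
  provenance <- setNames(rep(0L, length(walign$alignment$rows)),
                         names(walign$alignment$rows))
  accepted <- data.frame(genome_id = character(0), start0 = integer(0),
                         end0 = integer(0), strand = character(0))
  member_seqs <- gsub("-", "", walign$alignment$rows, fixed = TRUE)

  for (round in seq_len(rounds)) {
    prof <- build_profile(walign, structure, alpha = alpha)
    cal <- calibrate_evalues(prof, genomes, n_shuffles = n_shuffles,
                             seed = seed + round)
    hits <- cal$hits
    hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
    added <- 0L
    for (k in seq_len(nrow(hits))) {
      h <- hits[k, ]
      useq <- gsub("-", "", h$aligned, fixed = TRUE)
      if (useq %in% member_seqs) next
      if (is_member(accepted, h)) next
      rid <- sprintf("%s/%d-%d(%s)", h$genome_id, h$start0 + 1L, h$end0,
                     h$strand)
      if (rid %in% names(walign$alignment$rows)) next
      rows <- c(walign$alignment$rows, setNames(h$aligned, rid))
      aln <- rna_alignment(rows, structure = walign$alignment$structure,
                           metadata = walign$alignment$metadata)
      walign <- reweight_alignment(aln)
      provenance[rid] <- round
      accepted <- rbind(accepted, h[, c("genome_id", "start0", "end0",
                                        "strand")])
      member_seqs <- c(member_seqs, useq)
      added <- added + 1L
    }
    if (added == 0L) break
  }
  walign$provenance <- provenance
  walign
}

#' @noRd
is_member <- function(accepted, h) {
  if (!nrow(accepted)) return(FALSE)
  same <- accepted$genome_id == h$genome_id & accepted$strand == h$strand
  if (!any(same)) return(FALSE)
  a <- accepted[same, , drop = FALSE]
  ov <- pmin(a$end0, h$end0) - pmax(a$start0, h$start0)
  wk <- h$end0 - h$start0
  wa <- a$end0 - a$start0
  any(ov > 0 & ov / wk > 0.5 & ov / pmax(wa, 1L) > 0.5)
}

# distance-from-alignment reweighting used while the alignment grows:
# UPGMA over per-column mismatch distances, then GSC
#' @noRd
reweight_alignment <- function(aln) {
  n <- length(aln$rows)
  if (n == 1L) return(weighted_alignment(aln))
  codes <- alignment_codes(aln)
  D <- matrix(0, n, n, dimnames = list(names(aln$rows), names(aln$rows)))
  for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    ok <- codes[a, ] <= 4L & codes[b, ] <= 4L
    D[a, b] <- D[b, a] <- if (any(ok)) {
      mean(codes[a, ok] != codes[b, ok])
    } else 1
  }
  hc <- hclust(as.dist(D), method = "average")
  gsc_weights(aln, ape::as.phylo(hc))
}
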