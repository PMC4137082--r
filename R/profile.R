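#' Build a motif profile from a weighted alignment
#'
#' Summarises a curated structured alignment as a sequence + structure
#' profile: weighted, pseudocounted per-column nucleotide frequencies
#' with a per-column gap frequency, plus a per-pair frequency table
#' over the 6 canonical pair types and an "other" category for every
#' consensus pair.
#'
#' @param walign `weighted_alignment`.
#' @param structure `consensus_structure` whose pairs are columns of
#'   `walign`.
#' @param alpha Laplace pseudocount (default 0.5) applied to the four
#'   nucleotide categories and the seven pair categories.
#' @param background nucleotide background distribution (default
#'   uniform 0.25).
#' @return Object of class `motif_profile`: list with `p` (4 x L
#'   nucleotide frequency matrix), `gapfreq` (length L), `pairs`
#'   (data frame `i`, `j`), `pairfreq` (7 x n_pairs matrix, rows
#'   `AU,UA,CG,GC,GU,UG,other`), `consensus` (majority-nucleotide
#'   string), `alpha`, `background`, `length`.
#' @export
build_profile <- function(walign, structure = NULL, alpha = 0.5,
                          background = rep(0.25, 4)) {
  aln <- walign$alignment
  if (!length(aln$rows)) stop("empty alignment")
  codes <- alignment_codes(aln)
  w <- walign$weights
  L <- ncol(codes)
  if (alpha < 0) stop("pseudocount alpha must be >= 0")

  p <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "U"), NULL))
  gapfreq <- numeric(L)
  for (c0 in seq_len(L)) {
    col <- codes[, c0]
    for (x in 1:4) p[x, c0] <- sum(w[col == x])
    gapfreq[c0] <- sum(w[col >= 5L])
  }
  denom <- colSums(p) + 4 * alpha
  p <- sweep(p + alpha, 2L, denom, "/")

  pairs <- if (!is.null(structure) && nrow(structure$pairs)) {
    structure$pairs[structure$pairs$tier == 1L, c("i", "j"), drop = FALSE]
  } else {
    data.frame(i = integer(0), j = integer(0))
  }
  pairfreq <- matrix(0, 7L, nrow(pairs),
                     dimnames = list(c(PAIR_TYPE_NAMES, "other"), NULL))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ci <- codes[, pairs$i[k]]; cj <- codes[, pairs$j[k]]
      idx <- ifelse(ci <= 4L & cj <= 4L, 6L * (ci - 1L) + cj, NA_integer_)
      type <- ifelse(is.na(idx), NA_integer_, CANONICAL_LOOKUP[idx])
      cnt <- numeric(7L)
      for (t in 1:6) cnt[t] <- sum(w[!is.na(type) & type == t])
      cnt[7L] <- 1 - sum(cnt[1:6])
      pairfreq[, k] <- (cnt + alpha) / (1 + 7 * alpha)
    }
  }
  consensus <- paste(rownames(p)[apply(p, 2L, which.max)], collapse = "")
  structure(list(p = p, gapfreq = gapfreq, pairs = pairs,
                 pairfreq = pairfreq, consensus = consensus,
                 alpha = alpha, background = background, length = L),
            class = "motif_profile")
}

#' Scan a genome with a motif profile
#'
#' Glocal dynamic programming: the profile must be matched end to end,
#' the sequence is local.  Per-column match scores are
#' `log2(p_col(x) / q(x))`; deleting a profile column costs a penalty
#' derived from its gap frequency; unmatched sequence insertions cost
#' a flat 2 bits each.  After traceback, consensus pairs whose matched
#' sequence nucleotides form a canonical pair receive a bonus
#' `beta * log2(p_pair(xy) / (q(x) q(y)))`.  Overlapping hits (over
#' 50% reciprocal overlap) are suppressed keeping the higher score.
#' Hits matching fewer than half the profile columns, or touching
#' unresolvable nucleotides (`N`), are discarded.
#'
#' @param profile `motif_profile`.
#' @param genome `genome_record`, `annotated_genome`, or a plain
#'   nucleotide string.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param beta pair-bonus weight (default 1.0).
#' @param max_hits cap on reported hits per strand (default 20).
#' @return data frame of hits: `genome_id`, `start0`, `end0` (0-based
#'   half-open forward-strand), `strand`, `raw_score` (bits), `evalue`
#'   (NA until calibrated), `aligned` (hit mapped to profile columns,
#'   `-` for deleted columns).  Sorted by decreasing score.
#' @export
scan_genome <- function(profile, genome, both_strands = TRUE, beta = 1.0,
                        max_hits = 20L) {
  if (inherits(genome, "annotated_genome")) genome <- genome$record
  if (inherits(genome, "genome_record")) {
    gid <- genome$id; seqchr <- genome$sequence
  } else {
    gid <- "seq"; seqchr <- toupper(as.character(genome))
  }
  n <- nchar(seqchr)
  if (n < profile$length) stop("genome shorter than profile")
  hits <- scan_strand(profile, seqchr, gid, "+", beta, max_hits)
  if (both_strands) {
    hits_m <- scan_strand(profile, revcomp_chr(seqchr), gid, "-", beta,
                          max_hits)
    if (nrow(hits_m)) {
      # map minus-strand coordinates back to the forward strand
      s0 <- n - hits_m$end0
      e0 <- n - hits_m$start0
      hits_m$start0 <- s0; hits_m$end0 <- e0
      hits <- rbind(hits, hits_m)
    }
  }
  if (nrow(hits)) {
    hits <- hits[order(-hits$raw_score), , drop = FALSE]
    hits <- suppress_overlaps(hits)
    if (nrow(hits) > max_hits) hits <- hits[seq_len(max_hits), ,
                                            drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' @noRd
profile_score_params <- function(profile) {
  q <- profile$background
  m <- log2(profile$p / q)            # 4 x L match scores
  g <- pmin(pmax(profile$gapfreq, 1e-3), 0.9)
  del <- pmax(log2(g / (1 - g)), -6)  # favour deleting gappy columns
  list(m = m, del = del, ins = -2)
}

#' @noRd
scan_strand <- function(profile, seqchr, gid, strand, beta, max_hits) {
  L <- profile$length
  n <- nchar(seqchr)
  sp <- profile_score_params(profile)
  x <- seq_to_codes(seqchr, rna = TRUE)
  # match score of column c against sequence position: N / other = -Inf
  BIG <- -1e9
  ms <- rbind(sp$m, BIG, BIG)         # 6 x L: rows indexed by code

  M <- matrix(0, L + 1L, n + 1L)
  ins <- sp$ins
  for (c0 in seq_len(L)) {
    mrow <- ms[cbind(x, rep(c0, n))]
    Tv <- pmax(M[c0, 1:n] + mrow, M[c0, 2:(n + 1L)] + sp$del[c0])
    U <- c(M[c0, 1L] + sp$del[c0], Tv - ins * (1:n))
    M[c0 + 1L, ] <- cummax(U) + ins * (0:n)
  }
  ends <- M[L + 1L, ]
  # candidate hit ends: local maxima of the end-score vector
  cand <- which(diff(sign(diff(c(-Inf, ends, -Inf)))) < 0)  # peaks, 1-based
  cand <- cand - 1L                    # sequence end position (0 = none)
  cand <- cand[cand >= 1L & ends[cand + 1L] > BIG / 2]
  if (!length(cand)) {
    return(empty_hits())
  }
  cand <- cand[order(-ends[cand + 1L])]
  cand <- head(cand, max_hits * 3L)

  res <- empty_hits()
  for (jend in cand) {
    tb <- traceback_glocal(M, sp, ms, x, jend)
    if (is.null(tb)) next
    if (tb$n_matched < L / 2) next
    raw <- ends[jend + 1L] + pair_bonus(profile, tb$aligned_codes, beta)
    res <- rbind(res, data.frame(
      genome_id = gid, start0 = tb$start, end0 = jend, strand = strand,
      raw_score = raw, evalue = NA_real_,
      aligned = codes_to_seq(tb$aligned_codes),
      stringsAsFactors = FALSE
    ))
  }
  res
}

#' @noRd
empty_hits <- function() {
  data.frame(genome_id = character(0), start0 = integer(0),
             end0 = integer(0), strand = character(0),
             raw_score = numeric(0), evalue = numeric(0),
             aligned = character(0), stringsAsFactors = FALSE)
}

#' @noRd
traceback_glocal <- function(M, sp, ms, x, jend) {
  L <- nrow(M) - 1L
  ins <- sp$ins
  eps <- 1e-9
  c0 <- L; j <- jend
  aligned <- integer(L)
  n_matched <- 0L
  while (c0 > 0L) {
    here <- M[c0 + 1L, j + 1L]
    if (j > 0L &&
        abs(here - (M[c0, j] + ms[x[j], c0])) < eps) {
      aligned[c0] <- x[j]
      n_matched <- n_matched + 1L
      c0 <- c0 - 1L; j <- j - 1L
    } else if (abs(here - (M[c0, j + 1L] + sp$del[c0])) < eps) {
      aligned[c0] <- 5L
      c0 <- c0 - 1L
    } else if (j > 0L &&
               abs(here - (M[c0 + 1L, j] + ins)) < eps) {
      j <- j - 1L
    } else {
      return(NULL)   # numerically ambiguous; skip candidate
    }
  }
  list(start = j, aligned_codes = aligned, n_matched = n_matched)
}

#' @noRd
pair_bonus <- function(profile, aligned_codes, beta) {
  if (!nrow(profile$pairs)) return(0)
  q2 <- profile$background[1L]^2      # uniform background assumed per pair
  bonus <- 0
  for (k in seq_len(nrow(profile$pairs))) {
    ci <- aligned_codes[profile$pairs$i[k]]
    cj <- aligned_codes[profile$pairs$j[k]]
    if (ci <= 4L && cj <= 4L) {
      t <- CANONICAL_LOOKUP[6L * (ci - 1L) + cj]
      if (!is.na(t)) {
        bonus <- bonus + beta * log2(profile$pairfreq[t, k] / q2)
      }
    }
  }
  bonus
}

#' @noRd
suppress_overlaps <- function(hits) {
  keep <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (hits$genome_id[j] != hits$genome_id[k]) next
      ov <- min(hits$end0[k], hits$end0[j]) -
        max(hits$start0[k], hits$start0[j])
      if (ov <= 0) next
      wk <- hits$end0[k] - hits$start0[k]
      wj <- hits$end0[j] - hits$start0[j]
      if (ov / wk > 0.5 && ov / wj > 0.5) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  hits[keep, , drop = FALSE]
}
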