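# Progressive multiple alignment: UPGMA guide tree over pairwise
# identity distances, then profile-profile Needleman-Wunsch merges up
# the tree.  Scoring is match +1 / mismatch -1 / gap -2 on weighted
# column frequencies, with deterministic tie-breaking.

# expected substitution score between two frequency profiles:
# S = t(FA) %*% M %*% FB over the 4 nucleotides (gap rows score 0 here;
# gaps are charged through the linear gap penalty instead)
PROFILE_MATCH <- local({
  m <- matrix(-1, 4, 4)
  diag(m) <- 1
  m
})

#' @noRd
profile_freqs <- function(codes) {
  # 5 x L frequency matrix over A,C,G,U,gap (code 6 treated as gap-like
  # unknown: contributes to neither match nor mismatch)
  L <- ncol(codes)
  f <- matrix(0, 5L, L)
  nr <- nrow(codes)
  for (x in 1:5) f[x, ] <- colSums(codes == x) / nr
  f
}

# Needleman-Wunsch on two profiles; returns merged code matrix.
# Vectorised row-wise; the within-row gap recurrence is resolved with a
# cummax scan (linear gap penalty).
#' @noRd
align_profiles <- function(mA, mB, gap = -2) {
  fA <- profile_freqs(mA); fB <- profile_freqs(mB)
  LA <- ncol(mA); LB <- ncol(mB)
  S <- t(fA[1:4, , drop = FALSE]) %*% PROFILE_MATCH %*%
    fB[1:4, , drop = FALSE]
  M <- matrix(0, LA + 1L, LB + 1L)
  M[1L, ] <- gap * (0:LB)
  M[, 1L] <- gap * (0:LA)
  for (i in seq_len(LA)) {
    Tv <- pmax(M[i, 1:LB] + S[i, ], M[i, 2:(LB + 1L)] + gap)
    U <- c(M[i + 1L, 1L], Tv - gap * (1:LB))
    M[i + 1L, ] <- cummax(U) + gap * (0:LB)
  }
  # traceback; prefer diagonal, then up (gap in B), then left
  i <- LA; j <- LB
  ops <- character(0)
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(M[i + 1L, j + 1L] - (M[i, j] + S[i, j])) < eps) {
      ops <- c("d", ops); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(M[i + 1L, j + 1L] - (M[i, j + 1L] + gap)) < eps) {
      ops <- c("u", ops); i <- i - 1L
    } else {
      ops <- c("l", ops); j <- j - 1L
    }
  }
  nA <- nrow(mA); nB <- nrow(mB)
  out <- matrix(5L, nA + nB, length(ops))
  rownames(out) <- c(rownames(mA), rownames(mB))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op != "l") { ia <- ia + 1L; out[1:nA, k] <- mA[, ia] }
    if (op != "u") { ib <- ib + 1L; out[nA + (1:nB), k] <- mB[, ib] }
  }
  out
}

#' Progressive alignment of a sequence cluster
#'
#' Builds a UPGMA guide tree from pairwise identity distances
#' (`d = 1 - identity`, computed with the free-end-gap aligner of
#' [pair_identity()]) and merges sequences up the tree by
#' profile-profile Needleman-Wunsch (match +1 / mismatch -1 / gap -2 on
#' column frequencies).  Ties are broken deterministically
#' (lexicographic by row id in the distance ordering).
#'
#' @param cluster a `leader_cluster`, a list of `leader_seq`s, or a
#'   named character vector of (ungapped) sequences.
#' @return `rna_alignment` with rows in input order and the guide tree
#'   (class `phylo`) in `$guide_tree`.  A single sequence is returned
#'   as a 1-row alignment with a warning.
#' @export
progressive_align <- function(cluster) {
  seqs <- cluster_sequences(cluster)
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in cluster")
  n <- length(seqs)
  if (n == 1L) {
    warning("single sequence: returning 1-row alignment")
    return(rna_alignment(seqs))
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (b in 2:n) {
    idn <- identity_cov_many(seqs[1:(b - 1L)], seqs[b])$identity
    D[1:(b - 1L), b] <- D[b, 1:(b - 1L)] <- 1 - idn
  }
  hc <- hclust(as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)

  mats <- lapply(seqs, function(s) {
    m <- matrix(seq_to_codes(s), nrow = 1L)
    m
  })
  for (k in seq_along(mats)) rownames(mats[[k]]) <- names(seqs)[k]
  nodes <- vector("list", nrow(hc$merge))
  fetch <- function(x) if (x < 0L) mats[[-x]] else nodes[[x]]
  for (k in seq_len(nrow(hc$merge))) {
    nodes[[k]] <- align_profiles(fetch(hc$merge[k, 1L]),
                                 fetch(hc$merge[k, 2L]))
  }
  final <- nodes[[length(nodes)]]
  final <- final[match(names(seqs), rownames(final)), , drop = FALSE]
  rows <- setNames(apply(final, 1L, codes_to_seq), rownames(final))
  rna_alignment(rows, guide_tree = tree)
}

#' @noRd
cluster_sequences <- function(cluster) {
  if (inherits(cluster, "leader_cluster")) cluster <- cluster$members
  if (is.character(cluster)) {
    seqs <- cluster
  } else if (is.list(cluster)) {
    seqs <- vapply(cluster, function(l) {
      if (is.character(l)) l else l$sequence
    }, character(1L))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      ids <- vapply(cluster, function(l) {
        if (is.character(l)) NA_character_ else l$genome_id
      }, character(1L))
      names(seqs) <- ifelse(is.na(ids), paste0("seq", seq_along(seqs)), ids)
    }
  } else {
    stop("cannot interpret cluster input")
  }
  names(seqs) <- make.unique(names(seqs) %||% paste0("seq", seq_along(seqs)))
  vapply(seqs, function(s) toupper(dna_to_rna(s)), character(1L))
}
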