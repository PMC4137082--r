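# Weighted covariation scoring of alignment column pairs.  This is the
# evidence class the curation of comparative-genomics alignments leans
# on: correlated double substitutions that preserve canonical pairing
# ("covarying"), single changes that still permit a canonical pair
# ("compatible"), and invariant canonical pairs ("conserved").

#' Score a candidate base-paired column pair
#'
#' For columns `i < j` of a weighted alignment, computes
#' \itemize{
#' \item a covariation score: sum over ordered row pairs `(a, b)` that
#'   are both canonical at `(i, j)` of `w_a * w_b * h_ab`, where
#'   `h_ab` in `{0, 1, 2}` counts the positions at which the two rows'
#'   pair types differ, minus an inconsistency penalty
#'   `phi *` (weight fraction of rows with a gap or a non-canonical
#'   combination);
#' \item the weighted mutual information (bits) of the two columns over
#'   gap-free rows (weights renormalised);
#' \item a pair class: `covarying` (at least 2 canonical pair types,
#'   some `h_ab = 2`), `compatible` (at least 2 types, max `h_ab = 1`),
#'   `conserved` (a single type carrying at least 75% of the weight),
#'   else `rejected`.
#' }
#' Canonical pairs are Watson-Crick plus wobble:
#' `AU, UA, CG, GC, GU, UG`.
#'
#' @param walign `weighted_alignment`.
#' @param i,j column indices with `i + 4 <= j` (minimum hairpin loop of
#'   3 columns).
#' @param phi inconsistency penalty weight (default 1.0).
#' @return Object of class `pair_evidence`: list with `i`, `j`,
#'   `score`, `mi`, `class`, `canonical_fraction`, `n_types`.
#' @export
pair_score <- function(walign, i, j, phi = 1.0) {
  if (i + 4L > j) stop("minimum hairpin loop is 3: need i + 4 <= j")
  codes <- alignment_codes(walign$alignment)
  ev <- pair_stats(codes, walign$weights, i, j, phi)
  structure(ev, class = "pair_evidence")
}

# workhorse, reused by fold_alignment over all column pairs
#' @noRd
pair_stats <- function(codes, w, i, j, phi = 1.0) {
  ci <- codes[, i]; cj <- codes[, j]
  if (all(ci == 5L) || all(cj == 5L)) {
    return(list(i = i, j = j, score = -Inf, mi = 0,
                class = "rejected", canonical_fraction = 0, n_types = 0L))
  }
  # canonical pair-type weights
  idx <- ifelse(ci <= 6L & cj <= 6L & ci <= 4L & cj <= 4L,
                6L * (ci - 1L) + cj, NA_integer_)
  type <- ifelse(is.na(idx), NA_integer_, CANONICAL_LOOKUP[idx])
  Wt <- numeric(6L)
  ok <- !is.na(type)
  if (any(ok)) {
    for (t in unique(type[ok])) Wt[t] <- sum(w[ok & type == t])
  }
  canonical_fraction <- sum(Wt)
  covariation <- as.numeric(t(Wt) %*% PAIR_DIFF %*% Wt)
  inconsistency <- phi * (1 - canonical_fraction)
  score <- covariation - inconsistency

  # weighted mutual information over gap-free rows
  mi <- 0
  gf <- ci <= 4L & cj <= 4L
  if (any(gf)) {
    P <- matrix(0, 4L, 4L)
    for (k in which(gf)) {
      P[ci[k], cj[k]] <- P[ci[k], cj[k]] + w[k]
    }
    P <- P / sum(P)
    pi_ <- rowSums(P); pj_ <- colSums(P)
    nz <- P > 0
    mi <- sum(P[nz] * log2(P[nz] / (pi_[row(P)[nz]] * pj_[col(P)[nz]])))
    mi <- max(mi, 0)
  }

  present <- which(Wt > 0)
  n_types <- length(present)
  hmax <- if (n_types >= 2L) {
    max(PAIR_DIFF[present, present])
  } else 0L
  cls <- if (n_types >= 2L && hmax == 2L) {
    "covarying"
  } else if (n_types >= 2L && hmax == 1L) {
    "compatible"
  } else if (n_types == 1L && canonical_fraction >= 0.75) {
    "conserved"
  } else {
    "rejected"
  }
  list(i = i, j = j, score = score, mi = mi, class = cls,
       canonical_fraction = canonical_fraction, n_types = n_types)
}

#' @export
print.pair_evidence <- function(x, ...) {
  cat("<pair_evidence> (", x$i, ",", x$j, ") score=", signif(x$score, 4),
      " mi=", signif(x$mi, 4), " class=", x$class, "\n", sep = "")
  invisible(x)
}
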