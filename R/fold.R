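#' Infer a consensus nested structure by covariation folding
#'
#' Nussinov-style dynamic programming that maximises the total
#' covariation score over non-crossing column pairs, considering only
#' pairs with [pair_score()] at least `tau` and hairpin loops of at
#' least 3 columns.  Traceback is deterministic (pairing preferred over
#' leaving the 3' column unpaired; the 5'-most pairing partner wins
#' ties).  Isolated pairs -- stacked runs shorter than `min_helix` --
#' are pruned post hoc.  Helices are named `H0, H1, ...` 5' to 3' by
#' their outermost opening column.
#'
#' @param walign `weighted_alignment`.
#' @param tau minimum pair score for a candidate pair (default 0.05).
#' @param min_helix minimum stacked run length (default 2).
#' @param phi inconsistency penalty passed to the pair scorer.
#' @return Object of class `consensus_structure`: list with `length`
#'   (number of columns), `pairs` (data frame: `i`, `j`, `score`,
#'   `mi`, `class`, `canonical_fraction`, `tier`, `helix`) and
#'   `helices` (data frame: `name`, `i_outer`, `j_outer`, `n_pairs`,
#'   `tss_support`).  No qualifying pairs yields a valid empty
#'   structure.
#' @export
fold_alignment <- function(walign, tau = 0.05, min_helix = 2L, phi = 1.0) {
  aln <- walign$alignment
  L <- nchar(aln$rows[[1L]])
  if (L < 2L) stop("alignment must have at least 2 columns")
  codes <- alignment_codes(aln)
  w <- walign$weights

  S <- matrix(-Inf, L, L)
  info <- vector("list", 0L)
  if (L >= 5L) {
    for (i in 1:(L - 4L)) for (j in (i + 4L):L) {
      st <- pair_stats(codes, w, i, j, phi)
      if (is.finite(st$score) && st$score >= tau) {
        S[i, j] <- st$score
        info[[paste(i, j)]] <- st
      }
    }
  }
  pairs <- nussinov_trace(S, L, tau)
  structure_from_pairs(pairs, info, L, min_helix)
}

# DP over candidate pair scores; S[i,j] finite only for qualifying pairs
#' @noRd
nussinov_trace <- function(S, L, tau) {
  if (L < 5L) return(matrix(integer(0), ncol = 2L))
  N <- matrix(0, L + 1L, L + 1L)  # N[i, j+1] = best score over cols i..j
  nv <- function(i, j) if (j < i) 0 else N[i, j + 1L]
  cand <- lapply(seq_len(L), function(j) which(is.finite(S[, j])))
  for (span in 5:L) {
    for (i in 1:(L - span + 1L)) {
      j <- i + span - 1L
      best <- N[i, j]  # j unpaired: cols i..j-1
      ks <- cand[[j]]
      ks <- ks[ks >= i & ks <= j - 4L]
      for (k in ks) {
        v <- nv(i, k - 1L) + nv(k + 1L, j - 1L) + S[k, j]
        if (v > best) best <- v
      }
      N[i, j + 1L] <- best
    }
  }
  # traceback, iterative stack; prefer pairing (5'-most k), then j unpaired
  out_i <- integer(0); out_j <- integer(0)
  stack <- list(c(1L, L))
  eps <- 1e-9
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    while (j - i >= 4L) {
      target <- nv(i, j)
      ks <- cand[[j]]
      ks <- ks[ks >= i & ks <= j - 4L]
      paired <- FALSE
      for (k in ks) {
        if (abs(nv(i, k - 1L) + nv(k + 1L, j - 1L) + S[k, j] - target) <
            eps) {
          out_i <- c(out_i, k); out_j <- c(out_j, j)
          if (k - 1L >= i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          i <- k + 1L; j <- j - 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) j <- j - 1L
    }
  }
  cbind(i = out_i, j = out_j)
}

#' @noRd
structure_from_pairs <- function(pairs, info, L, min_helix,
                                 tiers = NULL) {
  if (nrow(pairs)) {
    ord <- order(pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    if (!is.null(tiers)) tiers <- tiers[ord]
  }
  # group into stacked helices and prune short runs
  n <- nrow(pairs)
  helix_id <- integer(n)
  cur <- 0L
  has <- function(i, j) any(pairs[, 1L] == i & pairs[, 2L] == j)
  for (k in seq_len(n)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (k > 1L && has(i - 1L, j + 1L) &&
        (is.null(tiers) ||
           tiers[k] == tiers[which(pairs[, 1L] == i - 1L &
                                     pairs[, 2L] == j + 1L)][1L])) {
      helix_id[k] <- helix_id[which(pairs[, 1L] == i - 1L &
                                      pairs[, 2L] == j + 1L)][1L]
    } else {
      cur <- cur + 1L
      helix_id[k] <- cur
    }
  }
  keep <- helix_id %in% which(tabulate(helix_id) >= min_helix)
  pairs <- pairs[keep, , drop = FALSE]
  helix_id <- helix_id[keep]
  if (!is.null(tiers)) tiers <- tiers[keep]

  # name surviving helices 5'->3' by outermost opening column
  helices <- data.frame(name = character(0), i_outer = integer(0),
                        j_outer = integer(0), n_pairs = integer(0),
                        tss_support = character(0),
                        stringsAsFactors = FALSE)
  helix_name <- character(length(helix_id))
  if (length(helix_id)) {
    open_col <- vapply(split(pairs[, 1L], helix_id), min, numeric(1L))
    rank <- rank(open_col, ties.method = "first")
    name_of <- setNames(paste0("H", rank - 1L), names(open_col))
    helix_name <- name_of[as.character(helix_id)]
    helices <- data.frame(
      name = unname(name_of),
      i_outer = as.integer(open_col),
      j_outer = vapply(split(pairs[, 2L], helix_id), max, numeric(1L)),
      n_pairs = as.integer(tabulate(helix_id)[as.integer(names(open_col))]),
      tss_support = NA_character_,
      stringsAsFactors = FALSE
    )
    helices <- helices[order(helices$i_outer), , drop = FALSE]
    rownames(helices) <- NULL
  }

  get_info <- function(i, j, field, default) {
    st <- info[[paste(i, j)]]
    if (is.null(st)) default else st[[field]]
  }
  np <- nrow(pairs)
  pdf <- data.frame(
    i = as.integer(pairs[, 1L]),
    j = as.integer(pairs[, 2L]),
    score = vapply(seq_len(np), function(k)
      get_info(pairs[k, 1L], pairs[k, 2L], "score", NA_real_), numeric(1L)),
    mi = vapply(seq_len(np), function(k)
      get_info(pairs[k, 1L], pairs[k, 2L], "mi", NA_real_), numeric(1L)),
    class = vapply(seq_len(np), function(k)
      get_info(pairs[k, 1L], pairs[k, 2L], "class", NA_character_),
      character(1L)),
    canonical_fraction = vapply(seq_len(np), function(k)
      get_info(pairs[k, 1L], pairs[k, 2L], "canonical_fraction", NA_real_),
      numeric(1L)),
    tier = if (is.null(tiers)) rep(1L, np) else as.integer(tiers),
    helix = helix_name,
    stringsAsFactors = FALSE
  )
  structure(list(length = L, pairs = pdf, helices = helices),
            class = "consensus_structure")
}

#' Total score of a consensus structure
#'
#' @param structure `consensus_structure`.
#' @return Sum of retained pair scores.
#' @export
structure_score <- function(structure) {
  if (!nrow(structure$pairs)) return(0)
  sum(structure$pairs$score, na.rm = TRUE)
}

#' Merge two nested structures into a pseudoknotted annotation
#'
#' Takes the union of the two pair sets.  If the union is non-crossing
#' everything stays on tier 1; otherwise the structure whose outermost
#' opening column is 5'-most (ties: the one with more pairs) keeps
#' tier 1 and pairs of the other structure that cross it are marked as
#' pseudoknot tier 2.  No pair is deleted.  The tier assignment is
#' symmetric in the argument order.
#'
#' @param structure_a,structure_b `consensus_structure` objects over
#'   the same number of columns, each individually nested.
#' @return `consensus_structure` with a `tier` column distinguishing
#'   the pseudoknot layer.
#' @export
merge_pseudoknot <- function(structure_a, structure_b) {
  stopifnot(structure_a$length == structure_b$length)
  pa <- structure_a$pairs; pb <- structure_b$pairs
  cols_a <- c(pa$i, pa$j); cols_b <- c(pb$i, pb$j)
  clash <- intersect(cols_a, cols_b)
  if (length(clash)) {
    stop("pair conflict: column(s) ", paste(sort(clash), collapse = ", "),
         " used by both structures")
  }
  # order-independent: primary = 5'-most outermost opening column
  a_first <- if (!nrow(pa)) Inf else min(pa$i)
  b_first <- if (!nrow(pb)) Inf else min(pb$i)
  if (a_first < b_first ||
      (a_first == b_first && nrow(pa) >= nrow(pb))) {
    prim <- pa; sec <- pb
  } else {
    prim <- pb; sec <- pa
  }
  sec_tier <- rep(1L, nrow(sec))
  if (nrow(prim) && nrow(sec)) {
    for (k in seq_len(nrow(sec))) {
      i <- sec$i[k]; j <- sec$j[k]
      cross <- (prim$i < i & i < prim$j & prim$j < j) |
        (i < prim$i & prim$i < j & j < prim$j)
      if (any(cross)) sec_tier[k] <- 2L
    }
  }
  all_pairs <- rbind(
    cbind(i = prim$i, j = prim$j),
    cbind(i = sec$i, j = sec$j)
  )
  tiers <- c(rep(1L, nrow(prim)), sec_tier)
  info <- list()
  put <- function(df) {
    for (k in seq_len(nrow(df))) {
      info[[paste(df$i[k], df$j[k])]] <<- list(
        score = df$score[k], mi = df$mi[k], class = df$class[k],
        canonical_fraction = df$canonical_fraction[k]
      )
    }
  }
  put(prim); put(sec)
  structure_from_pairs(all_pairs, info, structure_a$length,
                       min_helix = 1L, tiers = tiers)
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat("<consensus_structure> ", x$length, " columns, ",
      nrow(x$pairs), " pairs in ", nrow(x$helices), " helices\n", sep = "")
  if (nrow(x$helices)) {
    for (k in seq_len(nrow(x$helices))) {
      h <- x$helices[k, ]
      cat("  ", h$name, ": cols ", h$i_outer, "..", h$j_outer, " (",
          h$n_pairs, " bp)",
          if (!is.na(h$tss_support)) paste0(" [", h$tss_support, "]"),
          "\n", sep = "")
    }
  }
  invisible(x)
}
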