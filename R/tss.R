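#' Call a transcription start site from a coverage step
#'
#' Single change-point segmentation of a per-base read-depth window
#' under a Poisson model: for every candidate breakpoint the
#' two-segment log-likelihood (segment means as rates) is compared to
#' the one-segment log-likelihood, and the breakpoint maximising the
#' gain is the putative TSS.  A call is accepted only if the
#' downstream mean is at least `min_fold` times the upstream mean
#' (floored at 0.5) and at least `min_depth`; ties are broken 5'-most.
#' The call position is invariant to uniform depth scaling.
#'
#' @param profile `coverage_profile` (depth oriented 5' to 3' of the
#'   gene; window length >= 20).
#' @param min_fold minimum downstream/upstream fold change (default 3).
#' @param min_depth minimum downstream mean depth (default 5).
#' @return Object of class `tss_call` -- list with `position` (genomic
#'   0-based coordinate of the first transcribed base), `offset`
#'   (0-based index within the oriented window), `confidence`
#'   (log-likelihood-ratio score), `upstream_mean`, `downstream_mean`,
#'   `genome_id`, `strand` -- or `NULL` when no acceptable step exists
#'   (flat profiles are a no-call, not an error).
#' @export
call_tss <- function(profile, min_fold = 3.0, min_depth = 5.0) {
  x <- profile$depth
  n <- length(x)
  if (n < 20L) stop("coverage window must be at least 20 bases")
  cs <- cumsum(x)
  tot <- cs[n]
  # Poisson profile log-likelihood of a segment with total S, length m:
  # S log(S/m) - S  (the x! term is constant in the breakpoint)
  seg_ll <- function(S, m) ifelse(S > 0, S * log(S / m) - S, 0)
  t <- 1:(n - 1L)                      # downstream starts at index t (0-based)
  ll2 <- seg_ll(cs[t], t) + seg_ll(tot - cs[t], n - t)
  ll1 <- seg_ll(tot, n)
  gain <- ll2 - ll1
  best <- which.max(gain)              # which.max takes the first (5'-most)
  up_mean <- cs[best] / best
  down_mean <- (tot - cs[best]) / (n - best)
  if (!(down_mean >= min_fold * max(up_mean, 0.5) &&
          down_mean >= min_depth)) {
    return(NULL)
  }
  position <- if (profile$strand == "+") {
    profile$window[1L] + best
  } else {
    profile$window[2L] - 1L - best
  }
  structure(list(position = as.integer(position), offset = as.integer(best),
                 confidence = gain[best], upstream_mean = up_mean,
                 downstream_mean = down_mean,
                 genome_id = profile$genome_id, strand = profile$strand),
            class = "tss_call")
}

#' Flag helices not supported by the transcript boundary
#'
#' Maps a TSS call into alignment columns through an example row with
#' known genomic coordinates and flags every helix of the structure:
#' `unsupported` when both its 5' and 3' extents lie 5' of the TSS
#' column (predicted by comparative genomics but not transcribed),
#' `conflicted` when it straddles the TSS, `supported` otherwise.
#' Pair sets are never altered, only flagged; helix names are kept so
#' that dropping an untranscribed 5' helix leaves the remaining names
#' unchanged.
#'
#' @param structure `consensus_structure`.
#' @param alignment `rna_alignment` containing `example_row`.
#' @param tss `tss_call` on the example row's genome.
#' @param example_row a `leader_seq` (preferred: carries genomic
#'   region and strand) whose genome matches `tss`, or the name of an
#'   alignment row together with `region`/`strand` attributes.
#' @return `structure` with `helices$tss_support` filled and
#'   `tss_column` recorded.
#' @export
truncate_to_transcript <- function(structure, alignment, tss, example_row) {
  if (!inherits(example_row, "leader_seq")) {
    stop("example_row must be a leader_seq with genomic region and strand")
  }
  row_name <- example_row$genome_id
  idx <- match(row_name, names(alignment$rows))
  if (is.na(idx)) {
    idx <- match(row_name, sub("/.*", "", names(alignment$rows)))
  }
  if (is.na(idx)) stop("example row '", row_name, "' not in alignment")
  row <- alignment$rows[[idx]]

  # genomic position -> 0-based position within the leader sequence
  r <- example_row$region
  p <- if (example_row$strand == "+") {
    tss$position - r[1L]
  } else {
    r[2L] - 1L - tss$position
  }
  len <- r[2L] - r[1L]
  if (p < 0L || p >= len) {
    stop("TSS at ", tss$position, " falls outside the aligned region [",
         r[1L], ",", r[2L], ") of ", row_name)
  }
  # leader position -> alignment column ((p+1)-th non-gap character)
  ch <- strsplit(row, "", fixed = TRUE)[[1L]]
  nong <- which(!ch %in% c("-", "."))
  if (p + 1L > length(nong)) stop("TSS beyond the end of the example row")
  tss_col <- nong[p + 1L]

  h <- structure$helices
  if (nrow(h)) {
    h$tss_support <- ifelse(
      h$j_outer < tss_col, "unsupported",
      ifelse(h$i_outer < tss_col, "conflicted", "supported")
    )
    structure$helices <- h
  }
  structure$tss_column <- tss_col
  structure
}

#' Convert between internal and leader-relative positions
#'
#' Leader-relative numbering follows the field convention for 5'
#' regions: `+1` is the A of the start codon, `-1` the base
#' immediately 5' of it, and there is no position 0.
#'
#' @param pos0 0-based position(s) within a leader sequence.
#' @param start_codon_offset 0-based index of the A of AUG in the same
#'   sequence.
#' @return integer relative position(s).
#' @export
leader_relative_position <- function(pos0, start_codon_offset) {
  as.integer(ifelse(pos0 >= start_codon_offset,
                    pos0 - start_codon_offset + 1L,
                    pos0 - start_codon_offset))
}

#' @rdname leader_relative_position
#' @param rel relative position(s) (no 0 allowed).
#' @export
leader_absolute_position <- function(rel, start_codon_offset) {
  if (any(rel == 0L)) stop("relative position 0 does not exist")
  as.integer(ifelse(rel > 0L, rel - 1L + start_codon_offset,
                    rel + start_codon_offset))
}

#' @export
print.tss_call <- function(x, ...) {
  cat("<tss_call> ", x$genome_id, " position ", x$position, " (",
      x$strand, "), ", round(x$upstream_mean, 2), " -> ",
      round(x$downstream_mean, 2), " (LLR ", round(x$confidence, 1),
      ")\n", sep = "")
  invisible(x)
}
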