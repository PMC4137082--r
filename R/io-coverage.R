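#' Construct a per-base coverage profile
#'
#' @param genome_id accession string.
#' @param window integer vector `c(start0, end0)`, 0-based half-open,
#'   forward strand.
#' @param depth numeric vector of per-base depth, length
#'   `window[2] - window[1]`, oriented 5' to 3' of the gene of interest
#'   (see `strand`).
#' @param strand `"+"` (depth runs left-to-right along the genome) or
#'   `"-"` (depth is the reversed window, so `depth[1]` is the base at
#'   `window[2] - 1`).
#' @return Object of class `coverage_profile`.
#' @export
coverage_profile <- function(genome_id, window, depth, strand = "+") {
  window <- as.integer(window)
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("window must be c(start0, end0) with end0 > start0")
  }
  if (length(depth) != window[2L] - window[1L]) {
    stop("depth length ", length(depth), " != window length ",
         window[2L] - window[1L])
  }
  if (any(depth < 0)) stop("negative depth values")
  stopifnot(strand %in% c("+", "-"))
  structure(list(genome_id = genome_id, window = window,
                 depth = as.numeric(depth), strand = strand),
            class = "coverage_profile")
}

#' Read per-base coverage from bedGraph
#'
#' bedGraph intervals are 0-based half-open.  Bases of the requested
#' window not covered by any interval get depth 0.  Overlapping
#' intervals with conflicting values raise an error.
#'
#' @param path bedGraph file.
#' @param genome_id chromosome/accession to extract.
#' @param window `c(start0, end0)` 0-based half-open window.
#' @param strand orientation of the gene of interest (see
#'   [coverage_profile()]).
#' @return `coverage_profile` over `window`.
#' @export
read_coverage <- function(path, genome_id, window, strand = "+") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == genome_id]
  window <- as.integer(window)
  n <- window[2L] - window[1L]
  depth <- numeric(n)
  seen <- rep(NA_real_, n)
  if (length(gr)) {
    s0 <- GenomicRanges::start(gr) - 1L   # back to 0-based half-open
    e0 <- GenomicRanges::end(gr)
    val <- GenomicRanges::mcols(gr)$score
    for (k in seq_along(gr)) {
      lo <- max(s0[k], window[1L]); hi <- min(e0[k], window[2L])
      if (lo >= hi) next
      idx <- (lo - window[1L] + 1L):(hi - window[1L])
      conflict <- !is.na(seen[idx]) & seen[idx] != val[k]
      if (any(conflict)) {
        stop("overlapping bedGraph intervals with conflicting values at ",
             genome_id, ":", lo + which(conflict)[1L] - 1L)
      }
      seen[idx] <- val[k]
      depth[idx] <- val[k]
    }
  }
  coverage_profile(genome_id, window, depth, strand = strand)
}

#' Write a coverage profile as bedGraph
#'
#' Runs of equal depth are merged into intervals; zero-depth runs are
#' omitted (bedGraph convention).  A profile with `strand == "-"` is
#' written in genome orientation.
#'
#' @param profile `coverage_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(profile, path) {
  depth <- profile$depth
  if (profile$strand == "-") depth <- rev(depth)
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s",
                   profile$genome_id,
                   profile$window[1L] + starts[keep] - 1L,
                   profile$window[1L] + ends[keep],
                   format(r$values[keep], trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> ", x$genome_id, " [", x$window[1L], ",",
      x$window[2L], ") strand ", x$strand, ", mean depth ",
      round(mean(x$depth), 2), "\n", sep = "")
  invisible(x)
}
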