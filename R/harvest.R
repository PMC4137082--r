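#' Locate the target gene in an annotated genome
#'
#' Looks the gene up in the annotation by name or product
#' (case-insensitive).  If no annotated match exists and a query
#' protein is supplied, all six reading frames are translated and
#' scanned by Smith-Waterman local alignment (BLOSUM62, gap open 11 /
#' extend 1); the implied CDS interval of the best hit above
#' `min_score` is returned (extended to include an immediately
#' following stop codon).
#'
#' @param genome `annotated_genome`.
#' @param gene_name gene symbol, e.g. `"rpsO"`.
#' @param query_protein optional amino-acid string for the translated
#'   fallback scan.
#' @param min_score minimum raw Smith-Waterman score; defaults to
#'   `2 * nchar(query_protein)`.
#' @return One-row feature data frame (`genome_id`, `name`, `start`,
#'   `end`, `strand`, 1-based inclusive).
#' @export
locate_gene <- function(genome, gene_name, query_protein = NULL,
                        min_score = NULL) {
  if (!nzchar(gene_name)) stop("gene_name must be non-empty")
  f <- genome$features
  hit <- which(tolower(f$name) == tolower(gene_name) |
                 (!is.na(f$product) &
                    grepl(gene_name, f$product, ignore.case = TRUE)))
  # a gene may carry both a 'gene' and a 'CDS' record; prefer CDS rows,
  # and collapse records spanning the same interval
  if (length(hit) > 1L) {
    h <- f[hit, , drop = FALSE]
    key <- paste(h$start, h$end, h$strand)
    if (length(unique(key)) == 1L) {
      cds <- which(h$type == "CDS")
      hit <- hit[if (length(cds)) cds[1L] else 1L]
    } else {
      stop("ambiguous gene name '", gene_name, "': candidates at ",
           paste(unique(paste0(h$start, "-", h$end, h$strand)),
                 collapse = ", "))
    }
  }
  if (length(hit) == 1L) {
    return(f[hit, c("genome_id", "name", "type", "start", "end", "strand"),
             drop = FALSE])
  }
  if (is.null(query_protein)) {
    stop("gene '", gene_name, "' not found in annotation of ",
         genome$record$id, " and no query_protein given")
  }
  sixframe_locate(genome, gene_name, query_protein, min_score)
}

#' @noRd
sixframe_locate <- function(genome, gene_name, query_protein, min_score) {
  seqchr <- genome$record$sequence
  n <- nchar(seqchr)
  if (is.null(min_score)) min_score <- 2 * nchar(query_protein)
  b62 <- get_blosum62()
  query <- Biostrings::AAString(toupper(query_protein))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqchr else revcomp_chr(seqchr)
    for (frame in 0:2) {
      len <- n - frame
      len <- len - (len %% 3L)
      if (len < 3L) next
      sub <- substr(s, frame + 1L, frame + len)
      aa <- suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X"
      ))
      al <- Biostrings::pairwiseAlignment(
        pattern = query, subject = aa, type = "local",
        substitutionMatrix = b62, gapOpening = 11, gapExtension = 1
      )
      sc <- Biostrings::score(al)
      if (is.null(best) || sc > best$score) {
        sa <- Biostrings::subject(al)
        best <- list(score = sc, strand = strand, frame = frame,
                     aa_start = Biostrings::start(sa),
                     aa_end = Biostrings::end(sa))
      }
    }
  }
  if (is.null(best) || best$score < min_score) {
    stop("no translated hit for '", gene_name, "' above score ", min_score)
  }
  # nucleotide interval on the scanned strand, then map to forward coords
  nt_start <- best$frame + 3L * (best$aa_start - 1L) + 1L
  nt_end <- best$frame + 3L * best$aa_end
  s <- if (best$strand == "+") seqchr else revcomp_chr(seqchr)
  if (nt_end + 3L <= n &&
      substr(s, nt_end + 1L, nt_end + 3L) %in% c("TAA", "TAG", "TGA")) {
    nt_end <- nt_end + 3L
  }
  if (best$strand == "+") {
    start <- nt_start; end <- nt_end
  } else {
    start <- n - nt_end + 1L; end <- n - nt_start + 1L
  }
  data.frame(genome_id = genome$record$id, name = gene_name, type = "CDS",
             start = start, end = end, strand = best$strand,
             stringsAsFactors = FALSE)
}

#' @noRd
get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Extract the putative 5' leader of a gene
#'
#' Collects up to `upstream_max` nucleotides 5' of the translation
#' start -- truncated at the 3' end of the nearest annotated feature
#' upstream on either strand, and at contig edges -- plus the first
#' `coding_tail` nucleotides of the coding region.  Output is in mRNA
#' orientation (reverse-complemented for minus-strand genes) as RNA.
#'
#' @param genome `annotated_genome`.
#' @param gene one-row feature data frame as returned by
#'   [locate_gene()].
#' @param upstream_max maximum upstream span (default 500).
#' @param coding_tail coding nucleotides appended (default 25).
#' @return Object of class `leader_seq`: list with `genome_id`,
#'   `gene_name`, `sequence` (RNA), `region` (`c(start0, end0)`
#'   forward-strand internal coordinates), `strand`,
#'   `offset_of_start_codon` (0-based index of the A of AUG within
#'   `sequence`), `taxonomy`, and `truncated` (TRUE when the upstream
#'   span collapsed to zero).
#' @export
extract_leader <- function(genome, gene, upstream_max = 500L,
                           coding_tail = 25L) {
  seqchr <- genome$record$sequence
  n <- nchar(seqchr)
  stopifnot(gene$start >= 1L, gene$end <= n)
  f <- genome$features
  # exclude the target itself (same interval)
  f <- f[!(f$start == gene$start & f$end == gene$end), , drop = FALSE]
  tail_len <- min(coding_tail, gene$end - gene$start + 1L)

  if (gene$strand == "+") {
    s <- gene$start                       # translation start, 1-based
    prev <- f$end[f$end < s]
    gap <- if (length(prev)) s - 1L - max(prev) else s - 1L
    span <- min(upstream_max, max(gap, 0L))
    up <- if (span > 0L) substr(seqchr, s - span, s - 1L) else ""
    cod <- substr(seqchr, s, s + tail_len - 1L)
    region <- c(s - span - 1L, s + tail_len - 1L)   # 0-based half-open
    mrna <- paste0(up, cod)
  } else {
    s <- gene$end
    nxt <- f$start[f$start > s]
    gap <- if (length(nxt)) min(nxt) - s - 1L else n - s
    span <- min(upstream_max, max(gap, 0L))
    up <- if (span > 0L) substr(seqchr, s + 1L, s + span) else ""
    cod <- substr(seqchr, s - tail_len + 1L, s)
    region <- c(s - tail_len, s + span)
    mrna <- revcomp_chr(paste0(cod, up))
  }
  structure(list(
    genome_id = genome$record$id,
    gene_name = gene$name,
    sequence = dna_to_rna(mrna),
    region = as.integer(region),
    strand = gene$strand,
    offset_of_start_codon = as.integer(span),
    taxonomy = genome$record$taxonomy,
    truncated = span == 0L
  ), class = "leader_seq")
}

#' Pairwise identity and coverage between two sequences
#'
#' Global alignment with free end gaps (match +1, mismatch -1, gap -2).
#' Identity is matches / aligned columns excluding the end-gap
#' overhangs; coverage is the aligned (non-gap) span of the shorter
#' sequence divided by its length.
#'
#' @param a,b character sequences (RNA or DNA; normalised to RNA).
#' @param match,mismatch,gap scoring parameters.
#' @return list with `identity` and `coverage`.
#' @export
pair_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  res <- identity_cov_many(a, b, match, mismatch, gap)
  list(identity = res$identity[1L], coverage = res$coverage[1L])
}

# vectorised core: many patterns against one subject in a single
# pairwiseAlignment call (the per-call overhead dominates otherwise)
#' @noRd
identity_cov_many <- function(patterns, subject, match = 1, mismatch = -1,
                              gap = -2) {
  patterns <- toupper(dna_to_rna(patterns))
  subject <- toupper(dna_to_rna(subject))
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "RNA"
  )
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::RNAStringSet(patterns),
    subject = Biostrings::RNAString(subject),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = abs(gap)
  )
  ncols <- Biostrings::nchar(al)      # aligned region incl internal gaps
  idn <- ifelse(ncols > 0, Biostrings::nmatch(al) / ncols, 0)
  wp <- IRanges::width(Biostrings::pattern(al))   # pattern span consumed
  ws <- IRanges::width(Biostrings::subject(al))
  plen <- nchar(patterns); slen <- nchar(subject)
  short_cols <- ifelse(plen <= slen, wp, ws)
  cov <- short_cols / pmin(plen, slen)
  data.frame(identity = idn, coverage = cov)
}

#' Remove redundant leader sequences
#'
#' Greedy, order-stable redundancy filter: leaders are visited in input
#' order and one is dropped when it exceeds `id_threshold` identity to
#' an already-kept leader over more than `cov_threshold` of the shorter
#' sequence's length (see [pair_identity()] for the alignment model).
#' The first occurrence of any sequence content is always kept, and the
#' filter is idempotent.
#'
#' @param leaders list of `leader_seq` objects (or character sequences).
#' @param id_threshold identity above which a pair is redundant
#'   (default 0.90).
#' @param cov_threshold minimum aligned fraction of the shorter
#'   sequence (default 0.70).
#' @return The kept subset, in input order.
#' @export
dedupe <- function(leaders, id_threshold = 0.90, cov_threshold = 0.70) {
  if (!length(leaders)) return(leaders)
  seqs <- vapply(leaders, function(l) {
    if (is.character(l)) l else l$sequence
  }, character(1L))
  kept <- integer(0)
  for (k in seq_along(seqs)) {
    redundant <- FALSE
    if (length(kept)) {
      pid <- identity_cov_many(seqs[kept], seqs[k])
      redundant <- any(pid$identity > id_threshold &
                         pid$coverage > cov_threshold)
    }
    if (!redundant) kept <- c(kept, k)
  }
  leaders[kept]
}

#' Cluster leaders by taxonomy into bounded groups
#'
#' Groups leaders by the deepest taxonomy prefix such that every group
#' has at most `max_size` members: grouping starts at the rank below
#' the domain and any oversized group is split recursively by its next
#' rank.  Groups that cannot be split further are chunked
#' deterministically (lexicographic by `genome_id`).  Leaders with
#' empty taxonomy form "unclassified" group(s).
#'
#' @param leaders list of `leader_seq` objects.
#' @param max_size maximum cluster size (default 100).
#' @return List of objects of class `leader_cluster`, each with
#'   `label` (taxonomy prefix) and `members`.
#' @export
cluster_by_taxonomy <- function(leaders, max_size = 100L) {
  if (!length(leaders)) return(list())
  tax <- lapply(leaders, function(l) l$taxonomy %||% character(0))
  ids <- vapply(leaders, function(l) l$genome_id, character(1L))

  chunk <- function(idx, label) {
    idx <- idx[order(ids[idx])]
    parts <- split(idx, ceiling(seq_along(idx) / max_size))
    lapply(seq_along(parts), function(p) {
      lab <- if (length(parts) > 1L) {
        paste0(label, ";chunk", p)
      } else label
      structure(list(label = lab, members = leaders[parts[[p]]]),
                class = "leader_cluster")
    })
  }

  recurse <- function(idx, rank, label) {
    if (length(idx) <= max_size) {
      return(list(structure(list(label = label, members = leaders[idx]),
                            class = "leader_cluster")))
    }
    depths <- vapply(tax[idx], length, integer(1L))
    if (all(depths < rank)) return(chunk(idx, label))
    keys <- vapply(tax[idx], function(t) {
      if (length(t) >= rank) t[rank] else "<none>"
    }, character(1L))
    out <- list()
    for (key in sort(unique(keys))) {
      sub <- idx[keys == key]
      sub_label <- if (key == "<none>") label else {
        if (nzchar(label)) paste0(label, ";", key) else key
      }
      out <- c(out, recurse(sub, rank + 1L, sub_label))
    }
    out
  }

  has_tax <- vapply(tax, length, integer(1L)) > 0L
  clusters <- list()
  if (any(has_tax)) {
    idx <- which(has_tax)
    # rank 1 is the domain; grouping starts one rank below it
    first <- vapply(tax[idx], function(t) {
      if (length(t) >= 2L) t[2L] else t[1L]
    }, character(1L))
    for (key in sort(unique(first))) {
      sub <- idx[first == key]
      dom <- tax[[sub[1L]]][1L]
      lab <- if (length(tax[[sub[1L]]]) >= 2L) paste0(dom, ";", key) else dom
      clusters <- c(clusters, recurse(sub, 3L, lab))
    }
  }
  if (any(!has_tax)) {
    clusters <- c(clusters, chunk(which(!has_tax), "unclassified"))
  }
  clusters
}

#' @export
print.leader_seq <- function(x, ...) {
  cat("<leader_seq> ", x$genome_id, " ", x$gene_name, ": ",
      nchar(x$sequence), " nt (", x$strand, "), start codon at +",
      x$offset_of_start_codon, "\n", sep = "")
  invisible(x)
}

#' @export
print.leader_cluster <- function(x, ...) {
  cat("<leader_cluster> '", x$label, "': ", length(x$members),
      " members\n", sep = "")
  invisible(x)
}
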