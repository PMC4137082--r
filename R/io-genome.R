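#' Read an annotated genome
#'
#' Reads a genome sequence (FASTA), its gene annotation (GFF3) and an
#' optional taxonomy table into an `annotated_genome` object.  GFF3
#' coordinates (1-based, inclusive, forward strand) are preserved in the
#' feature table; every internal computation in this package uses 0-based
#' half-open coordinates obtained through [gff_to_internal()], so the
#' conversion happens at exactly one boundary.
#'
#' @param path FASTA file with a single sequence record.  `U` is
#'   normalised to `T` on read; the alphabet is restricted to `ACGTN`.
#' @param annotation_path GFF3 file whose `seqid` matches the FASTA
#'   header id.
#' @param taxonomy_path optional two-column tab-separated table
#'   (accession, semicolon-delimited lineage).  Absent taxonomy is
#'   allowed; downstream clustering then falls back to an
#'   "unclassified" group.
#'
#' @return An object of class `annotated_genome`: a list with `record`
#'   (class `genome_record`: `id`, `sequence`, `taxonomy`) and
#'   `features`, a data frame with columns `genome_id`, `name`, `type`,
#'   `start`, `end`, `strand`, `product` (GFF3 coordinates).
#' @export
read_genome <- function(path, annotation_path, taxonomy_path = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (!file.exists(annotation_path)) {
    stop("GFF3 file not found: ", annotation_path)
  }
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) < 1L) stop("no sequence records in ", path)
  id <- sub("\\s.*$", "", names(dss)[1L])
  sequence <- toupper(chartr("U", "T", as.character(dss[[1L]])))
  if (nchar(sequence) == 0L) stop("empty sequence in ", path)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }

  validate_gff_lines(annotation_path)
  gr <- rtracklayer::import(annotation_path, format = "gff3")
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr) && !any(seqids == id)) {
    stop("GFF3 seqid(s) [", paste(unique(seqids), collapse = ","),
         "] do not match FASTA id '", id, "'")
  }
  gr <- gr[seqids == id]
  md <- as.data.frame(GenomicRanges::mcols(gr))
  pick <- function(cols) {
    for (cn in cols) {
      if (cn %in% names(md)) {
        v <- as.character(md[[cn]])
        if (any(!is.na(v))) return(v)
      }
    }
    rep(NA_character_, length(gr))
  }
  features <- data.frame(
    genome_id = rep(id, length(gr)),
    name = pick(c("gene", "Name", "locus_tag", "ID")),
    type = as.character(md$type %||% rep(NA_character_, length(gr))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = pick("product"),
    stringsAsFactors = FALSE
  )
  # drop region-level records, keep gene-like features
  features <- features[!features$type %in% c("region", "chromosome"), ,
                       drop = FALSE]
  bad <- which(features$start < 1L | features$end > nchar(sequence) |
                 features$start > features$end)
  if (length(bad)) {
    stop("feature out of genome bounds: ",
         paste(features$name[bad], collapse = ", "))
  }
  features$strand[!features$strand %in% c("+", "-")] <- "+"
  rownames(features) <- NULL

  taxonomy <- character(0)
  if (!is.null(taxonomy_path)) {
    tab <- read.delim(taxonomy_path, header = FALSE,
                      stringsAsFactors = FALSE)
    hit <- match(id, tab[[1L]])
    if (!is.na(hit)) {
      taxonomy <- strsplit(tab[[2L]][hit], ";", fixed = TRUE)[[1L]]
      taxonomy <- trimws(taxonomy)
    }
  }

  record <- structure(
    list(id = id, sequence = sequence, taxonomy = taxonomy),
    class = "genome_record"
  )
  structure(list(record = record, features = features),
            class = "annotated_genome")
}

# cheap structural validation so malformed lines are reported by number
#' @noRd
validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf != 9L) {
      stop("malformed GFF line ", k, ": expected 9 tab-separated fields, got ",
           nf)
    }
  }
  invisible(TRUE)
}

#' Write an annotated genome to FASTA + GFF3
#'
#' Inverse of [read_genome()] (round-trip identity on the record id,
#' sequence and feature table).
#'
#' @param genome `annotated_genome` object.
#' @param path output FASTA path.
#' @param annotation_path output GFF3 path.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, path, annotation_path) {
  rec <- genome$record
  dss <- Biostrings::DNAStringSet(rec$sequence)
  names(dss) <- rec$id
  Biostrings::writeXStringSet(dss, path, width = 70L)
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = rec$id,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand
  )
  GenomicRanges::mcols(gr)$type <- f$type
  GenomicRanges::mcols(gr)$gene <- f$name
  GenomicRanges::mcols(gr)$ID <-
    paste0(f$name, "_", seq_len(nrow(f)))
  GenomicRanges::mcols(gr)$phase <-
    ifelse(f$type == "CDS", 0L, NA_integer_)
  if (any(!is.na(f$product))) GenomicRanges::mcols(gr)$product <- f$product
  rtracklayer::export(gr, annotation_path, format = "gff3")
  invisible(genome)
}

#' Convert GFF3 feature coordinates to internal coordinates
#'
#' Internal coordinates throughout the package are 0-based half-open on
#' the forward strand; GFF3 is 1-based inclusive.  The two converters
#' are exact inverses.
#'
#' @param features data frame with `start`, `end` columns (1-based
#'   inclusive).
#' @return The same data frame with `start0` (= start - 1) and `end0`
#'   (= end) columns replacing `start`/`end`.
#' @export
gff_to_internal <- function(features) {
  out <- features
  out$start0 <- features$start - 1L
  out$end0 <- features$end
  out$start <- NULL
  out$end <- NULL
  out
}

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(features) {
  out <- features
  out$start <- features$start0 + 1L
  out$end <- features$end0
  out$start0 <- NULL
  out$end0 <- NULL
  out
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$record$id, ": ",
      nchar(x$record$sequence), " nt, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}
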