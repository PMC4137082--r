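#' Construct an RNA alignment object
#'
#' @param rows named character vector of equal-length gapped sequences
#'   over `{A,C,G,U,-}` (`T` is normalised to `U`).
#' @param structure optional dot-bracket consensus structure line of the
#'   same length (may use `<>`, `()`, `[]`, `{}` and `Aa`-style
#'   pseudoknot letters).
#' @param metadata named character vector of free-text annotations
#'   (Stockholm `#=GF`).
#' @param gc named character vector of extra per-column annotation lines
#'   (Stockholm `#=GC` other than `SS_cons`), each the alignment length.
#' @param guide_tree optional `phylo` guide tree (attached by
#'   [progressive_align()]).
#' @return Object of class `rna_alignment`.
#' @export
rna_alignment <- function(rows, structure = NULL, metadata = character(0),
                          gc = character(0), guide_tree = NULL) {
  rows <- vapply(rows, function(s) toupper(dna_to_rna(s)), character(1L))
  if (is.null(names(rows)) || any(names(rows) == "")) {
    names(rows) <- paste0("seq", seq_along(rows))
  }
  w <- unique(nchar(rows))
  if (length(w) != 1L) {
    stop("ragged alignment: row lengths ", paste(w, collapse = ", "))
  }
  if (!is.null(structure)) {
    if (nchar(structure) != w) {
      stop("structure line length ", nchar(structure),
           " does not match alignment length ", w)
    }
    check_balanced_structure(structure)
  }
  structure(list(rows = rows, structure = structure, metadata = metadata,
                 gc = gc, guide_tree = guide_tree),
            class = "rna_alignment")
}

#' @noRd
check_balanced_structure <- function(ss) {
  ch <- strsplit(ss, "", fixed = TRUE)[[1L]]
  openers <- c("<" = ">", "(" = ")", "[" = "]", "{" = "}",
               setNames(letters, LETTERS))
  stacks <- list()
  for (c0 in ch) {
    if (c0 %in% names(openers)) {
      key <- openers[[c0]]
      stacks[[key]] <- c(stacks[[key]] %||% integer(0), 1L)
    } else if (c0 %in% unname(openers)) {
      st <- stacks[[c0]] %||% integer(0)
      if (!length(st)) stop("unbalanced structure line at closer '", c0, "'")
      stacks[[c0]] <- st[-length(st)]
    }
  }
  left <- vapply(stacks, length, integer(1L))
  if (any(left > 0L)) {
    stop("unbalanced structure line: ", sum(left), " unclosed bracket(s)")
  }
  invisible(TRUE)
}

#' Parse a dot-bracket structure line into a base-pair table
#'
#' Nested brackets `<>()[]{}` are tier 1; uppercase/lowercase letter
#' pairs (`Aa`, `Bb`, ...) are read as pseudoknot tier 2.
#'
#' @param ss dot-bracket string.
#' @return data frame with columns `i`, `j` (1-based columns, `i < j`)
#'   and `tier`.
#' @export
parse_structure_line <- function(ss) {
  check_balanced_structure(ss)
  ch <- strsplit(ss, "", fixed = TRUE)[[1L]]
  res_i <- integer(0); res_j <- integer(0); res_t <- integer(0)
  pop_pairs <- function(open_set, close_map, tier) {
    stacks <- list()
    for (k in seq_along(ch)) {
      c0 <- ch[k]
      if (c0 %in% open_set) {
        key <- close_map[[c0]]
        stacks[[key]] <- c(stacks[[key]] %||% integer(0), k)
      } else if (c0 %in% unlist(close_map, use.names = FALSE)) {
        st <- stacks[[c0]]
        res_i <<- c(res_i, st[length(st)])
        res_j <<- c(res_j, k)
        res_t <<- c(res_t, tier)
        stacks[[c0]] <- st[-length(st)]
      }
    }
  }
  pop_pairs(c("<", "(", "[", "{"),
            list("<" = ">", "(" = ")", "[" = "]", "{" = "}"), 1L)
  pop_pairs(LETTERS, as.list(setNames(letters, LETTERS)), 2L)
  ord <- order(res_i)
  data.frame(i = res_i[ord], j = res_j[ord], tier = res_t[ord])
}

#' Read a multiple alignment (Stockholm or aligned FASTA)
#'
#' Stockholm `#=GC SS_cons` is mapped to the alignment's
#' `structure` line, other `#=GC` lines to `gc`, and `#=GF` lines to
#' `metadata`.  `T` is normalised to `U` (alignments are RNA-facing).
#' Interleaved Stockholm blocks are concatenated.
#'
#' @param path input file.  Format is auto-detected (`# STOCKHOLM`
#'   header vs `>` FASTA header).
#' @return `rna_alignment` object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "# STOCKHOLM")) {
    read_stockholm(path)
  } else {
    ss <- Biostrings::readBStringSet(path)
    rows <- setNames(toupper(as.character(ss)),
                     sub("\\s.*$", "", names(ss)))
    rna_alignment(rows)
  }
}

#' @noRd
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list(); gc <- list(); gf <- character(0)
  for (ln in lines) {
    if (ln == "" || ln == "//" || startsWith(ln, "# STOCKHOLM")) next
    if (startsWith(ln, "#=GF")) {
      parts <- strsplit(sub("^#=GF\\s+", "", ln), "\\s+")[[1L]]
      gf[parts[1L]] <- paste(parts[-1L], collapse = " ")
    } else if (startsWith(ln, "#=GC")) {
      parts <- strsplit(sub("^#=GC\\s+", "", ln), "\\s+")[[1L]]
      key <- parts[1L]
      gc[[key]] <- paste0(gc[[key]] %||% "", parts[2L])
    } else if (startsWith(ln, "#")) {
      next
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(parts) != 2L) {
        stop("cannot parse Stockholm sequence line: ", ln)
      }
      rows[[parts[1L]]] <- paste0(rows[[parts[1L]]] %||% "", parts[2L])
    }
  }
  if (!length(rows)) stop("no sequence rows in ", path)
  structure_line <- gc[["SS_cons"]]
  gc[["SS_cons"]] <- NULL
  rna_alignment(unlist(rows), structure = structure_line,
                metadata = gf, gc = unlist(gc) %||% character(0))
}

#' Write an alignment to Stockholm or aligned FASTA
#'
#' @param aln `rna_alignment` object.
#' @param path output path.
#' @param format `"stockholm"` (default; carries structure and
#'   annotation lines) or `"fasta"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("stockholm", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(aln$rows)
    Biostrings::writeXStringSet(ss, path)
    return(invisible(path))
  }
  idw <- max(nchar(names(aln$rows)), nchar("#=GC SS_cons"),
             if (length(aln$gc)) nchar(paste0("#=GC ", names(aln$gc))) else 0L)
  pad <- function(s) formatC(s, width = -(idw + 2L))
  out <- c("# STOCKHOLM 1.0")
  if (length(aln$metadata)) {
    out <- c(out, paste0("#=GF ", names(aln$metadata), " ",
                         unname(aln$metadata)))
  }
  out <- c(out, paste0(pad(names(aln$rows)), unname(aln$rows)))
  if (!is.null(aln$structure)) {
    out <- c(out, paste0(pad("#=GC SS_cons"), aln$structure))
  }
  if (length(aln$gc)) {
    out <- c(out, paste0(pad(paste0("#=GC ", names(aln$gc))),
                         unname(aln$gc)))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Map an ungapped sequence position to its alignment column
#'
#' @param aln `rna_alignment`.
#' @param row row name or index.
#' @param pos 1-based position(s) within the row's ungapped sequence.
#' @return 1-based alignment column(s).
#' @export
column_of_position <- function(aln, row, pos) {
  r <- aln$rows[[row]]
  ch <- strsplit(r, "", fixed = TRUE)[[1L]]
  nong <- which(!ch %in% c("-", "."))
  if (any(pos > length(nong))) stop("position beyond end of ungapped row")
  nong[pos]
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("<rna_alignment> ", length(x$rows), " rows x ",
      nchar(x$rows[[1L]]), " columns",
      if (!is.null(x$structure)) " (with structure)", "\n", sep = "")
  invisible(x)
}
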