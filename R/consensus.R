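#' Per-column consensus statistics
#'
#' Weighted column summaries in the style of consensus-diagram
#' renderers: the fraction of sequence weight present (non-gap), the
#' weighted-majority nucleotide, and an identity class at the
#' conventional 97 / 90 / 75 percent thresholds computed over the
#' non-gap weight.
#'
#' @param walign `weighted_alignment` (weights normalised).
#' @param structure optional `consensus_structure`; pair classes are
#'   copied into the result.
#' @return list with `columns` (data frame: `column`,
#'   `present_fraction`, `majority_nt`, `majority_fraction`,
#'   `identity_class` in `{">=97", ">=90", ">=75", "none"}`) and
#'   `pairs` (the structure's pair-class table, or an empty frame).
#' @export
summarize_alignment <- function(walign, structure = NULL) {
  codes <- alignment_codes(walign$alignment)
  w <- walign$weights
  L <- ncol(codes)
  present <- numeric(L)
  maj_nt <- character(L)
  maj_fr <- numeric(L)
  for (c0 in seq_len(L)) {
    col <- codes[, c0]
    wnt <- vapply(1:4, function(x) sum(w[col == x]), numeric(1L))
    pres <- sum(wnt)
    present[c0] <- pres
    if (pres > 0) {
      b <- which.max(wnt)
      maj_nt[c0] <- c("A", "C", "G", "U")[b]
      maj_fr[c0] <- wnt[b] / pres
    } else {
      maj_nt[c0] <- "-"
      maj_fr[c0] <- 0
    }
  }
  identity_class <- ifelse(maj_fr >= 0.97, ">=97",
                           ifelse(maj_fr >= 0.90, ">=90",
                                  ifelse(maj_fr >= 0.75, ">=75", "none")))
  cols <- data.frame(column = seq_len(L), present_fraction = present,
                     majority_nt = maj_nt, majority_fraction = maj_fr,
                     identity_class = identity_class,
                     stringsAsFactors = FALSE)
  pairs <- if (!is.null(structure)) structure$pairs else
    data.frame(i = integer(0), j = integer(0), class = character(0))
  list(columns = cols, pairs = pairs)
}

#' Annotated-Stockholm consensus report
#'
#' Text rendering of a curated family: the alignment plus `#=GC`
#' annotation lines for the consensus structure (`SS_cons`, with the
#' pseudoknot tier as `Aa` brackets), a 4-class conservation string
#' (uppercase majority nucleotide at >=97% identity, lowercase at
#' >=90%, `:` at >=75%, `.` otherwise), a pair-class string (`C`
#' covarying / `c` compatible / `=` conserved / `x` rejected, `.` for
#' unpaired columns), and `#=GF` lines recording each helix and its
#' transcript support flag.
#'
#' @param walign `weighted_alignment`.
#' @param structure `consensus_structure` (optionally flagged by
#'   [truncate_to_transcript()]).
#' @param path optional output file; when given, the annotated
#'   Stockholm is written there.
#' @return the annotated `rna_alignment` (invisibly when `path` is
#'   given); `$gc` carries the `cons` and `pair_class` strings.
#' @export
report_consensus <- function(walign, structure, path = NULL) {
  sm <- summarize_alignment(walign, structure)
  L <- structure$length
  ss <- rep(".", L)
  if (nrow(structure$pairs)) {
    p1 <- structure$pairs[structure$pairs$tier == 1L, , drop = FALSE]
    p2 <- structure$pairs[structure$pairs$tier == 2L, , drop = FALSE]
    ss[p1$i] <- "<"; ss[p1$j] <- ">"
    ss[p2$i] <- "A"; ss[p2$j] <- "a"
  }
  cons <- character(L)
  for (c0 in seq_len(L)) {
    cl <- sm$columns$identity_class[c0]
    nt <- sm$columns$majority_nt[c0]
    cons[c0] <- switch(cl,
                       ">=97" = nt,
                       ">=90" = tolower(nt),
                       ">=75" = ":",
                       ".")
  }
  pc <- rep(".", L)
  if (nrow(structure$pairs)) {
    sym <- c(covarying = "C", compatible = "c", conserved = "=",
             rejected = "x")
    for (k in seq_len(nrow(structure$pairs))) {
      s0 <- sym[[structure$pairs$class[k]]]
      pc[structure$pairs$i[k]] <- s0
      pc[structure$pairs$j[k]] <- s0
    }
  }
  md <- walign$alignment$metadata
  if (nrow(structure$helices)) {
    for (k in seq_len(nrow(structure$helices))) {
      h <- structure$helices[k, ]
      md[paste0("HELIX_", h$name)] <- paste0(
        "cols ", h$i_outer, "-", h$j_outer, " (", h$n_pairs, " bp)",
        if (!is.na(h$tss_support)) paste0(" tss=", h$tss_support)
      )
    }
  }
  if (!is.null(structure$tss_column)) {
    md["TSS_COLUMN"] <- as.character(structure$tss_column)
  }
  out <- rna_alignment(
    walign$alignment$rows,
    structure = paste(ss, collapse = ""),
    metadata = md,
    gc = c(cons = paste(cons, collapse = ""),
           pair_class = paste(pc, collapse = ""))
  )
  if (!is.null(path)) {
    write_alignment(out, path, format = "stockholm")
    return(invisible(out))
  }
  out
}
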