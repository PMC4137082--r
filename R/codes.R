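# Internal nucleotide encoding shared by the alignment / covariation /
# profile machinery.  Codes: A=1, C=2, G=3, U(T)=4, gap=5, other(N,...)=6.

NT_LETTERS <- c("A", "C", "G", "U", "-", "N")

# canonical pair types, in a fixed order used by pair tables everywhere
PAIR_TYPE_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")
PAIR_TYPE_CODES <- matrix(
  c(1L, 4L,
    4L, 1L,
    2L, 3L,
    3L, 2L,
    3L, 4L,
    4L, 3L),
  ncol = 2L, byrow = TRUE,
  dimnames = list(PAIR_TYPE_NAMES, c("i", "j"))
)

# H[t1, t2]: number of positions at which two canonical pair types differ
PAIR_DIFF <- local({
  h <- matrix(0L, 6L, 6L, dimnames = list(PAIR_TYPE_NAMES, PAIR_TYPE_NAMES))
  for (a in 1:6) for (b in 1:6) {
    h[a, b] <- sum(PAIR_TYPE_CODES[a, ] != PAIR_TYPE_CODES[b, ])
  }
  h
})

# map a 6*6 joint-code index (6*(ci-1)+cj) to a canonical type 1..6 or NA
CANONICAL_LOOKUP <- local({
  m <- rep(NA_integer_, 36L)
  for (t in 1:6) {
    m[6L * (PAIR_TYPE_CODES[t, 1L] - 1L) + PAIR_TYPE_CODES[t, 2L]] <- t
  }
  m
})

#' @noRd
seq_to_codes <- function(x, rna = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (rna) ch[ch == "T"] <- "U" else ch[ch == "U"] <- "T"
  code <- match(ch, c("A", "C", "G", if (rna) "U" else "T", "-", "."))
  code[ch == "."] <- 5L
  code[is.na(code)] <- 6L
  code
}

#' @noRd
codes_to_seq <- function(code) {
  paste(NT_LETTERS[code], collapse = "")
}

#' @noRd
alignment_codes <- function(aln) {
  rows <- aln$rows
  m <- t(vapply(rows, seq_to_codes, integer(nchar(rows[[1L]]))))
  rownames(m) <- names(rows)
  m
}

# reverse complement of a plain DNA/RNA character string
#' @noRd
revcomp_chr <- function(x, rna = FALSE) {
  y <- if (rna) chartr("ACGUacgu", "UGCAugca", x) else
    chartr("ACGTacgt", "TGCAtgca", x)
  paste(rev(strsplit(y, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' @noRd
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @noRd
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
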