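# Shared fixtures and independent oracles, built in code at test time.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# write a toy genome (FASTA + GFF3) and return the paths
write_toy_genome <- function(seq, features, id = "TOY1",
                             dir = withr::local_tempdir(.local_envir =
                                                          parent.frame())) {
  fasta <- file.path(dir, paste0(id, ".fna"))
  gff <- file.path(dir, paste0(id, ".gff3"))
  writeLines(c(paste0(">", id), seq), fasta)
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(features)), function(k) {
               f <- features[k, ]
               paste(id, "toy", f$type, f$start, f$end, ".", f$strand, ".",
                     paste0("ID=f", k, ";gene=", f$name),
                     sep = "\t")
             }, character(1L)))
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff)
}

toy_features <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], type = "CDS", start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

make_leader <- function(sequence, genome_id = "G1", taxonomy = character(0),
                        region = NULL, strand = "+") {
  structure(list(
    genome_id = genome_id, gene_name = "rpsO",
    sequence = chartr("T", "U", toupper(sequence)),
    region = region %||% c(0L, nchar(sequence)),
    strand = strand,
    offset_of_start_codon = max(nchar(sequence) - 25L, 0L),
    taxonomy = taxonomy, truncated = FALSE
  ), class = "leader_seq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force maximiser over all non-crossing pairings with
# hairpin >= 3, used as the folding oracle (exponential recursion; only
# for <= 12 columns)
brute_force_fold <- function(S, tau) {
  L <- nrow(S)
  memo <- new.env(hash = TRUE)
  best <- function(i, j) {
    if (j - i < 4L) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    b <- best(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (is.finite(S[k, j]) && S[k, j] >= tau) {
        v <- S[k, j] + (if (k > i) best(i, k - 1L) else 0) +
          best(k + 1L, j - 1L)
        if (v > b) b <- v
      }
    }
    memo[[key]] <- b
    b
  }
  if (L < 5L) return(0)
  best(1L, L)
}

# pair-score matrix for an alignment, via the public pair_score API
score_matrix <- function(walign, tau = 0.05, phi = 1.0) {
  L <- nchar(walign$alignment$rows[[1L]])
  S <- matrix(-Inf, L, L)
  if (L >= 5L) {
    for (i in 1:(L - 4L)) for (j in (i + 4L):L) {
      ev <- pair_score(walign, i, j, phi = phi)
      if (is.finite(ev$score)) S[i, j] <- ev$score
    }
  }
  S
}

# random small RNA alignment for property tests
random_alignment <- function(n_rows, n_cols) {
  rows <- vapply(seq_len(n_rows), function(i) {
    random_seq(n_cols, c("A", "C", "G", "U"))
  }, character(1L))
  names(rows) <- paste0("r", seq_len(n_rows))
  rna_alignment(rows)
}

# Gumbel sampler by inversion (independent of the package's fitter)
rgumbel <- function(n, mu, lambda) {
  mu - log(-log(runif(n))) / lambda
}
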