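# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own code paths.

# toy record: given gene tuples (name, strand, start, end), a deterministic
# sequence is synthesized to fit
toy_record <- function(genes, seq_len = NULL, is_circular = TRUE,
                       is_complete = TRUE, sequence = NULL) {
  feats <- do.call(rbind, lapply(genes, function(g)
    data.frame(name = g[[1]], strand = g[[2]],
               start = as.integer(g[[3]]), end = as.integer(g[[4]]),
               stringsAsFactors = FALSE)))
  if (is.null(seq_len)) seq_len <- max(feats$end)
  if (is.null(sequence))
    sequence <- paste(rep(c("A", "C", "G", "T"), length.out = seq_len),
                      collapse = "")
  mito_record("toy", sequence, feats, is_circular, is_complete,
              check_census = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent base-counting oracle
oracle_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  vapply(c("A", "T", "G", "C"), function(b) sum(ch == b), integer(1))
}

# brute-force dot-bracket pair enumeration (independent of count_pair_types)
oracle_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  open <- integer(0)
  out <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    if (ch[i] == ")") {
      out[[length(out) + 1L]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  out
}

# random balanced dot-bracket structure of length n
random_structure <- function(n) {
  ch <- rep(".", n)
  open <- integer(0)
  for (i in seq_len(n)) {
    remaining <- n - i
    if (length(open) > 0 && (remaining < length(open) || runif(1) < 0.35)) {
      ch[i] <- ")"
      open <- open[-length(open)]
    } else if (remaining > length(open) && runif(1) < 0.45) {
      ch[i] <- "("
      open <- c(open, i)
    }
  }
  while (length(open)) {  # close any dangling opens over trailing dots
    i <- max(which(ch == "." & seq_len(n) > open[length(open)]))
    ch[i] <- ")"
    open <- open[-length(open)]
  }
  paste(ch, collapse = "")
}

# brute-force codon enumeration oracle
oracle_codons <- function(seq, offset = 0) {
  s <- substr(seq, offset + 1, nchar(seq))
  n <- nchar(s) %/% 3
  vapply(seq_len(n), function(i) substr(s, 3 * i - 2, 3 * i), character(1))
}

# small aligned block with random rows
toy_block <- function(gene, len, taxa = c("sp1", "sp2", "sp3"),
                      alphabet = c("A", "C", "G", "T")) {
  alignment_block(gene, stats::setNames(
    vapply(taxa, function(x) random_seq(len, alphabet), character(1)), taxa))
}

# PCG aligned lengths summing to the published PCG123 width (11,157 columns)
pcg123_lengths <- function() {
  stats::setNames(
    c(1023L, 1536L, 687L, 159L, 678L, 786L, 354L, 1722L, 1341L, 294L,
      522L, 1134L, 921L),
    c("ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3", "ND5", "ND4",
      "ND4L", "ND6", "CYTB", "ND1"))
}

full_block_set <- function(taxa = c("sp1", "sp2", "sp3"), rna_len = 66L) {
  lens <- pcg123_lengths()
  c(lapply(names(lens), function(g) toy_block(g, lens[[g]], taxa)),
    lapply(grep("^trn", MITO_GENES, value = TRUE),
           function(g) toy_block(g, rna_len, taxa)),
    list(toy_block("rrnL", 1302L, taxa), toy_block("rrnS", 780L, taxa)))
}
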