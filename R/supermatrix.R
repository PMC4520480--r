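# Concatenated phylogenetic datasets from per-gene alignments, with
# codon-position partition (charset) maps. Four schemes: PCG123 (all codon
# positions), PCG123RNA (plus 22 tRNAs and 2 rRNAs), PCG12 (third positions
# removed), PCG12RNA. Partition counts: 13 genes x included codon positions
# + 22 tRNA + 2 rRNA when RNA is included (63 for PCG123RNA, 50 for
# PCG12RNA, 39 for PCG123, 26 for PCG12).

#' Supported concatenation schemes
#' @format character vector of scheme names.
#' @export
SUPERMATRIX_SCHEMES <- c("PCG123", "PCG123RNA", "PCG12", "PCG12RNA")

#' Construct a per-gene alignment block
#'
#' @param gene canonical gene token.
#' @param seqs named character vector of equal-length aligned sequences
#'   (gaps "-"), names are taxon labels.
#' @return object of class \code{alignment_block}.
#' @export
alignment_block <- function(gene, seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment sequences must be named by taxon")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels in alignment for ", gene)
  w <- unique(nchar(seqs))
  if (length(w) > 1)
    stop("alignment rows for ", gene, " have unequal lengths")
  structure(list(gene = gene, seqs = toupper(seqs),
                 width = if (length(w)) w else 0L),
            class = "alignment_block")
}

#' Remove third codon positions from a protein-coding alignment block
#'
#' Keeps columns at codon positions 1 and 2 (the alignment must be in
#' frame and of length divisible by 3); the result is 2/3 of the original
#' length.
#'
#' @param block an \code{alignment_block}.
#' @return an \code{alignment_block} without third positions.
#' @export
drop_third_positions <- function(block) {
  if (block$width %% 3L != 0L)
    stop("alignment length of ", block$gene, " (", block$width,
         ") is not divisible by 3")
  keep <- which(seq_len(block$width) %% 3L != 0L)
  seqs <- vapply(block$seqs, function(s)
    paste(substring(s, keep, keep), collapse = ""), character(1))
  alignment_block(block$gene, seqs)
}

#' Remove gap-heavy columns from an alignment block
#'
#' A reproducible surrogate for by-hand removal of ambiguously aligned RNA
#' positions: columns whose gap fraction exceeds \code{max_gap_fraction}
#' are dropped. The default threshold 1.0 disables masking (a fraction can
#' never exceed 1).
#'
#' @param block an \code{alignment_block}.
#' @param max_gap_fraction proportion in [0, 1].
#' @return filtered \code{alignment_block}.
#' @export
mask_ambiguous_columns <- function(block, max_gap_fraction = 1.0) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  if (block$width == 0L || max_gap_fraction >= 1) return(block)
  m <- do.call(rbind, strsplit(unname(block$seqs), "", fixed = TRUE))
  gap_frac <- colMeans(m == "-" | m == ".")
  keep <- which(gap_frac <= max_gap_fraction)
  seqs <- vapply(block$seqs, function(s)
    paste(substring(s, keep, keep), collapse = ""), character(1))
  alignment_block(block$gene, seqs)
}

.gene_rank <- function(genes) match(genes, ANCESTRAL_INSECT_ORDER$gene)

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in a fixed canonical order (PCGs first, then
#' tRNAs, then rRNAs, each set in ancestral-order rank) with a charset map
#' for downstream partitioned analyses. PCG blocks must be in frame and of
#' length divisible by 3; for PCG12 schemes third positions are removed
#' first. RNA blocks are used only by the *RNA schemes.
#'
#' @param blocks list of \code{alignment_block}s (unique genes).
#' @param scheme one of PCG123, PCG123RNA, PCG12, PCG12RNA.
#' @param fill_missing fill taxa absent from a block with gaps instead of
#'   erroring on taxon-set mismatch.
#' @return object of class \code{supermatrix}: \code{taxa}, \code{seqs}
#'   (named character vector), \code{charsets} (label/start/end/step,
#'   1-based inclusive), \code{scheme}, \code{length}.
#' @export
concatenate_blocks <- function(blocks, scheme = "PCG123", fill_missing = FALSE) {
  scheme <- match.arg(scheme, SUPERMATRIX_SCHEMES)
  genes <- vapply(blocks, `[[`, character(1), "gene")
  if (anyDuplicated(genes)) stop("duplicate gene blocks: ",
                                 paste(genes[duplicated(genes)], collapse = ", "))
  cls <- gene_class(genes)
  if (anyNA(cls)) stop("blocks with non-canonical gene names: ",
                       paste(genes[is.na(cls)], collapse = ", "))
  use_rna <- grepl("RNA$", scheme)
  keep <- cls == "PCG" | (use_rna & cls %in% c("tRNA", "rRNA"))
  blocks <- blocks[keep]; genes <- genes[keep]; cls <- cls[keep]
  if (!any(cls == "PCG")) stop("no protein-coding blocks supplied")
  ord <- order(match(cls, c("PCG", "tRNA", "rRNA")), .gene_rank(genes))
  blocks <- blocks[ord]; genes <- genes[ord]; cls <- cls[ord]

  taxa <- Reduce(union, lapply(blocks, function(b) names(b$seqs)))
  for (b in blocks) {
    if (!setequal(names(b$seqs), taxa) && !fill_missing)
      stop("taxon sets differ across blocks (gene ", b$gene,
           "); use fill_missing = TRUE to pad with gaps")
  }

  drop3 <- grepl("^PCG12($|RNA$)", scheme)
  pieces <- vector("list", length(blocks))
  charsets <- list()
  offset <- 0L
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (cls[k] == "PCG") {
      if (b$width %% 3L != 0L)
        stop("PCG alignment length of ", b$gene, " is not divisible by 3")
      if (drop3) b <- drop_third_positions(b)
    }
    s <- b$seqs[taxa]
    s[is.na(s)] <- strrep("-", b$width)
    names(s) <- taxa
    pieces[[k]] <- s
    if (cls[k] == "PCG") {
      npos <- if (drop3) 2L else 3L
      for (pos in seq_len(npos)) {
        charsets[[length(charsets) + 1L]] <- data.frame(
          label = paste0(b$gene, "_pos", pos),
          start = offset + pos, end = offset + b$width, step = npos,
          stringsAsFactors = FALSE)
      }
    } else {
      charsets[[length(charsets) + 1L]] <- data.frame(
        label = b$gene, start = offset + 1L, end = offset + b$width,
        step = 1L, stringsAsFactors = FALSE)
    }
    offset <- offset + b$width
  }
  seqs <- vapply(taxa, function(tx)
    paste(vapply(pieces, `[[`, character(1), tx), collapse = ""), character(1))
  structure(list(taxa = taxa, seqs = seqs,
                 charsets = do.call(rbind, charsets),
                 scheme = scheme, length = offset),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix [", x$scheme, "]: ", length(x$taxa), " taxa x ",
      x$length, " columns, ", nrow(x$charsets), " partitions\n", sep = "")
  invisible(x)
}

.sanitize_taxon <- function(x) gsub("[^A-Za-z0-9_.]+", "_", x)

#' Export a supermatrix and its partition definitions
#'
#' Writes any of: aligned FASTA, relaxed PHYLIP, a NEXUS \code{sets} block
#' with charsets, a RAxML-style partition file
#' (\code{DNA, label = start-end\\3}), and a PartitionFinder configuration
#' stub. Codon-position charsets use the \code{\\3} (or \code{\\2}) stride
#' notation.
#'
#' @param sm a \code{supermatrix}.
#' @param dir output directory (created if absent).
#' @param basename file name stem; defaults to the scheme.
#' @param formats subset of c("fasta","phylip","nexus","raxml",
#'   "partitionfinder").
#' @return named character vector of written paths, invisibly.
#' @export
export_supermatrix <- function(sm, dir, basename = NULL,
                               formats = c("fasta", "phylip", "nexus",
                                           "raxml", "partitionfinder")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(basename)) basename <- sm$scheme
  formats <- match.arg(formats, several.ok = TRUE)
  clean <- .sanitize_taxon(sm$taxa)
  if (anyDuplicated(clean))
    stop("taxon labels collide after PHYLIP sanitation: ",
         paste(unique(clean[duplicated(clean)]), collapse = ", "))
  cs_txt <- function(r) {
    paste0(r$start, "-", r$end, if (r$step > 1) paste0("\\", r$step) else "")
  }
  paths <- character(0)
  if ("fasta" %in% formats) {
    p <- file.path(dir, paste0(basename, ".fasta"))
    writeLines(as.vector(rbind(paste0(">", clean), unname(sm$seqs))), p)
    paths["fasta"] <- p
  }
  if ("phylip" %in% formats) {
    p <- file.path(dir, paste0(basename, ".phy"))
    writeLines(c(paste(length(sm$taxa), sm$length),
                 paste0(formatC(clean, width = max(nchar(clean)) + 2L,
                                flag = "-"), unname(sm$seqs))), p)
    paths["phylip"] <- p
  }
  if ("nexus" %in% formats) {
    p <- file.path(dir, paste0(basename, ".charsets.nex"))
    lines <- c("#NEXUS", "begin sets;")
    for (i in seq_len(nrow(sm$charsets)))
      lines <- c(lines, paste0("    charset ", sm$charsets$label[i], " = ",
                               cs_txt(sm$charsets[i, ]), ";"))
    lines <- c(lines, "end;")
    writeLines(lines, p)
    paths["nexus"] <- p
  }
  if ("raxml" %in% formats) {
    p <- file.path(dir, paste0(basename, ".partitions.txt"))
    writeLines(vapply(seq_len(nrow(sm$charsets)), function(i)
      paste0("DNA, ", sm$charsets$label[i], " = ", cs_txt(sm$charsets[i, ])),
      character(1)), p)
    paths["raxml"] <- p
  }
  if ("partitionfinder" %in% formats) {
    p <- file.path(dir, paste0(basename, ".partition_finder.cfg"))
    lines <- c(paste0("alignment = ", basename, ".phy;"),
               "branchlengths = unlinked;",
               "models = all;",
               "model_selection = BIC;",
               "[data_blocks]",
               vapply(seq_len(nrow(sm$charsets)), function(i)
                 paste0(sm$charsets$label[i], " = ",
                        cs_txt(sm$charsets[i, ]), ";"), character(1)),
               "[schemes]",
               "search = greedy;")
    writeLines(lines, p)
    paths["partitionfinder"] <- p
  }
  invisible(paths)
}

#' Parse charsets back out of an exported NEXUS sets block
#'
#' Round-trip companion to \code{\link{export_supermatrix}}.
#'
#' @param path a \code{.charsets.nex} file.
#' @return data.frame with columns label/start/end/step.
#' @export
parse_nexus_charsets <- function(path) {
  lines <- grep("^\\s*charset ", readLines(path), value = TRUE)
  rows <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(
      "charset\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+)(\\\\(\\d+))?\\s*;", ln))[[1]]
    if (!length(m)) stop("unparseable charset line: ", ln)
    data.frame(label = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
               step = if (nzchar(m[6])) as.integer(m[6]) else 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
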