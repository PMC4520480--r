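# Gene order, junction (overlap/spacer/abutting), start/stop codon and
# ORF-validity analyses on an annotated mitogenome.

#' Signed circular gene order of a record
#'
#' Canonical names in genomic order with strand signs (N-strand genes
#' prefixed "-"), rotated to start at trnI by convention (falling back to
#' the first feature when trnI is absent). Compare against
#' \code{gene_order_string(ANCESTRAL_INSECT_ORDER)}-style vectors via
#' \code{\link{breakpoint_count}}.
#'
#' @param record a \code{mito_record} with canonicalized features.
#' @param include_cr include the control region in the order string.
#' @return character vector of signed tokens; attribute \code{missing}
#'   lists absent census genes.
#' @export
gene_order_string <- function(record, include_cr = FALSE) {
  f <- record$features
  if (!include_cr) f <- f[f$class != "CR", , drop = FALSE]
  if (!nrow(f)) return(character(0))
  signed <- ifelse(f$strand == "N", paste0("-", f$name), f$name)
  i <- match("trnI", f$name)
  if (!is.na(i) && i > 1) signed <- c(signed[i:length(signed)], signed[seq_len(i - 1)])
  missing <- setdiff(setdiff(MITO_GENES, "CR"), f$name)
  if (length(missing))
    message("gene_order_string: record '", record$record_id, "' is missing ",
            paste(missing, collapse = ", "))
  structure(signed, missing = missing)
}

#' Signed order string of the ancestral insect arrangement
#' @param include_cr include the CR token.
#' @return character vector of signed tokens starting at trnI.
#' @export
ancestral_order_string <- function(include_cr = FALSE) {
  ord <- ANCESTRAL_INSECT_ORDER
  if (!include_cr) ord <- ord[ord$gene != "CR", , drop = FALSE]
  ifelse(ord$strand == "N", paste0("-", ord$gene), ord$gene)
}

#' Breakpoint count between two circular gene orders
#'
#' Unsigned adjacent-pair definition: the number of gene adjacencies (on
#' the circle, strand signs ignored) present in \code{order1} but absent in
#' \code{order2}. Zero iff the unsigned circular orders share all
#' adjacencies.
#'
#' @param order1,order2 signed order vectors over the same gene set.
#' @return integer breakpoint count.
#' @export
breakpoint_count <- function(order1, order2) {
  unsign <- function(x) sub("^-", "", x)
  adj <- function(ord) {
    g <- unsign(ord)
    n <- length(g)
    pairs <- cbind(g, g[c(2:n, 1)])
    # unordered adjacency (orientation-free)
    apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
  }
  a1 <- adj(order1); a2 <- adj(order2)
  sum(!(a1 %in% a2))
}

#' Junction (overlap/spacer/abutting) report for a record
#'
#' For each pair of features adjacent in genomic order, the gap
#' \code{next_start - prev_end} classifies the junction: negative gaps are
#' overlaps of \code{|gap|} bp, positive gaps are intergenic spacers,
#' zero-gap pairs abut. Complete circular records contribute the
#' origin-spanning junction as well (n junctions for n features);
#' near-complete or linear records do not (n-1). A feature nested inside
#' its predecessor is reported as an overlap of the nested feature's full
#' length, with a warning. Junctions flanking the control region are
#' excluded unless \code{include_cr}.
#'
#' @param record a \code{mito_record}.
#' @param include_cr keep CR-flanking junctions.
#' @return a data.frame of class \code{mito_junctions} with columns
#'   \code{upstream}, \code{downstream}, \code{relation}, \code{length};
#'   attribute \code{summary} holds counts and min/max per relation.
#' @export
junctions <- function(record, include_cr = FALSE) {
  f <- record$features
  f <- f[order(f$start, f$end), , drop = FALSE]
  n <- nrow(f)
  L <- genome_length(record)
  circular <- record$is_circular && record$is_complete
  if (n < 2) {
    entries <- data.frame(upstream = character(0), downstream = character(0),
                          relation = character(0), length = integer(0),
                          stringsAsFactors = FALSE)
    return(.junction_report(entries))
  }
  idx_prev <- if (circular) seq_len(n) else seq_len(n - 1)
  idx_next <- if (circular) c(2:n, 1) else 2:n
  entries <- vector("list", length(idx_prev))
  for (k in seq_along(idx_prev)) {
    i <- idx_prev[k]; j <- idx_next[k]
    gap <- if (j == 1 && circular) f$start[j] + L - f$end[i]
           else f$start[j] - f$end[i]
    if (j != 1 && f$end[j] <= f$end[i]) {
      warning("feature ", f$name[j], " is nested inside ", f$name[i],
              "; reported as overlap of its full length")
      rel <- "overlap"; len <- f$end[j] - f$start[j]
    } else if (gap < 0) {
      rel <- "overlap"; len <- -gap
    } else if (gap > 0) {
      rel <- "spacer"; len <- gap
    } else {
      rel <- "abutting"; len <- 0L
    }
    entries[[k]] <- data.frame(upstream = f$name[i], downstream = f$name[j],
                               relation = rel, length = as.integer(len),
                               stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries)
  if (!include_cr) {
    cr <- f$name[f$class == "CR"]
    entries <- entries[!(entries$upstream %in% cr | entries$downstream %in% cr),
                       , drop = FALSE]
  }
  rownames(entries) <- NULL
  .junction_report(entries)
}

.junction_report <- function(entries) {
  sm <- lapply(c("overlap", "spacer", "abutting"), function(rel) {
    len <- entries$length[entries$relation == rel]
    data.frame(relation = rel, n = length(len),
               min = if (length(len)) min(len) else NA_integer_,
               max = if (length(len)) max(len) else NA_integer_,
               total = sum(len), stringsAsFactors = FALSE)
  })
  structure(entries, summary = do.call(rbind, sm),
            class = c("mito_junctions", "data.frame"))
}

#' @export
print.mito_junctions <- function(x, ...) {
  NextMethod()
  cat("\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

.invertebrate_code <- NULL
.mito_code <- function() {
  if (is.null(.invertebrate_code))
    utils::assignInMyNamespace(".invertebrate_code",
                               Biostrings::getGeneticCode("5"))
  .invertebrate_code
}

.codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Classify start and stop codons of all protein-coding genes
#'
#' For each PCG the sense-strand sequence (after the reading-frame offset)
#' is inspected: the start codon is the first full codon, classified as
#' canonical ATN or non-canonical; the stop is read from the 3' end. A
#' length divisible by 3 with terminal TAA/TAG is a complete stop; a
#' trailing single T (length mod 3 = 1) or TA (mod 3 = 2) is a partial stop
#' completed by transcript polyadenylation. Anything else is flagged
#' anomalous with a warning, never an error.
#'
#' @param record a \code{mito_record}.
#' @return data.frame with columns \code{gene}, \code{start_codon},
#'   \code{start_class} ("canonical_ATN"/"noncanonical"),
#'   \code{stop_codon} (TAA/TAG/TA/T or NA), \code{stop_class}
#'   ("complete"/"partial"/"anomalous").
#' @export
classify_codons <- function(record) {
  f <- record$features
  pcgs <- which(f$class == "PCG")
  rows <- lapply(pcgs, function(i) {
    s <- feature_seq(record, i)
    off <- f$frame_offset[i]
    if (off > 0) s <- substr(s, off + 1L, nchar(s))
    if (nchar(s) < 6L) stop("PCG ", f$name[i], " shorter than 6 nt")
    start_codon <- substr(s, 1L, 3L)
    start_class <- if (grepl("^AT[ACGT]$", start_codon)) "canonical_ATN"
                   else "noncanonical"
    len <- nchar(s); rem <- len %% 3L
    if (rem == 0L) {
      last <- substr(s, len - 2L, len)
      if (last %in% c("TAA", "TAG")) {
        stop_codon <- last; stop_class <- "complete"
      } else {
        stop_codon <- NA_character_; stop_class <- "anomalous"
      }
    } else if (rem == 1L) {
      if (substr(s, len, len) == "T") {
        stop_codon <- "T"; stop_class <- "partial"
      } else {
        stop_codon <- NA_character_; stop_class <- "anomalous"
      }
    } else {
      if (substr(s, len - 1L, len) == "TA") {
        stop_codon <- "TA"; stop_class <- "partial"
      } else {
        stop_codon <- NA_character_; stop_class <- "anomalous"
      }
    }
    if (stop_class == "anomalous")
      warning("anomalous 3' terminus for ", f$name[i],
              " (length mod 3 = ", rem, ")")
    data.frame(gene = f$name[i], start_codon = start_codon,
               start_class = start_class, stop_codon = stop_codon,
               stop_class = stop_class, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene = character(0), start_codon = character(0),
                      start_class = character(0), stop_codon = character(0),
                      stop_class = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count internal stop codons in a protein-coding gene
#'
#' Translates the sense-strand sequence (reading-frame offset applied,
#' terminal complete or partial stop excluded) under the invertebrate
#' mitochondrial genetic code and returns the number of internal stops.
#' Zero is expected for a valid ORF; a nonzero count is a QC signal, not an
#' error.
#'
#' @param record a \code{mito_record}.
#' @param gene canonical PCG token.
#' @return integer count of internal stop codons.
#' @export
validate_orf <- function(record, gene) {
  f <- record$features
  i <- match(gene, f$name)
  if (is.na(i) || f$class[i] != "PCG") stop(gene, " is not a PCG in this record")
  s <- feature_seq(record, i)
  off <- f$frame_offset[i]
  if (off > 0) s <- substr(s, off + 1L, nchar(s))
  len <- nchar(s); rem <- len %% 3L
  drop <- if (rem == 0L &&
              substr(s, len - 2L, len) %in% c("TAA", "TAG")) 3L else rem
  s <- substr(s, 1L, len - drop)
  codons <- .codons_of(s)
  code <- .mito_code()
  aa <- code[codons]
  sum(!is.na(aa) & aa == "*")
}
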