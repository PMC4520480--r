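# Plain-text feature-table I/O (the "Organization of the mt genome" table
# shape) and machine-readable report writers. External coordinates are
# 1-based inclusive; internal are 0-based half-open.

#' Read a per-gene feature table paired with a FASTA sequence
#'
#' The table is TSV with columns \code{name}, \code{start}, \code{end},
#' \code{strand} (1-based inclusive coordinates; strand "J"/"N" or "+"/"-").
#' On a circular record, \code{end < start} denotes a feature wrapping the
#' origin. Gene names are canonicalized via the synonym map; unresolvable
#' names are kept verbatim with a warning.
#'
#' @param path TSV feature table.
#' @param fasta FASTA file whose first record is the genome sequence.
#' @param is_circular,is_complete record flags.
#' @return a \code{mito_record}.
#' @export
read_feature_table <- function(path, fasta, is_circular = TRUE,
                               is_complete = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  req <- c("name", "start", "end", "strand")
  if (!all(req %in% names(tab)))
    stop("feature table must have columns name, start, end, strand")
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) stop("empty FASTA: ", fasta)
  sequence <- as.character(seqs[[1]])
  L <- nchar(sequence)

  strand <- ifelse(tab$strand %in% c("J", "+"), "J",
                   ifelse(tab$strand %in% c("N", "-"), "N", NA))
  if (anyNA(strand)) stop("strand must be one of J/N/+/-")
  start1 <- as.integer(tab$start); end1 <- as.integer(tab$end)
  if (any(start1 < 1) || any(start1 > L) || any(end1 < 1) || any(end1 > L))
    stop("coordinate outside the sequence (length ", L, ")")
  wrap <- end1 < start1
  if (any(wrap) && !is_circular)
    stop("end < start on a non-circular record")
  start0 <- start1 - 1L
  end0 <- ifelse(wrap, end1 + L, end1)

  canon <- canonicalize_gene_name(tab$name)
  unknown <- canon == "unknown"
  if (any(unknown)) {
    warning("could not canonicalize: ", paste(tab$name[unknown], collapse = ", "))
    canon[unknown] <- tab$name[unknown]
  }
  if (anyDuplicated(canon))
    stop("duplicate gene names in feature table: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  off <- if ("frame_offset" %in% names(tab)) as.integer(tab$frame_offset) else 0L
  features <- data.frame(name = canon, class = gene_class(canon),
                         strand = strand, start = start0, end = end0,
                         frame_offset = off, stringsAsFactors = FALSE)
  features$class[is.na(features$class)] <- "CR"
  mito_record(tools::file_path_sans_ext(basename(path)), sequence, features,
              is_circular, is_complete, check_census = FALSE)
}

#' Write a record as a feature table plus FASTA
#'
#' Inverse of \code{\link{read_feature_table}}: 1-based inclusive
#' coordinates, wrap-around features written with \code{end < start}.
#'
#' @param record a \code{mito_record}.
#' @param path output TSV path.
#' @param fasta output FASTA path (omit to skip sequence export).
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(record, path, fasta = NULL) {
  f <- record$features
  L <- genome_length(record)
  tab <- data.frame(name = f$name,
                    start = f$start + 1L,
                    end = ifelse(f$end > L, f$end - L, f$end),
                    strand = f$strand,
                    frame_offset = f$frame_offset,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(record$sequence)
    names(x) <- record$record_id
    Biostrings::writeXStringSet(x, fasta, width = 70L)
  }
  invisible(path)
}

.round_display <- function(metric, value) {
  digits <- ifelse(grepl("skew", metric), 2L, 1L)
  round(value, digits)
}

#' Write composition profiles as twin TSV/JSON reports
#'
#' One row per (record, region class, metric), full precision plus a
#' rounded display column (1 decimal for percentages, 2 for skews).
#' \code{<path>.tsv} and \code{<path>.json} are written and agree
#' value-for-value.
#'
#' @param profiles a profile data.frame from \code{\link{profile_record}},
#'   or a (possibly named) list of them.
#' @param path output path stem (extensions are appended).
#' @return character vector of the two file paths, invisibly.
#' @export
write_profile_report <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  long <- list()
  for (p in profiles) {
    rid <- attr(p, "record_id")
    if (is.null(rid)) rid <- NA_character_
    if (nrow(p) == 0) next
    metrics <- c("at_percent", "gc_percent", "at_skew", "gc_skew")
    for (m in metrics) {
      long[[length(long) + 1L]] <- data.frame(
        record_id = rid, region_class = p$region_class, metric = m,
        value = p[[m]], display = .round_display(m, p[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(long)) do.call(rbind, long)
         else data.frame(record_id = character(0), region_class = character(0),
                         metric = character(0), value = numeric(0),
                         display = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$record_id, out$region_class, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  tsv <- paste0(path, ".tsv"); json <- paste0(path, ".json")
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out, json, digits = NA, na = "null", auto_unbox = FALSE)
  invisible(c(tsv, json))
}

#' Read one per-gene alignment from FASTA
#'
#' @param path aligned FASTA (gaps "-").
#' @param gene canonical gene token; defaults to the canonicalized file
#'   name.
#' @return an \code{alignment_block}.
#' @export
read_alignment_fasta <- function(path, gene = NULL) {
  if (is.null(gene)) {
    gene <- canonicalize_gene_name(tools::file_path_sans_ext(basename(path)))
    if (gene == "unknown")
      stop("cannot infer gene name from file name; pass `gene`")
  }
  x <- Biostrings::readDNAStringSet(path)
  alignment_block(gene, stats::setNames(as.character(x), names(x)))
}
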