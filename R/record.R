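# GenomeRecord: one annotated mitogenome. Internal coordinates are 0-based
# half-open on the J-strand; wrap-around features on circular genomes are
# stored unwrapped (end > genome length).

#' Construct an annotated mitogenome record
#'
#' @param record_id free-text identifier.
#' @param sequence nucleotide string over A/C/G/T/N and IUPAC ambiguity
#'   codes (J-strand as deposited). Case-insensitive; stored uppercase,
#'   ambiguity codes preserved verbatim.
#' @param features data.frame with columns \code{name} (canonical token),
#'   \code{strand} ("J"/"N"), \code{start}, \code{end} (0-based half-open)
#'   and optionally \code{class} and \code{frame_offset} (0-2, PCGs only;
#'   default 0). Rows are sorted by \code{start}.
#' @param is_circular logical; circular molecule.
#' @param is_complete logical; fully sequenced (control region included).
#' @param check_census warn when a complete record does not carry the
#'   37-gene census.
#' @return an object of class \code{mito_record}.
#' @export
mito_record <- function(record_id, sequence, features,
                        is_circular = TRUE, is_complete = TRUE,
                        check_census = is_complete) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!grepl("^[ACGTUNRYSWKMBDHV]*$", sequence))
    stop("sequence contains non-IUPAC characters")
  L <- nchar(sequence)
  if (is.null(features) || nrow(features) == 0) {
    features <- data.frame(name = character(0), class = character(0),
                           strand = character(0), start = integer(0),
                           end = integer(0), frame_offset = integer(0),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    if (is.null(features$class)) features$class <- gene_class(features$name)
    if (is.null(features$frame_offset)) features$frame_offset <- 0L
    features$frame_offset[is.na(features$frame_offset)] <- 0L
    req <- c("name", "class", "strand", "start", "end", "frame_offset")
    missing_cols <- setdiff(req, names(features))
    if (length(missing_cols))
      stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
    features <- features[req]
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features$frame_offset <- as.integer(features$frame_offset)
    if (any(features$start >= features$end))
      stop("feature spans must satisfy start < end (after circular unwrapping)")
    if (!all(features$strand %in% c("J", "N")))
      stop("feature strand must be 'J' or 'N'")
    hi <- if (is_circular) 2L * L else L
    if (any(features$start < 0L) || any(features$end > hi) ||
        any(features$start >= L))
      stop("feature coordinates outside the genome (length ", L, ")")
    if (!is_circular && any(features$end > L))
      stop("wrap-around feature on a non-circular record")
    known <- features$name[features$name %in% MITO_GENES]
    if (anyDuplicated(known))
      stop("duplicate canonical feature names: ",
           paste(unique(known[duplicated(known)]), collapse = ", "))
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  rec <- structure(
    list(record_id = record_id, sequence = sequence,
         is_circular = isTRUE(is_circular), is_complete = isTRUE(is_complete),
         features = features),
    class = "mito_record")
  if (check_census && rec$is_complete && nrow(features) > 0) {
    missing_genes <- setdiff(MITO_GENES, features$name)
    if (length(missing_genes))
      warning("complete record '", record_id, "' is missing ",
              length(missing_genes), " of the 37-gene census (plus CR): ",
              paste(utils::head(missing_genes, 5), collapse = ", "),
              if (length(missing_genes) > 5) ", ..." else "")
  }
  rec
}

#' @export
print.mito_record <- function(x, ...) {
  cls <- table(factor(x$features$class, levels = c("PCG", "tRNA", "rRNA", "CR")))
  cat("mito_record '", x$record_id, "': ", genome_length(x), " bp, ",
      if (x$is_circular) "circular" else "linear", ", ",
      if (x$is_complete) "complete" else "near-complete", "\n",
      "  features: ", nrow(x$features),
      " (PCG ", cls[["PCG"]], ", tRNA ", cls[["tRNA"]],
      ", rRNA ", cls[["rRNA"]], ", CR ", cls[["CR"]], ")\n", sep = "")
  invisible(x)
}

#' Genome length of a record
#' @param record a \code{mito_record}.
#' @return integer length in bp.
#' @export
genome_length <- function(record) nchar(record$sequence)

# complement map covering IUPAC ambiguity codes
.comp_from <- "ACGTUNRYSWKMBDHV"
.comp_to   <- "TGCAANYRSWMKVHDB"

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware; preserves ambiguity codes (complementing them), never
#' converts N.
#' @param seq character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- chartr(.comp_from, .comp_to, toupper(s))
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# genome slice [start, end) with circular unwrap (end may exceed L)
.slice <- function(record, start, end) {
  L <- genome_length(record)
  if (end <= L) return(substr(record$sequence, start + 1L, end))
  paste0(substr(record$sequence, start + 1L, L),
         substr(record$sequence, 1L, end - L))
}

#' Extract the sense-strand sequence of a feature
#'
#' Returns the genome slice of the feature span, reverse-complemented for
#' N-strand features, with circular wrap-around handled.
#'
#' @param record a \code{mito_record}.
#' @param name canonical gene token, or a row index into
#'   \code{record$features}.
#' @return nucleotide string (sense strand of the gene).
#' @export
feature_seq <- function(record, name) {
  f <- record$features
  i <- if (is.numeric(name)) as.integer(name) else match(name, f$name)
  if (is.na(i) || i < 1 || i > nrow(f)) stop("no such feature: ", name)
  s <- .slice(record, f$start[i], f$end[i])
  if (f$strand[i] == "N") s <- revcomp(s)
  s
}

#' Rotate the origin of a circular record
#'
#' Moves the sequence origin forward by \code{offset} bases; features are
#' re-projected (a feature spanning the new origin becomes an unwrapped
#' wrap-around feature). Composition, junction and codon statistics are
#' invariant under rotation.
#'
#' @param record a circular \code{mito_record}.
#' @param offset integer in [0, genome length).
#' @return rotated \code{mito_record}.
#' @export
rotate_record <- function(record, offset) {
  if (!record$is_circular) stop("cannot rotate a non-circular record")
  L <- genome_length(record)
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(record)
  seq2 <- paste0(substr(record$sequence, offset + 1L, L),
                 substr(record$sequence, 1L, offset))
  f <- record$features
  if (nrow(f)) {
    len <- f$end - f$start
    f$start <- (f$start - offset) %% L
    f$end <- f$start + len
  }
  mito_record(record$record_id, seq2, f, record$is_circular,
              record$is_complete, check_census = FALSE)
}

#' Reverse the orientation of a record
#'
#' Reverse-complements the deposited strand and flips feature strands and
#' coordinates. Junction lengths/relations and sense-strand statistics are
#' preserved.
#'
#' @param record a \code{mito_record}.
#' @return reversed \code{mito_record}.
#' @export
reverse_record <- function(record) {
  L <- genome_length(record)
  f <- record$features
  if (nrow(f)) {
    len <- f$end - f$start
    new_start <- (L - (f$end %% L)) %% L
    f2 <- f
    f2$start <- as.integer(new_start)
    f2$end <- as.integer(new_start + len)
    f2$strand <- ifelse(f$strand == "J", "N", "J")
    f <- f2
  }
  mito_record(record$record_id, revcomp(record$sequence), f,
              record$is_circular, record$is_complete, check_census = FALSE)
}
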