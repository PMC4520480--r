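# GenBank flat-file reader/writer for annotated mitogenomes. The reader
# covers the constructs these records actually use: CDS/tRNA/rRNA, D-loop or
# misc_feature control regions, complement() strands, two-segment join()
# across the circular origin, partial-span markers (< >), /gene, /product
# and /codon_start qualifiers. No pre-installed R package parses GenBank
# flat files, so this dialect subset is implemented here.

.gb_feature_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")

# "complement(join(123..456,1..78))" -> list(start0, end0_unwrapped, strand)
.parse_location <- function(loc, genome_length, is_circular) {
  raw <- loc
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    iv <- lapply(parts, .parse_span)
    if (length(iv) == 2 && is_circular &&
        iv[[1]][2] == genome_length && iv[[2]][1] == 1) {
      return(list(start = iv[[1]][1] - 1L, end = genome_length + iv[[2]][2],
                  strand = strand))
    }
    stop("unsupported join() location: ", raw)
  }
  iv <- .parse_span(loc)
  list(start = iv[1] - 1L, end = iv[2], strand = strand)
}

.parse_span <- function(x) {
  if (grepl("^\\d+$", x)) {
    v <- as.integer(x)
    return(c(v, v))
  }
  if (!grepl("^\\d+\\.\\.\\d+$", x)) stop("unparseable span: ", x)
  as.integer(strsplit(x, "..", fixed = TRUE)[[1]][c(1, 2)])
}

#' Read a GenBank flat file into a mitogenome record
#'
#' Parses sequence, topology and CDS/tRNA/rRNA/D-loop/misc_feature
#' annotations; gene names are resolved to canonical tokens via the bundled
#' synonym map (\code{/gene} first, then \code{/product}); complement-strand
#' features map to strand "N"; \code{/codon_start} maps to the reading-frame
#' offset. A feature whose label cannot be canonicalized is retained with
#' its raw label and a class inferred from the feature key, with a warning.
#'
#' @param path path to a GenBank flat file.
#' @param is_complete completeness flag; defaults to the LOCUS topology
#'   (circular records are taken as complete).
#' @return a \code{mito_record}.
#' @export
read_genbank <- function(path, is_complete = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (missing LOCUS line): ", path)
  is_circular <- grepl("\\bcircular\\b", lines[1], ignore.case = TRUE)
  record_id <- {
    toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(toks) >= 2) toks[2] else basename(path)
  }
  acc <- grep("^ACCESSION\\s+\\S", lines, value = TRUE)
  if (length(acc)) record_id <- strsplit(trimws(acc[1]), "\\s+")[[1]][2]

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN section: ", path)
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(end_rec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  L <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  features <- NULL
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(ori[1] - 1L)]
    # a new feature starts with a key in columns 6-20 (i.e. 5 leading spaces)
    starts <- grep("^ {5}\\S", block)
    entries <- list()
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1] - 1L else length(block)
      entry <- block[from:to]
      key <- sub("^\\s*(\\S+).*$", "\\1", entry[1])
      if (!(key %in% .gb_feature_keys)) next
      body <- paste(trimws(entry), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+"), "", trimws(entry[1]))
      # location may continue over lines until the first qualifier
      extra <- entry[-1]
      qual_start <- grep("^\\s*/", extra)
      if (length(qual_start) && qual_start[1] > 1)
        loc <- paste0(loc, paste(trimws(extra[seq_len(qual_start[1] - 1)]), collapse = ""))
      else if (!length(qual_start) && length(extra))
        loc <- paste0(loc, paste(trimws(extra), collapse = ""))
      q <- function(name) {
        m <- regmatches(body, regexpr(paste0("/", name, '="[^"]*"'), body))
        if (!length(m)) {
          m <- regmatches(body, regexpr(paste0("/", name, "=[^ /]+"), body))
          if (!length(m)) return(NA_character_)
          return(sub(paste0("/", name, "="), "", m))
        }
        sub(paste0("/", name, '="([^"]*)"'), "\\1", m)
      }
      entries[[length(entries) + 1L]] <-
        list(key = key, loc = loc, gene = q("gene"), product = q("product"),
             codon_start = q("codon_start"))
    }
    if (length(entries)) {
      rows <- lapply(entries, function(e) {
        pos <- .parse_location(e$loc, L, is_circular)
        label <- if (!is.na(e$gene)) e$gene else e$product
        canon <- if (is.na(label)) "unknown" else canonicalize_gene_name(label)
        if (canon == "unknown" && e$key %in% c("D-loop")) canon <- "CR"
        cls <- gene_class(canon)
        if (is.na(cls)) {
          cls <- switch(e$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                        "D-loop" = "CR", misc_feature = "CR")
          warning("cannot canonicalize feature label '",
                  if (is.na(label)) e$key else label,
                  "'; retained with class ", cls)
          canon <- if (is.na(label)) paste0("unknown_", e$key) else label
        }
        off <- 0L
        if (!is.na(e$codon_start)) off <- as.integer(e$codon_start) - 1L
        data.frame(name = canon, class = cls, strand = pos$strand,
                   start = pos$start, end = pos$end, frame_offset = off,
                   stringsAsFactors = FALSE)
      })
      features <- do.call(rbind, rows)
      # drop duplicate rows for the same canonical gene (e.g. gene + CDS pairs)
      features <- features[!duplicated(features$name) |
                             !(features$name %in% MITO_GENES), , drop = FALSE]
    }
  }
  if (is.null(is_complete)) is_complete <- is_circular
  mito_record(record_id, sequence, features, is_circular, is_complete,
              check_census = FALSE)
}

.fmt_location <- function(start, end, strand, L) {
  loc <- if (end <= L) paste0(start + 1L, "..", end)
         else paste0("join(", start + 1L, "..", L, ",1..", end - L, ")")
  if (strand == "N") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN sections with 1-based inclusive coordinates,
#' \code{complement()} for N-strand features, a two-segment \code{join()}
#' for features crossing the circular origin, and \code{/codon_start} for
#' nonzero reading-frame offsets. Output round-trips through
#' \code{\link{read_genbank}}.
#'
#' @param record a \code{mito_record}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genbank <- function(record, path) {
  L <- genome_length(record)
  topo <- if (record$is_circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   INV %s",
                   record$record_id, L, topo, format(Sys.Date(), "%d-%b-%Y")),
           sprintf("DEFINITION  %s mitochondrion%s.", record$record_id,
                   if (record$is_complete) ", complete genome"
                   else ", nearly complete genome"),
           sprintf("ACCESSION   %s", record$record_id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$class[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", "misc_feature")
    loc <- .fmt_location(f$start[i], f$end[i], f$strand[i], L)
    out <- c(out,
             sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", f$name[i]))
    if (f$class[i] == "PCG" && f$frame_offset[i] > 0L)
      out <- c(out, sprintf("                     /codon_start=%d",
                            f$frame_offset[i] + 1L))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
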