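# Base-pair-type census for given RNA secondary structures (dot-bracket).
# The package does not predict structures; it counts pair classes in
# structures supplied by the user (Watson-Crick, G-U wobble, mismatches
# such as the U-U pairs of muscoid tRNA arms).

#' Count base-pair types in a dot-bracket secondary structure
#'
#' Pairs are extracted by bracket matching; each pair is classified as
#' Watson-Crick (A-U, G-C), G-U wobble, or mismatch (keyed by the
#' unordered base pair, e.g. "U-U"). T is read as U.
#'
#' @param sequence RNA or DNA string, same length as \code{structure}.
#' @param structure dot-bracket string over ".()".
#' @return list of class \code{pair_type_counts}: \code{counts} (data.frame
#'   pair/class/count), \code{n_pairs}, and per-class totals \code{wc},
#'   \code{wobble}, \code{mismatch}.
#' @examples
#' count_pair_types("GGGAAACCC", "(((...)))")
#' @export
count_pair_types <- function(sequence, structure) {
  if (nchar(sequence) != nchar(structure))
    stop("sequence and structure lengths differ")
  if (grepl("[^.()]", structure))
    stop("structure may contain only '.', '(' and ')'")
  seq <- chartr("T", "U", toupper(sequence))
  sch <- strsplit(structure, "", fixed = TRUE)[[1]]
  bch <- strsplit(seq, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(sch)) {
    if (sch[i] == "(") {
      stack <- c(stack, i)
    } else if (sch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1L]] <- c(j, i)
    }
  }
  if (length(stack)) stop("unbalanced structure: unmatched '('")
  keys <- vapply(pairs, function(p) paste(sort(bch[p]), collapse = "-"),
                 character(1))
  cls <- vapply(keys, function(k) {
    if (k %in% c("A-U", "C-G")) "WC"
    else if (k == "G-U") "wobble"
    else "mismatch"
  }, character(1), USE.NAMES = FALSE)
  if (length(keys)) {
    tab <- table(keys)
    counts <- data.frame(pair = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts$class <- vapply(counts$pair, function(k) {
      if (k %in% c("A-U", "C-G")) "WC" else if (k == "G-U") "wobble" else "mismatch"
    }, character(1), USE.NAMES = FALSE)
    counts <- counts[order(counts$class, counts$pair),
                     c("pair", "class", "count")]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(pair = character(0), class = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, n_pairs = length(pairs),
                 wc = sum(cls == "WC"), wobble = sum(cls == "wobble"),
                 mismatch = sum(cls == "mismatch")),
            class = "pair_type_counts")
}

#' @export
print.pair_type_counts <- function(x, ...) {
  cat("pair types over", x$n_pairs, "paired positions: WC", x$wc,
      "| wobble", x$wobble, "| mismatch", x$mismatch, "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Read a structure file (one record per line: id, sequence, structure)
#'
#' @param path tab-separated text file.
#' @return data.frame with columns \code{id}, \code{sequence},
#'   \code{structure}.
#' @export
read_structures <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sequence", "structure"))
  if (!nrow(tab)) stop("empty structure file: ", path)
  tab
}
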