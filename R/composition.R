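# Strand-, gene-class- and codon-position-resolved nucleotide composition,
# AT/GC skews and codon usage. Every gene-class row is computed on the
# sense strand of its genes (concatenated): this is the convention that
# reproduces the opposite-sign GC-skews of J- vs N-strand PCGs.

.base_counts <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  c(A = sum(ch == "A"), T = sum(ch == "T"), G = sum(ch == "G"),
    C = sum(ch == "C"),
    ambiguous = sum(!(ch %in% c("A", "T", "G", "C"))))
}

#' Base composition of a nucleotide sequence
#'
#' Fractions are computed over unambiguous bases only; ambiguity codes
#' (including N) are counted separately and excluded from denominators.
#'
#' @param seq nucleotide string.
#' @return list with integer \code{counts} (A/T/G/C/ambiguous), fractions
#'   \code{a,t,g,c}, and \code{at_percent}, \code{gc_percent} (0-100).
#' @export
base_composition <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop("empty sequence")
  n <- .base_counts(seq)
  tot <- sum(n[c("A", "T", "G", "C")])
  if (tot == 0) stop("sequence has no unambiguous bases")
  list(counts = n,
       a = n[["A"]] / tot, t = n[["T"]] / tot,
       g = n[["G"]] / tot, c = n[["C"]] / tot,
       at_percent = 100 * (n[["A"]] + n[["T"]]) / tot,
       gc_percent = 100 * (n[["G"]] + n[["C"]]) / tot)
}

#' AT- and GC-skew of a nucleotide sequence
#'
#' AT-skew = (A - T)/(A + T); GC-skew = (G - C)/(G + C), on the strand as
#' given. A zero denominator yields \code{NA} for that component (reported
#' as null in JSON output), not an error.
#'
#' @param seq nucleotide string.
#' @return list with \code{at_skew} and \code{gc_skew}.
#' @export
skews <- function(seq) {
  n <- .base_counts(seq)
  at <- n[["A"]] + n[["T"]]; gc <- n[["G"]] + n[["C"]]
  list(at_skew = if (at == 0) NA_real_ else (n[["A"]] - n[["T"]]) / at,
       gc_skew = if (gc == 0) NA_real_ else (n[["G"]] - n[["C"]]) / gc)
}

.profile_row <- function(region_class, seq) {
  n <- .base_counts(seq)
  tot <- sum(n[c("A", "T", "G", "C")])
  sk <- skews(seq)
  data.frame(region_class = region_class,
             A = n[["A"]], T = n[["T"]], G = n[["G"]], C = n[["C"]],
             ambiguous = n[["ambiguous"]],
             at_percent = if (tot) 100 * (n[["A"]] + n[["T"]]) / tot else NA_real_,
             gc_percent = if (tot) 100 * (n[["G"]] + n[["C"]]) / tot else NA_real_,
             at_skew = sk$at_skew, gc_skew = sk$gc_skew,
             stringsAsFactors = FALSE)
}

# sense-strand sequence of a PCG with frame offset applied and the trailing
# partial codon optionally trimmed
.pcg_sense <- function(record, i, trim_partial = FALSE) {
  s <- feature_seq(record, i)
  off <- record$features$frame_offset[i]
  if (off > 0) s <- substr(s, off + 1L, nchar(s))
  if (trim_partial) {
    rem <- nchar(s) %% 3L
    if (rem > 0) s <- substr(s, 1L, nchar(s) - rem)
  }
  s
}

.codon_pos_chars <- function(seq, pos) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return("")
  idx <- 3L * seq_len(n) - 3L + pos
  paste(substring(seq, idx, idx), collapse = "")
}

#' Region-class composition profile of a mitogenome
#'
#' Computes the full set of region-class rows: J- and N-strand PCG sets
#' concatenated on their sense strands, codon positions 1-3 per strand
#' class, all tRNAs (sense), each rRNA (sense), the control region when
#' annotated, and the whole genome on the J-strand for complete records.
#' Partial terminal codons are excluded from codon-position rows (a
#' position label is undefined for an incomplete codon); complete stop
#' codons are included. Missing region classes are omitted with a warning.
#'
#' @param record a \code{mito_record} with canonicalized features.
#' @return data.frame (one row per region class) with base counts,
#'   A+T\%/G+C\% and AT/GC skews; attribute \code{record_id}.
#' @export
profile_record <- function(record) {
  f <- record$features
  rows <- list()
  add <- function(region_class, seq) {
    if (!is.null(seq) && nzchar(seq))
      rows[[length(rows) + 1L]] <<- .profile_row(region_class, seq)
    else
      warning("region class ", region_class, " absent in record '",
              record$record_id, "'; row omitted")
  }
  for (strand in c("J", "N")) {
    idx <- which(f$class == "PCG" & f$strand == strand)
    idx <- idx[order(f$start[idx])]
    if (!length(idx)) {
      warning("no ", strand, "-strand PCGs in record '", record$record_id, "'")
      next
    }
    whole <- paste(vapply(idx, function(i) .pcg_sense(record, i),
                          character(1)), collapse = "")
    add(paste0("PCG_", strand), whole)
    trimmed <- vapply(idx, function(i) .pcg_sense(record, i, trim_partial = TRUE),
                      character(1))
    for (pos in 1:3) {
      add(paste0("pos", pos, "_", strand),
          paste(vapply(trimmed, .codon_pos_chars, character(1), pos = pos),
                collapse = ""))
    }
  }
  trna_idx <- which(f$class == "tRNA")
  if (length(trna_idx))
    add("tRNA", paste(vapply(trna_idx[order(f$start[trna_idx])],
                             function(i) feature_seq(record, i), character(1)),
                      collapse = ""))
  else warning("no tRNAs in record '", record$record_id, "'")
  if ("rrnL" %in% f$name) add("rRNA_large", feature_seq(record, "rrnL"))
  if ("rrnS" %in% f$name) add("rRNA_small", feature_seq(record, "rrnS"))
  if ("CR" %in% f$name) add("CR", feature_seq(record, "CR"))
  if (record$is_complete) add("whole_genome", record$sequence)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "record_id") <- record$record_id
  out
}

#' Codon usage table of a mitogenome
#'
#' Sense-strand codon counts per PCG (reading-frame offset applied,
#' trailing partial stop excluded -- it is not a full codon) and
#' aggregated over all PCGs, with per-codon percentages and the start/stop
#' calls of \code{\link{classify_codons}} attached.
#'
#' @param record a \code{mito_record}.
#' @return list of class \code{codon_usage_table}: \code{per_gene} (long
#'   data.frame gene/codon/count), \code{aggregate} (codon/count/percent
#'   over all 64 codons), \code{calls}.
#' @export
codon_usage <- function(record) {
  f <- record$features
  pcgs <- which(f$class == "PCG")
  all_codons <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                      paste0), c("T", "C", "A", "G"), paste0))
  per <- lapply(pcgs, function(i) {
    codons <- .codons_of(.pcg_sense(record, i, trim_partial = TRUE))
    tab <- table(factor(codons, levels = sort(all_codons)))
    data.frame(gene = f$name[i], codon = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  per_gene <- if (length(per)) do.call(rbind, per)
              else data.frame(gene = character(0), codon = character(0),
                              count = integer(0), stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ codon, per_gene, sum)
  if (!nrow(agg)) agg <- data.frame(codon = sort(all_codons), count = 0L)
  agg$percent <- if (sum(agg$count)) 100 * agg$count / sum(agg$count) else NA_real_
  structure(list(per_gene = per_gene, aggregate = agg,
                 calls = classify_codons(record)),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("codon usage over", length(unique(x$per_gene$gene)), "PCGs,",
      sum(x$aggregate$count), "codons\n")
  print(utils::head(x$aggregate[order(-x$aggregate$count), ], 10),
        row.names = FALSE)
  invisible(x)
}

#' Cross-species summary of composition profiles
#'
#' Unweighted mean of each metric per region class across records (cells
#' missing in some records are averaged over the records that have them,
#' with the count reported), plus codon-position composition pooled over
#' strand classes and species by summing base counts.
#'
#' @param profiles list of data.frames from \code{\link{profile_record}}.
#' @return list with \code{mean_profile} (region_class x metric means and
#'   \code{n_records}) and \code{codon_position_pooled} (per codon
#'   position: pooled A+T\%, G+C\%, skews).
#' @export
aggregate_species <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  if (is.data.frame(profiles)) profiles <- list(profiles)
  all <- do.call(rbind, lapply(profiles, function(p) {
    p$record_id <- attr(p, "record_id")
    p
  }))
  metrics <- c("at_percent", "gc_percent", "at_skew", "gc_skew")
  mean_profile <- do.call(rbind, lapply(split(all, all$region_class), function(d) {
    out <- data.frame(region_class = d$region_class[1], stringsAsFactors = FALSE)
    for (m in metrics) out[[m]] <- mean(d[[m]], na.rm = TRUE)
    out$n_records <- nrow(d)
    out
  }))
  rownames(mean_profile) <- NULL
  pooled <- do.call(rbind, lapply(1:3, function(pos) {
    d <- all[all$region_class %in% paste0("pos", pos, c("_J", "_N")), , drop = FALSE]
    A <- sum(d$A); T <- sum(d$T); G <- sum(d$G); C <- sum(d$C)
    data.frame(position = pos,
               at_percent = 100 * (A + T) / (A + T + G + C),
               gc_percent = 100 * (G + C) / (A + T + G + C),
               at_skew = (A - T) / (A + T), gc_skew = (G - C) / (G + C))
  }))
  list(mean_profile = mean_profile, codon_position_pooled = pooled,
       n_records = length(profiles))
}
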