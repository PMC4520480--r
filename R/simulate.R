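# Seeded generator of annotated circular insect mitogenomes with the
# muscoid statistical profile: ancestral gene order, strong A+T bias with
# opposite-sign GC-skew by strand, characteristic overlaps (ATP8/ATP6 7 bp,
# trnW/trnC 8 bp), the 27-bp TA-repeat spacer between trnS1 and trnE, the
# conserved 18-bp trnE/trnF spacer, non-canonical COX1/ND1 starts and T
# partial stops for COX2/ND5. Emits a ground-truth manifest so downstream
# analyses can be verified by round-trip.

# default gene lengths (bp); PCG lengths mod 3 encode the stop class
.default_gene_lengths <- c(
  ND2 = 1023L, COX1 = 1536L, COX2 = 685L, ATP8 = 159L, ATP6 = 678L,
  COX3 = 786L, ND3 = 354L, ND5 = 1720L, ND4 = 1341L, ND4L = 294L,
  ND6 = 522L, CYTB = 1134L, ND1 = 939L,
  trnI = 69L, trnQ = 69L, trnM = 69L, trnW = 68L, trnC = 65L, trnY = 66L,
  trnL2 = 66L, trnK = 71L, trnD = 68L, trnG = 65L, trnA = 67L, trnR = 65L,
  trnN = 66L, trnS1 = 67L, trnE = 66L, trnF = 66L, trnH = 67L, trnT = 65L,
  trnP = 66L, trnS2 = 68L, trnL1 = 65L, trnV = 72L, rrnL = 1325L,
  rrnS = 789L, CR = 1000L
)

.default_start_spec <- c(
  ND2 = "ATT", COX1 = "TCG", COX2 = "ATG", ATP8 = "ATC", ATP6 = "ATG",
  COX3 = "ATG", ND3 = "ATT", ND5 = "ATT", ND4 = "ATG", ND4L = "ATG",
  ND6 = "ATT", CYTB = "ATG", ND1 = "TTG"
)

.default_stop_spec <- c(
  ND2 = "TAA", COX1 = "TAA", COX2 = "T", ATP8 = "TAA", ATP6 = "TAA",
  COX3 = "TAA", ND3 = "TAA", ND5 = "T", ND4 = "TAA", ND4L = "TAA",
  ND6 = "TAA", CYTB = "TAA", ND1 = "TAA"
)

#' Default microsatellite-like TA-repeat spacer
#'
#' The 27-bp TA(n) intergenic spacer emitted between trnS1 and trnE by the
#' default simulation parameters (the longest spacer of the simulated
#' genome).
#' @format character scalar, 27 nt.
#' @export
TA_REPEAT_SPACER <- "GATATAAATTATATATATATATATATA"

.default_junction_spec <- data.frame(
  upstream  = c("ATP8", "trnW", "trnS1", "trnE"),
  downstream = c("ATP6", "trnC", "trnE", "trnF"),
  relation  = c("overlap", "overlap", "spacer", "spacer"),
  length    = c(7L, 8L, 27L, 18L),
  stringsAsFactors = FALSE
)

# per-class composition targets: A+T fraction, AT-skew, GC-skew on the
# SENSE strand of each gene class (muscoid values)
.default_composition <- list(
  PCG_J = c(at = 0.749, at_skew = -0.13, gc_skew = -0.09),
  PCG_N = c(at = 0.785, at_skew = -0.20, gc_skew = 0.28),
  tRNA  = c(at = 0.775, at_skew = 0.00, gc_skew = 0.10),
  rRNA  = c(at = 0.810, at_skew = -0.02, gc_skew = 0.29),
  CR    = c(at = 0.895, at_skew = 0.05, gc_skew = -0.09),
  spacer = c(at = 0.850, at_skew = 0.00, gc_skew = 0.00)
)

#' Parameters for the synthetic mitogenome generator
#'
#' Defaults emulate a muscoid fly mitogenome: 37 genes plus control region
#' in the ancestral insect order, per-class A+T/skew targets from the
#' muscoid range, the characteristic overlaps and spacers, non-canonical
#' start codons for COX1 (TCG) and ND1 (TTG), ATN starts elsewhere, and T
#' partial stops for COX2 and ND5.
#'
#' @param seed integer RNG seed (required for generation).
#' @param gene_order data.frame gene/strand (default the ancestral order).
#' @param gene_lengths named integer vector of gene lengths (bp). PCG
#'   lengths must be compatible with the stop spec (mod 3 = 0 for TAA/TAG,
#'   1 for "T", 2 for "TA").
#' @param composition named list of per-class targets, each
#'   \code{c(at=, at_skew=, gc_skew=)} for PCG_J, PCG_N, tRNA, rRNA, CR,
#'   spacer (sense strand).
#' @param junction_spec data.frame upstream/downstream/relation/length;
#'   adjacent pairs not listed abut. Lengths must be >= 1.
#' @param start_spec,stop_spec named codon maps for the 13 PCGs.
#' @param include_cr include a control region (complete genome); when
#'   FALSE the record is emitted near-complete and linearized, as for
#'   genomes whose control region could not be sequenced.
#' @param length_scale positive multiplier applied to PCG/rRNA/CR lengths
#'   (tRNAs untouched), for cheap desk-scale fixtures. Scaled PCG lengths
#'   are re-rounded to preserve stop-class compatibility.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(seed = NULL,
                       gene_order = ANCESTRAL_INSECT_ORDER,
                       gene_lengths = .default_gene_lengths,
                       composition = .default_composition,
                       junction_spec = .default_junction_spec,
                       start_spec = .default_start_spec,
                       stop_spec = .default_stop_spec,
                       include_cr = TRUE,
                       length_scale = 1) {
  stopifnot(length_scale > 0)
  if (length_scale != 1) {
    for (g in names(gene_lengths)) {
      cls <- gene_class(g)
      if (is.na(cls) || cls == "tRNA") next
      len <- as.integer(round(gene_lengths[[g]] * length_scale))
      if (cls == "PCG") {
        rem <- switch(stop_spec[[g]], T = 1L, TA = 2L, 0L)
        len <- max(9L + rem, 3L * (len %/% 3L) + rem)
      }
      gene_lengths[[g]] <- len
    }
  }
  for (cl in names(composition)) {
    p <- composition[[cl]]
    if (p[["at"]] <= 0 || p[["at"]] >= 1 || abs(p[["at_skew"]]) > 1 ||
        abs(p[["gc_skew"]]) > 1)
      stop("invalid composition target for class ", cl)
  }
  if (any(junction_spec$length < 1))
    stop("junction lengths must be >= 1")
  structure(list(seed = seed, gene_order = gene_order,
                 gene_lengths = gene_lengths, composition = composition,
                 junction_spec = junction_spec, start_spec = start_spec,
                 stop_spec = stop_spec, include_cr = isTRUE(include_cr)),
            class = "sim_params")
}

# per-base probabilities from (A+T, AT-skew, GC-skew)
.base_probs <- function(target) {
  at <- target[["at"]]; s <- target[["at_skew"]]; g <- target[["gc_skew"]]
  c(A = at * (1 + s) / 2, T = at * (1 - s) / 2,
    G = (1 - at) * (1 + g) / 2, C = (1 - at) * (1 - g) / 2)
}

.draw_bases <- function(n, probs) {
  if (n <= 0) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# n in-frame codons with TAA/TAG rejected (invertebrate mito code stops)
.draw_codons <- function(n, probs) {
  if (n <= 0) return(character(0))
  out <- character(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.2))
    b <- matrix(sample(names(probs), 3L * m, replace = TRUE, prob = probs),
                ncol = 3L)
    cod <- paste0(b[, 1], b[, 2], b[, 3])
    out <- c(out, cod[!(cod %in% c("TAA", "TAG"))])
  }
  out[seq_len(n)]
}

.sim_gene_seq <- function(gene, len, strand, params) {
  cls <- gene_class(gene)
  if (cls == "PCG") {
    start <- params$start_spec[[gene]]
    stop <- params$stop_spec[[gene]]
    rem <- len %% 3L
    want <- switch(stop, T = 1L, TA = 2L, 0L)
    if (rem != want)
      stop("length of ", gene, " (", len, ") incompatible with stop codon ",
           stop)
    probs <- .base_probs(params$composition[[paste0("PCG_", strand)]])
    n_mid <- (len - want) %/% 3L - 1L - (want == 0L)
    mid <- .draw_codons(n_mid, probs)
    paste0(start, paste(mid, collapse = ""), stop)
  } else {
    key <- switch(cls, tRNA = "tRNA", rRNA = "rRNA", CR = "CR")
    .draw_bases(len, .base_probs(params$composition[[key]]))
  }
}

#' Simulate an annotated mitogenome with a ground-truth manifest
#'
#' Genes are drawn base-by-base (tRNA/rRNA/CR, iid from per-class base
#' probabilities derived from the A+T/skew targets) or codon-by-codon
#' (PCGs, with in-frame TAA/TAG rejected so every ORF is clean); specified
#' start/stop codons and junctions are imposed exactly, and a repair pass
#' re-draws any base whose overlap-induced context created an in-frame
#' stop. With \code{include_cr = FALSE} the control region is dropped and
#' the record emitted near-complete (linear for junction purposes). Fixed
#' seed and parameters give byte-identical output (Mersenne-Twister,
#' integer draws only).
#'
#' @param params a \code{\link{sim_params}} object.
#' @param seed overrides \code{params$seed}.
#' @return list with elements \code{record} (a \code{mito_record}) and
#'   \code{manifest} (features, junctions, codon calls, realized per-class
#'   composition, parameters).
#' @export
simulate_genome <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) params$seed <- seed
  if (is.null(params$seed)) stop("a seed is required for simulation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(params$seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")

  ord <- params$gene_order
  if (!params$include_cr) ord <- ord[ord$gene != "CR", , drop = FALSE]
  jspec <- params$junction_spec
  jkey <- paste(jspec$upstream, jspec$downstream, sep = "->")

  lens <- params$gene_lengths
  # sanity: overlaps must fit inside both flanking genes
  for (k in which(jspec$relation == "overlap")) {
    if (jspec$length[k] >= min(lens[[jspec$upstream[k]]],
                               lens[[jspec$downstream[k]]]))
      stop("infeasible junction: overlap ", jspec$length[k], " bp exceeds ",
           jspec$upstream[k], "/", jspec$downstream[k])
  }

  n <- nrow(ord)
  genome <- character(0)   # per-base vector
  starts <- ends <- integer(n)
  locked <- integer(0)     # 0-based genome positions that must not be redrawn
  spacer_probs <- .base_probs(params$composition$spacer)

  cursor <- 0L
  for (i in seq_len(n)) {
    g <- ord$gene[i]; strand <- ord$strand[i]
    len <- lens[[g]]
    if (is.null(len)) stop("no length for gene ", g)
    gap <- 0L; spacer_seq <- NULL
    if (i > 1) {
      k <- match(paste(ord$gene[i - 1], g, sep = "->"), jkey)
      if (!is.na(k)) {
        if (jspec$relation[k] == "overlap") gap <- -jspec$length[k]
        else if (jspec$relation[k] == "spacer") {
          gap <- jspec$length[k]
          spacer_seq <- if (ord$gene[i - 1] == "trnS1" && g == "trnE" &&
                            gap == nchar(TA_REPEAT_SPACER)) TA_REPEAT_SPACER
                        else .draw_bases(gap, spacer_probs)
        }
      }
    }
    if (gap > 0) {
      sp <- strsplit(spacer_seq, "", fixed = TRUE)[[1]]
      genome[cursor + seq_len(gap)] <- sp
      if (!is.null(spacer_seq) && spacer_seq == TA_REPEAT_SPACER)
        locked <- c(locked, cursor + seq_len(gap) - 1L)
      cursor <- cursor + gap
    }
    start <- cursor + gap * (gap < 0)   # gap<0 rewinds into previous gene
    sense <- .sim_gene_seq(g, len, strand, params)
    contrib <- if (strand == "J") sense else revcomp(sense)
    cb <- strsplit(contrib, "", fixed = TRUE)[[1]]
    # write only positions beyond what exists, then impose start/stop
    new_region <- which(start + seq_len(len) - 1L >= cursor)
    genome[start + new_region] <- cb[new_region]
    if (gene_class(g) == "PCG") {
      # genome positions (1-based) of the imposed start and stop codons
      rem <- len %% 3L
      sense_idx_start <- 1:3
      sense_idx_stop <- (len - (if (rem == 0L) 2L else rem - 1L)):len
      gpos <- function(sidx) {
        if (strand == "J") start + sidx else start + (len - sidx + 1L)
      }
      # impose start/stop exactly, overwriting overlap-region content
      imp <- c(sense_idx_start, sense_idx_stop)
      pos1 <- vapply(imp, gpos, integer(1))
      sense_chars <- strsplit(sense, "", fixed = TRUE)[[1]]
      for (t in seq_along(imp)) {
        ch <- sense_chars[imp[t]]
        if (strand == "N") ch <- chartr("ACGT", "TGCA", ch)
        genome[pos1[t]] <- ch
      }
      locked <- c(locked, pos1 - 1L)
    }
    starts[i] <- start
    ends[i] <- start + len
    cursor <- max(cursor, ends[i])
  }
  L <- cursor
  sequence <- paste(genome, collapse = "")
  stopifnot(nchar(sequence) == L, !anyNA(genome))

  features <- data.frame(name = ord$gene, class = gene_class(ord$gene),
                         strand = ord$strand, start = starts, end = ends,
                         frame_offset = 0L, stringsAsFactors = FALSE)
  record <- mito_record(paste0("synthetic_", params$seed), sequence, features,
                        is_circular = params$include_cr,
                        is_complete = params$include_cr,
                        check_census = FALSE)
  record <- .repair_orfs(record, locked, params)
  manifest <- .build_manifest(record, params)
  list(record = record, manifest = manifest)
}

# redraw unlocked bases of in-frame stop codons created by imposed overlaps
.repair_orfs <- function(record, locked, params) {
  for (pass in 1:25) {
    dirty <- FALSE
    f <- record$features
    for (i in which(f$class == "PCG")) {
      if (validate_orf(record, f$name[i]) == 0L) next
      dirty <- TRUE
      s <- feature_seq(record, i)
      len <- nchar(s); rem <- len %% 3L
      body_len <- len - (if (rem == 0L) 3L else rem)
      codons <- .codons_of(substr(s, 1L, body_len))
      bad <- which(codons %in% c("TAA", "TAG"))
      bad <- setdiff(bad, 1L)  # never touch the imposed start codon
      seq_chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
      for (ci in bad) {
        sense_pos <- (3L * ci - 2L):(3L * ci)
        gpos0 <- if (f$strand[i] == "J") f$start[i] + sense_pos - 1L
                 else f$end[i] - sense_pos
        gpos0 <- gpos0 %% nchar(record$sequence)
        free <- which(!(gpos0 %in% locked))
        if (!length(free)) stop("cannot repair ORF of ", f$name[i],
                                ": stop codon fully locked")
        # flip the first free base to one that breaks the stop
        t <- free[1]
        probs <- .base_probs(params$composition[[paste0("PCG_", f$strand[i])]])
        repeat {
          ch <- sample(names(probs), 1L, prob = probs)
          cand <- codons[ci]
          substr(cand, t, t) <- ch
          if (!(cand %in% c("TAA", "TAG"))) break
        }
        gch <- if (f$strand[i] == "J") ch else chartr("ACGT", "TGCA", ch)
        seq_chars[gpos0[t] + 1L] <- gch
      }
      record$sequence <- paste(seq_chars, collapse = "")
    }
    if (!dirty) return(record)
  }
  stop("ORF repair did not converge")
}

.build_manifest <- function(record, params) {
  jr <- suppressWarnings(junctions(record, include_cr = TRUE))
  calls <- classify_codons(record)
  prof <- suppressWarnings(profile_record(record))
  list(features = record$features,
       junctions = as.data.frame(jr),
       junction_summary = attr(jr, "summary"),
       codon_calls = calls,
       realized_composition = prof,
       composition_targets = params$composition,
       seed = params$seed,
       include_cr = params$include_cr,
       genome_length = genome_length(record))
}

#' Degrade a complete simulated genome to a near-complete record
#'
#' Models records whose control region (or genome ends) could not be
#' sequenced. \code{drop_cr} removes the control region feature and
#' sequence and linearizes; \code{truncate_ends} additionally clips
#' \code{trim} bases from each end of the linearized molecule (features
#' falling wholly or partly outside are dropped).
#'
#' @param record a complete \code{mito_record} (CR annotated for
#'   \code{drop_cr}).
#' @param manifest its manifest (updated in the return value).
#' @param mode "drop_cr" or "truncate_ends".
#' @param trim bases clipped from each end in \code{truncate_ends} mode.
#' @return list with updated \code{record} and \code{manifest}.
#' @export
degrade <- function(record, manifest, mode = c("drop_cr", "truncate_ends"),
                    trim = 30L) {
  mode <- match.arg(mode)
  f <- record$features
  cr <- which(f$class == "CR")
  if (!length(cr)) stop("record has no control region to degrade")
  L <- genome_length(record)
  # rotate so the CR is the terminal feature, then cut it off
  record <- rotate_record(record, f$end[cr[1]] %% L)
  f <- record$features
  cr <- which(f$class == "CR")
  cut <- f$start[cr[1]]
  sequence <- substr(record$sequence, 1L, cut)
  f <- f[-cr, , drop = FALSE]
  f <- f[f$end <= cut, , drop = FALSE]
  if (mode == "truncate_ends") {
    trim <- as.integer(trim)
    sequence <- substr(sequence, trim + 1L, nchar(sequence) - trim)
    keep <- f$start >= trim & f$end <= trim + nchar(sequence)
    f <- f[keep, , drop = FALSE]
    f$start <- f$start - trim
    f$end <- f$end - trim
  }
  rec2 <- mito_record(record$record_id, sequence, f, is_circular = FALSE,
                      is_complete = FALSE, check_census = FALSE)
  manifest$features <- rec2$features
  jr <- suppressWarnings(junctions(rec2, include_cr = TRUE))
  manifest$junctions <- as.data.frame(jr)
  manifest$junction_summary <- attr(jr, "summary")
  manifest$codon_calls <- classify_codons(rec2)
  manifest$realized_composition <- suppressWarnings(profile_record(rec2))
  manifest$include_cr <- FALSE
  manifest$genome_length <- genome_length(rec2)
  list(record = rec2, manifest = manifest)
}
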