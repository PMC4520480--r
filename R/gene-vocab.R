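# Controlled vocabulary for the 37 genes of the insect mitochondrial genome
# plus the control region, with a synonym map covering the label dialects
# found in GenBank records (CO1/COI/cox1, 16S/lrRNA, tRNA-Ser(AGN), ...).

#' Canonical mitochondrial gene tokens
#'
#' The 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and the control
#' region (CR) of the typical insect mitogenome, as canonical tokens used
#' throughout the package. Leucine and serine tRNAs are split by codon
#' family: \code{trnL1} (CUN), \code{trnL2} (UUR), \code{trnS1} (AGN),
#' \code{trnS2} (UCN).
#'
#' @format A character vector of 38 tokens.
#' @export
MITO_GENES <- c(
  "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
  "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB",
  "rrnL", "rrnS",
  "trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI", "trnK",
  "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR", "trnS1",
  "trnS2", "trnT", "trnV", "trnW", "trnY",
  "CR"
)

PCG_GENES  <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB")
TRNA_GENES <- grep("^trn", MITO_GENES, value = TRUE)
RRNA_GENES <- c("rrnL", "rrnS")

#' Gene class of a canonical token
#'
#' @param name character vector of canonical tokens.
#' @return character vector over \code{{"PCG","tRNA","rRNA","CR"}}; \code{NA}
#'   for tokens outside the vocabulary.
#' @export
gene_class <- function(name) {
  out <- rep(NA_character_, length(name))
  out[name %in% PCG_GENES]  <- "PCG"
  out[name %in% TRNA_GENES] <- "tRNA"
  out[name %in% RRNA_GENES] <- "rRNA"
  out[name == "CR"]         <- "CR"
  out
}

#' Ancestral insect mitochondrial gene order
#'
#' The plesiomorphic arrangement of the 37 mitochondrial genes (plus the
#' control region) shared by most Diptera, by convention rotated to start at
#' trnI. Strand "J" is the majority strand as deposited; "N" the minority
#' (complement) strand. 23 genes lie on J and 14 on N.
#'
#' @format A data.frame with columns \code{gene} and \code{strand}.
#' @export
ANCESTRAL_INSECT_ORDER <- data.frame(
  gene = c("trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY",
           "COX1", "trnL2", "COX2", "trnK", "trnD", "ATP8", "ATP6",
           "COX3", "trnG", "ND3", "trnA", "trnR", "trnN", "trnS1",
           "trnE", "trnF", "ND5", "trnH", "ND4", "ND4L", "trnT",
           "trnP", "ND6", "CYTB", "trnS2", "ND1", "trnL1", "rrnL",
           "trnV", "rrnS", "CR"),
  strand = c("J", "N", "J", "J", "J", "N", "N",
             "J", "J", "J", "J", "J", "J", "J",
             "J", "J", "J", "J", "J", "J", "J",
             "J", "N", "N", "N", "N", "N", "J",
             "N", "J", "J", "J", "N", "N", "N",
             "N", "N", "J"),
  stringsAsFactors = FALSE
)

# single-letter and three-letter amino-acid aliases for the 18 unambiguous
# tRNAs (Leu/Ser handled separately through their codon families)
.trna_aa <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", M = "MET", N = "ASN", P = "PRO",
  Q = "GLN", R = "ARG", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
)

.build_synonym_table <- function() {
  syn <- character(0)
  add <- function(syn, keys, canonical) {
    keys <- unique(toupper(keys))
    syn[keys] <- canonical
    syn
  }
  for (i in 1:3) {
    cox <- paste0("COX", i)
    rom <- c("I", "II", "III")[i]
    syn <- add(syn, c(cox, paste0("CO", i), paste0("CO", rom),
                      paste0("COX", rom), paste0("COT", i)), cox)
  }
  for (i in 1:6)
    syn <- add(syn, c(paste0("ND", i), paste0("NAD", i), paste0("NADH", i)),
               paste0("ND", i))
  syn <- add(syn, c("ND4L", "NAD4L", "NADH4L"), "ND4L")
  syn <- add(syn, c("ATP6", "ATPASE6", "ATPASE-6", "ATP SYNTHASE F0 SUBUNIT 6"), "ATP6")
  syn <- add(syn, c("ATP8", "ATPASE8", "ATPASE-8", "ATP SYNTHASE F0 SUBUNIT 8"), "ATP8")
  syn <- add(syn, c("CYTB", "COB", "CYB", "CYTOCHROME B", "CYT B"), "CYTB")
  syn <- add(syn, c("RRNL", "LRRNA", "L-RRNA", "16S", "16SRRNA", "16S RRNA",
                    "16S RIBOSOMAL RNA", "LSU", "RRN16", "LARGE SUBUNIT RIBOSOMAL RNA"),
             "rrnL")
  syn <- add(syn, c("RRNS", "SRRNA", "S-RRNA", "12S", "12SRRNA", "12S RRNA",
                    "12S RIBOSOMAL RNA", "SSU", "RRN12", "SMALL SUBUNIT RIBOSOMAL RNA"),
             "rrnS")
  syn <- add(syn, c("CR", "CONTROL REGION", "D-LOOP", "DLOOP",
                    "A+T-RICH REGION", "AT-RICH REGION", "A+T RICH REGION"), "CR")
  for (aa in names(.trna_aa)) {
    canonical <- paste0("trn", aa)
    syn <- add(syn, c(paste0("TRN", aa), paste0("TRNA-", .trna_aa[[aa]]),
                      paste0("TRNA ", .trna_aa[[aa]]), paste0("TRNA", .trna_aa[[aa]]),
                      paste0("TRN", .trna_aa[[aa]]), paste0("TRN-", aa)), canonical)
  }
  # Leu/Ser split by codon family (L1: CUN, L2: UUR, S1: AGN, S2: UCN)
  syn <- add(syn, c("TRNL1", "TRNA-LEU(CUN)", "TRNL(CUN)", "TRNA-LEU(CTN)",
                    "TRNL-UAG", "TRNL-TAG"), "trnL1")
  syn <- add(syn, c("TRNL2", "TRNA-LEU(UUR)", "TRNL(UUR)", "TRNA-LEU(TTR)",
                    "TRNL-UAA", "TRNL-TAA"), "trnL2")
  syn <- add(syn, c("TRNS1", "TRNA-SER(AGN)", "TRNS(AGN)",
                    "TRNS-GCU", "TRNS-GCT", "TRNS-UCU", "TRNS-TCT"), "trnS1")
  syn <- add(syn, c("TRNS2", "TRNA-SER(UCN)", "TRNS(UCN)", "TRNA-SER(TCN)",
                    "TRNS-UGA", "TRNS-TGA"), "trnS2")
  syn
}

.synonyms <- .build_synonym_table()

.norm_label <- function(x) {
  x <- toupper(trimws(x))
  gsub("[_]", "-", x)
}

#' Canonicalize a free-text mitochondrial gene label
#'
#' Case-insensitive lookup through the bundled synonym table, resolving the
#' label dialects used across GenBank mitogenome records (CO1/COI/cox1,
#' 16S/lrRNA, D-loop, tRNA-Ser(AGN), ...). Leucine and serine tRNAs are
#' disambiguated only when the label carries the codon family (CUN/UUR or
#' AGN/UCN) or an anticodon; a bare "tRNA-Leu" cannot be resolved and maps
#' to the sentinel.
#'
#' @param raw character vector of free-text labels.
#' @return character vector of canonical tokens; \code{"unknown"} where the
#'   label cannot be resolved.
#' @examples
#' canonicalize_gene_name(c("CO1", "tRNA-Ser(AGN)", "D-loop", "nad4l"))
#' @export
canonicalize_gene_name <- function(raw) {
  vapply(raw, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return("unknown")
    if (x %in% MITO_GENES) return(x)  # already canonical (case-sensitive fast path)
    key <- .norm_label(x)
    hit <- .synonyms[key]
    if (!is.na(hit)) return(unname(hit))
    # squeeze out remaining separators and retry
    key2 <- gsub("[- ]", "", key)
    hit <- .synonyms[match(key2, gsub("[- ]", "", names(.synonyms)))]
    if (!is.na(hit)) return(unname(hit))
    # tRNA-Leu/Ser with a codon-family or anticodon hint anywhere in the label
    if (grepl("^TRN", key)) {
      fam <- regmatches(key, regexpr("CUN|CTN|UUR|TTR|AGN|UCN|TCN", key))
      if (length(fam) == 1) {
        return(switch(fam,
                      CUN = , CTN = "trnL1",
                      UUR = , TTR = "trnL2",
                      AGN = "trnS1",
                      UCN = , TCN = "trnS2"))
      }
    }
    "unknown"
  }, character(1), USE.NAMES = FALSE)
}
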