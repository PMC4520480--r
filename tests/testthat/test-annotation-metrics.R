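test_that("gene order of an ancestral-order genome matches the constant", {
  sim <- simulate_genome(sim_params(seed = 21))
  expect_equal(as.vector(gene_order_string(sim$record)),
               ancestral_order_string())
  expect_equal(breakpoint_count(gene_order_string(sim$record),
                                ancestral_order_string()), 0)
})

test_that("swapping two genes creates two breakpoints (naive definition)", {
  ord <- ancestral_order_string()
  swapped <- ord
  # swap two non-adjacent genes: each displaced gene breaks both its
  # adjacencies, but the naive unordered-pair count on this circle is 4;
  # verify against a brute-force adjacency-set oracle
  i <- 4; j <- 10
  swapped[c(i, j)] <- swapped[c(j, i)]
  unsign <- function(x) sub("^-", "", x)
  adjacencies <- function(o) {
    g <- unsign(o); n <- length(g)
    apply(cbind(g, g[c(2:n, 1)]), 1, function(p) paste(sort(p), collapse = "|"))
  }
  brute <- sum(!(adjacencies(swapped) %in% adjacencies(ord)))
  expect_equal(breakpoint_count(swapped, ord), brute)
  expect_gt(breakpoint_count(swapped, ord), 0)
  # swapping two adjacent genes breaks exactly 2 adjacencies
  adj_sw <- ord
  adj_sw[c(4, 5)] <- adj_sw[c(5, 4)]
  expect_equal(breakpoint_count(adj_sw, ord), 2)
})

test_that("junction classification covers abutting, spacer and overlap", {
  rec <- toy_record(list(list("trnI", "J", 0, 10), list("trnM", "J", 10, 20),
                         list("ND2", "J", 25, 40), list("trnW", "J", 38, 50)),
                    seq_len = 50, is_circular = FALSE, is_complete = FALSE)
  jr <- junctions(rec)
  expect_equal(jr$relation, c("abutting", "spacer", "overlap"))
  expect_equal(jr$length, c(0L, 5L, 2L))
  s <- attr(jr, "summary")
  expect_equal(s$n[s$relation == "abutting"], 1L)
})

test_that("circular complete records close the junction chain; others do not", {
  genes <- list(list("trnI", "J", 0, 10), list("trnM", "J", 12, 20))
  circ <- toy_record(genes, seq_len = 25)
  expect_equal(nrow(junctions(circ)), 2L)        # incl. wrap junction
  wrap <- junctions(circ)
  expect_equal(wrap$length[wrap$upstream == "trnM"], 5L)  # 25-20 + 0
  lin <- toy_record(genes, seq_len = 25, is_complete = FALSE)
  expect_equal(nrow(junctions(lin)), 1L)
})

test_that("CR-flanking junctions are excluded unless requested", {
  rec <- toy_record(list(list("trnI", "J", 0, 10), list("CR", "J", 10, 20),
                         list("trnM", "J", 20, 30)), seq_len = 30)
  expect_equal(nrow(junctions(rec, include_cr = FALSE)), 1L)  # only wrap trnM->trnI
  expect_equal(nrow(junctions(rec, include_cr = TRUE)), 3L)
})

test_that("nested features are reported as full-length overlap with warning", {
  rec <- toy_record(list(list("ND2", "J", 0, 30), list("trnW", "J", 5, 15)),
                    seq_len = 40, is_circular = FALSE, is_complete = FALSE)
  expect_warning(jr <- junctions(rec), "nested")
  expect_equal(jr$relation, "overlap")
  expect_equal(jr$length, 10L)
})

test_that("junction conservation identity holds on simulated genomes", {
  for (seed in c(101, 202, 303)) {
    sim <- simulate_genome(sim_params(seed = seed, length_scale = 0.25))
    jr <- junctions(sim$record, include_cr = TRUE)
    s <- attr(jr, "summary")
    expect_equal(sum(sim$record$features$end - sim$record$features$start) -
                   s$total[s$relation == "overlap"] +
                   s$total[s$relation == "spacer"],
                 genome_length(sim$record))
  }
})

test_that("junctions are invariant under orientation reversal", {
  sim <- simulate_genome(sim_params(seed = 31, length_scale = 0.25))
  j1 <- junctions(sim$record, include_cr = TRUE)
  j2 <- junctions(reverse_record(sim$record), include_cr = TRUE)
  expect_identical(attr(j1, "summary"), attr(j2, "summary"))
  # pairwise: each junction survives with the same relation/length,
  # flanks exchanged
  key1 <- sort(paste(j1$upstream, j1$downstream, j1$relation, j1$length))
  key2 <- sort(paste(j2$downstream, j2$upstream, j2$relation, j2$length))
  expect_equal(key1, key2)
})

test_that("start/stop codon classification covers the canonical toy cases", {
  rec <- toy_record(list(list("ND3", "J", 0, 9)), sequence = "ATGAAATAA",
                    is_circular = FALSE, is_complete = FALSE)
  cc <- classify_codons(rec)
  expect_equal(cc$start_codon, "ATG")
  expect_equal(cc$start_class, "canonical_ATN")
  expect_equal(cc$stop_codon, "TAA")
  expect_equal(cc$stop_class, "complete")
})

test_that("partial stops T and TA and anomalies are classified", {
  # length mod 3 = 1 ending in T
  recT <- toy_record(list(list("COX2", "J", 0, 10)), sequence = "TCGAAAGGGT",
                     is_circular = FALSE, is_complete = FALSE)
  ccT <- classify_codons(recT)
  expect_equal(ccT$stop_codon, "T")
  expect_equal(ccT$stop_class, "partial")
  expect_equal(ccT$start_class, "noncanonical")
  # length mod 3 = 2 ending in TA
  recTA <- toy_record(list(list("ND5", "J", 0, 11)), sequence = "ATTAAAGGGTA",
                      is_circular = FALSE, is_complete = FALSE)
  expect_equal(classify_codons(recTA)$stop_codon, "TA")
  # anomalous terminus warns, never errors
  recX <- toy_record(list(list("ND4", "J", 0, 10)), sequence = "ATGAAAGGGA",
                     is_circular = FALSE, is_complete = FALSE)
  expect_warning(ccX <- classify_codons(recX), "anomalous")
  expect_equal(ccX$stop_class, "anomalous")
  # too-short PCG is an error
  recS <- toy_record(list(list("ND1", "J", 0, 4)), sequence = "ATGA",
                     is_circular = FALSE, is_complete = FALSE)
  expect_error(classify_codons(recS), "shorter")
})

test_that("frame offsets shift the start codon and codon frame", {
  feats <- data.frame(name = "ND3", class = "PCG", strand = "J",
                      start = 0L, end = 10L, frame_offset = 1L)
  rec <- mito_record("t", "GATGAAATAA", feats, is_circular = FALSE,
                     is_complete = FALSE, check_census = FALSE)
  cc <- classify_codons(rec)
  expect_equal(cc$start_codon, "ATG")
  expect_equal(cc$stop_codon, "TAA")
  expect_equal(validate_orf(rec, "ND3"), 0L)
})

test_that("validate_orf counts internal stops under the mito code", {
  rec0 <- toy_record(list(list("ND3", "J", 0, 9)), sequence = "ATGAAATAA",
                     is_circular = FALSE, is_complete = FALSE)
  expect_equal(validate_orf(rec0, "ND3"), 0L)
  rec1 <- toy_record(list(list("ND3", "J", 0, 12)), sequence = "ATGTAAAAATAA",
                     is_circular = FALSE, is_complete = FALSE)
  expect_equal(validate_orf(rec1, "ND3"), 1L)
  # AGA/AGG are serine (not stop) in the invertebrate mito code
  rec2 <- toy_record(list(list("ND3", "J", 0, 12)), sequence = "ATGAGAAGGTAA",
                     is_circular = FALSE, is_complete = FALSE)
  expect_equal(validate_orf(rec2, "ND3"), 0L)
  expect_error(validate_orf(rec2, "trnI"), "not a PCG")
})

test_that("codon classification is invariant to origin rotation", {
  sim <- simulate_genome(sim_params(seed = 13, length_scale = 0.3))
  base <- classify_codons(sim$record)
  for (off in c(1L, 137L, genome_length(sim$record) %/% 2)) {
    rot <- classify_codons(rotate_record(sim$record, off))
    expect_equal(rot[order(rot$gene), ], base[order(base$gene), ],
                 ignore_attr = TRUE)
  }
})
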