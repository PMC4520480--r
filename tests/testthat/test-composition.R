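test_that("base composition of simple sequences", {
  bc <- base_composition("AATT")
  expect_equal(bc$at_percent, 100)
  expect_equal(bc$a, 0.5)
  expect_equal(bc$t, 0.5)
  expect_error(base_composition(""), "empty")
  # ambiguity codes excluded from denominators but counted
  bc2 <- base_composition("AANN")
  expect_equal(bc2$a, 1)
  expect_equal(bc2$counts[["ambiguous"]], 2L)
})

test_that("fractions sum to one and match direct counting", {
  set.seed(9)
  for (rep in 1:25) {
    s <- random_seq(sample(10:500, 1))
    bc <- base_composition(s)
    expect_equal(bc$a + bc$t + bc$g + bc$c, 1)
    n <- oracle_counts(s)
    expect_equal(unname(bc$counts[c("A", "T", "G", "C")]), unname(n))
    expect_equal(bc$at_percent + bc$gc_percent, 100)
  }
})

test_that("skews: degenerate, balanced, and bounded", {
  sk <- skews("AAAA")
  expect_equal(sk$at_skew, 1)
  expect_true(is.na(sk$gc_skew))
  sk2 <- skews("AATTGC")
  expect_equal(sk2$at_skew, 0)
  expect_equal(sk2$gc_skew, 0)
  set.seed(10)
  for (rep in 1:20) {
    sk3 <- skews(random_seq(50))
    expect_lte(abs(sk3$at_skew), 1)
    expect_lte(abs(sk3$gc_skew), 1)
  }
})

test_that("skews negate under reverse complement", {
  set.seed(11)
  for (rep in 1:25) {
    s <- random_seq(sample(20:300, 1))
    a <- skews(s); b <- skews(revcomp(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
  }
})

test_that("profile rows use the sense strand and correct codon positions", {
  # one J PCG "ATGAAATAA", one N PCG whose sense is "ATGCCCTAA"
  n_span <- revcomp("ATGCCCTAA")
  seqq <- paste0("ATGAAATAA", "TT", n_span)
  rec <- mito_record("t", seqq, data.frame(
    name = c("ND2", "ND1"), class = "PCG", strand = c("J", "N"),
    start = c(0L, 11L), end = c(9L, 20L), frame_offset = 0L),
    is_circular = FALSE, is_complete = FALSE, check_census = FALSE)
  prof <- suppressWarnings(profile_record(rec))
  pj <- prof[prof$region_class == "PCG_J", ]
  expect_equal(unlist(pj[c("A", "T", "G", "C")], use.names = FALSE),
               unname(oracle_counts("ATGAAATAA")))
  pn <- prof[prof$region_class == "PCG_N", ]
  expect_equal(unlist(pn[c("A", "T", "G", "C")], use.names = FALSE),
               unname(oracle_counts("ATGCCCTAA")))
  # codon positions of the J gene: pos1 = A,A,T / pos2 = T,A,A / pos3 = G,A,A
  p1 <- prof[prof$region_class == "pos1_J", ]
  expect_equal(unlist(p1[c("A", "T", "G", "C")], use.names = FALSE),
               unname(oracle_counts("AAT")))
  p3 <- prof[prof$region_class == "pos3_J", ]
  expect_equal(unlist(p3[c("A", "T", "G", "C")], use.names = FALSE),
               unname(oracle_counts("GAA")))
})

test_that("partial terminal codons are excluded from position rows only", {
  # COX2-like gene with partial stop T: length 10
  rec <- mito_record("t", "ATGAAACCCT", data.frame(
    name = "COX2", class = "PCG", strand = "J", start = 0L, end = 10L,
    frame_offset = 0L), is_circular = FALSE, is_complete = FALSE,
    check_census = FALSE)
  prof <- suppressWarnings(profile_record(rec))
  whole <- prof[prof$region_class == "PCG_J", ]
  expect_equal(whole$A + whole$T + whole$G + whole$C, 10)  # partial T included
  pos_sum <- sum(prof[grepl("^pos\\d_J$", prof$region_class),
                      c("A", "T", "G", "C")])
  expect_equal(pos_sum, 9)                                 # excluded here
})

test_that("pos1+pos2+pos3 counts equal whole-PCG counts minus partial bases", {
  sim <- simulate_genome(sim_params(seed = 77, length_scale = 0.3))
  prof <- profile_record(sim$record)
  cc <- classify_codons(sim$record)
  f <- sim$record$features
  for (strand in c("J", "N")) {
    genes <- f$name[f$class == "PCG" & f$strand == strand]
    partial_bases <- sum(nchar(cc$stop_codon[cc$gene %in% genes &
                                               cc$stop_class == "partial"]))
    whole <- prof[prof$region_class == paste0("PCG_", strand), ]
    pos <- prof[prof$region_class %in% paste0("pos", 1:3, "_", strand), ]
    expect_equal(sum(pos[, c("A", "T", "G", "C")]),
                 whole$A + whole$T + whole$G + whole$C - partial_bases)
  }
})

test_that("profile is invariant to feature order and origin rotation", {
  sim <- simulate_genome(sim_params(seed = 15, length_scale = 0.3))
  rec <- sim$record
  prof <- profile_record(rec)
  shuffled <- rec
  set.seed(1)
  shuffled$features <- shuffled$features[sample(nrow(shuffled$features)), ]
  # constructor re-sorts; go through mito_record to mimic reordered input
  shuffled <- mito_record(rec$record_id, rec$sequence, shuffled$features,
                          rec$is_circular, rec$is_complete, check_census = FALSE)
  expect_equal(profile_record(shuffled), prof, ignore_attr = TRUE)
  rot <- rotate_record(rec, 1234L)
  expect_equal(profile_record(rot), prof, ignore_attr = TRUE)
})

test_that("whole-genome row appears only for complete records", {
  sim <- simulate_genome(sim_params(seed = 16, length_scale = 0.25))
  expect_true("whole_genome" %in% profile_record(sim$record)$region_class)
  d <- degrade(sim$record, sim$manifest, "drop_cr")
  prof <- suppressWarnings(profile_record(d$record))
  expect_false("whole_genome" %in% prof$region_class)
  expect_false("CR" %in% prof$region_class)
})

test_that("codon usage matches the brute-force enumeration oracle", {
  rec <- toy_record(list(list("ND3", "J", 0, 9)), sequence = "ATGAAATAA",
                    is_circular = FALSE, is_complete = FALSE)
  cu <- codon_usage(rec)
  agg <- cu$aggregate[cu$aggregate$count > 0, ]
  expect_equal(sort(agg$codon), c("AAA", "ATG", "TAA"))
  expect_equal(agg$count, c(1L, 1L, 1L)[order(agg$codon)])
  sim <- simulate_genome(sim_params(seed = 18, length_scale = 0.25))
  cu2 <- codon_usage(sim$record)
  f <- sim$record$features
  for (g in f$name[f$class == "PCG"]) {
    s <- feature_seq(sim$record, g)
    want <- table(oracle_codons(s)[seq_len((nchar(s)) %/% 3)])
    got <- cu2$per_gene[cu2$per_gene$gene == g & cu2$per_gene$count > 0, ]
    expect_equal(stats::setNames(got$count, got$codon),
                 stats::setNames(as.integer(want), names(want)))
    # total = floor((len - offset)/3)
    expect_equal(sum(cu2$per_gene$count[cu2$per_gene$gene == g]),
                 nchar(s) %/% 3)
  }
})

test_that("aggregate_species averages metrics and pools position counts", {
  sim <- simulate_genome(sim_params(seed = 19, length_scale = 0.25))
  prof <- profile_record(sim$record)
  agg <- aggregate_species(list(prof, prof, prof))
  for (rc in prof$region_class) {
    expect_equal(agg$mean_profile$at_percent[agg$mean_profile$region_class == rc],
                 prof$at_percent[prof$region_class == rc])
  }
  expect_equal(agg$n_records, 3)
  # pooled codon positions equal direct pooling of counts
  d <- prof[grepl("^pos1_", prof$region_class), ]
  expect_equal(agg$codon_position_pooled$at_percent[1],
               100 * sum(d$A + d$T) / sum(d$A + d$T + d$G + d$C))
})
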