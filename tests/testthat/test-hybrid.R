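# panel mimicking the structure of a well-sampled pondweed genus: two
# species, one with nested genotype variants, a handful of diagnostic sites
PANEL_SEQS <- c(
  `sp1|1a` = "ACGTACGTACGTACGTACGT",
  `sp1|1b` = "ACGTACGTACGTACGAACGT", # 1 substitution from 1a
  `sp1|2a` = "ACGAACGAACGTACGTACGA", # 3 substitutions from 1a
  `sp2|1`  = "TCGTACGTACTTACGTACCT" # own species
)

test_that("expected_sequence merges pairs and marks indel-additive sites", {
  p <- make_panel(PANEL_SEQS)
  expect_identical(as.character(expected_sequence(p, "1a")),
                   PANEL_SEQS[["sp1|1a"]])
  e <- as.character(expected_sequence(p, c("1a", "1b")))
  expect_identical(substr(e, 16, 16), "W")
  pg <- make_panel(c(`sp1|g1` = "AC-TAC", `sp1|g2` = "ACGTAT"))
  eg <- expected_sequence(pg, c("g1", "g2"))
  expect_equal(attr(eg, "indel_additive"), 3L)
  expect_identical(substr(as.character(eg), 6, 6), "Y")
  expect_error(expected_sequence(p, "zz"), "unknown genotype")
})

test_that("classify_direct recovers pure genotypes and hybrid pairs", {
  p <- make_panel(PANEL_SEQS)
  # exact consensus -> pure
  call <- classify_direct(PANEL_SEQS[["sp1|1a"]], p)
  expect_identical(call$verdict, "pure")
  expect_identical(call$hypothesis, "1a")
  expect_equal(nrow(call$violated_sites), 0L)
  # merged 1a+2a -> intraspecific hybrid with zero violations
  q <- as.character(expected_sequence(p, c("1a", "2a")))
  call2 <- classify_direct(q, p)
  expect_identical(call2$verdict, "intraspecific_hybrid")
  expect_setequal(call2$hypothesis, c("1a", "2a"))
  expect_equal(nrow(call2$violated_sites), 0L)
  # merged across species -> interspecific
  q3 <- as.character(expected_sequence(p, c("2a", "1")))
  call3 <- classify_direct(q3, p)
  expect_identical(call3$verdict, "interspecific_hybrid")
  expect_setequal(call3$hypothesis, c("2a", "1"))
})

test_that("extra polymorphisms off the diagnostic sites stay pure", {
  p <- make_panel(PANEL_SEQS)
  q <- PANEL_SEQS[["sp1|1a"]]
  # column 2 (C in every genotype) is non-diagnostic; a W there is an
  # extra intra-individual polymorphism, not hybridity evidence
  substr(q, 2, 2) <- "M"
  call <- classify_direct(q, p)
  expect_identical(call$verdict, "pure")
  expect_identical(call$hypothesis, "1a")
  expect_equal(call$extra_polymorphic_sites, 2L)
})

test_that("a partial additive pattern is novel, not hybrid", {
  p <- make_panel(PANEL_SEQS)
  q <- as.character(expected_sequence(p, c("1a", "2a")))
  # destroy one of the three additive signals: strict set equality fails
  pos <- which(strsplit(q, "")[[1]] == "W")[1]
  substr(q, pos, pos) <- "A"
  call <- classify_direct(q, p, tolerance = 0L)
  expect_identical(call$verdict, "novel")
  # with tolerance 1 the intended pair is recovered
  call1 <- classify_direct(q, p, tolerance = 1L)
  expect_identical(call1$verdict, "intraspecific_hybrid")
  expect_setequal(call1$hypothesis, c("1a", "2a"))
})

test_that("classification is exhaustive-pair-correct on simulated panels", {
  # every ordered pair of panel consensuses with >= 1 diagnostic site must
  # be recovered from its own merge with zero violated sites
  cfg <- sim_config(seed = 5, n_species = 3,
                    genotypes_per_species = c(3, 3, 2),
                    seq_length = c(ITS = 200, `5S-NTS` = 120,
                                   `rpl20-rps12` = 120, `trnT-trnL` = 120))
  p <- simulate_panel(cfg)$panels[["ITS"]]
  expect_lte(length(p$labels), 8L)
  for (g1 in p$labels) for (g2 in p$labels) {
    if (g1 == g2) next
    if (nrow(diagnostic_sites(p, g1, g2)$sites) < 1L) next
    q <- as.character(expected_sequence(p, c(g1, g2)))
    call <- classify_direct(q, p)
    expect_setequal(call$hypothesis, c(g1, g2))
    expect_equal(nrow(call$violated_sites), 0L)
    expect_true(grepl("hybrid", call$verdict))
  }
})

test_that("classification is invariant under label permutation", {
  set.seed(9)
  perm <- sample(length(PANEL_SEQS))
  p1 <- make_panel(PANEL_SEQS)
  p2 <- make_panel(PANEL_SEQS[perm])
  q <- as.character(expected_sequence(p1, c("1b", "1")))
  c1 <- classify_direct(q, p1)
  c2 <- classify_direct(q, p2)
  expect_identical(c1$verdict, c2$verdict)
  expect_setequal(c1$hypothesis, c2$hypothesis)
})

test_that("single sequencing errors in pure samples never fake hybridity", {
  # panel whose minimum pairwise diagnostic distance is >= 2
  p <- make_panel(c(`sp1|g1` = "ACGTACGTACGTACGTACGT",
                    `sp1|g2` = "ACCTACCTACGTACGTACGT",
                    `sp2|g3` = "ACGTACGTACTTACTTACGT"))
  set.seed(10)
  bases <- c("A", "C", "G", "T")
  n_hybrid <- 0L
  for (i in 1:2000) {
    g <- sample(p$labels, 1)
    v <- strsplit(panel_consensus(p, g), "")[[1]]
    j <- sample(length(v), 1)
    v[j] <- sample(setdiff(bases, v[j]), 1)
    call <- classify_direct(paste(v, collapse = ""), p)
    if (grepl("hybrid", call$verdict)) n_hybrid <- n_hybrid + 1L
    expect_true(call$verdict %in% c("pure", "novel"))
  }
  expect_equal(n_hybrid, 0L)
})

test_that("peak_subtract inverts merging and flags residual ambiguity", {
  expect_identical(as.character(peak_subtract("ACGWACGW", "ACGTACGT")),
                   "ACGAACGA")
  expect_identical(as.character(peak_subtract("ACGT", "ACGT")), "ACGT")
  out <- peak_subtract("AVGT", "ACGT")
  expect_identical(as.character(out), "ARGT")
  expect_equal(attr(out, "still_ambiguous"), 2L)
  expect_error(peak_subtract("ACGT", "ACGA"), "column\\(s\\) 4")
})

test_that("peak subtraction round-trips merged panel pairs", {
  p <- make_panel(PANEL_SEQS)
  for (pair in list(c("1a", "2a"), c("1b", "1"), c("2a", "1"))) {
    q <- as.character(expected_sequence(p, pair))
    rec <- peak_subtract(q, panel_consensus(p, pair[1]))
    expect_identical(as.character(rec), panel_consensus(p, pair[2]))
  }
})

test_that("weak minor peaks are demoted before classification", {
  p <- make_panel(PANEL_SEQS)
  # true pure 1a, but the trace shows small extra peaks (< 30% of signal)
  # at two diagnostic columns, mimicking background noise
  q <- PANEL_SEQS[["sp1|1a"]]
  substr(q, 4, 4) <- "W" # diagnostic vs 2a (T/A)
  substr(q, 16, 16) <- "W" # diagnostic vs 1b
  noisy <- classify_direct(q, p, minor_fraction = c(`4` = 0.1, `16` = 0.15))
  expect_identical(noisy$verdict, "pure")
  expect_identical(noisy$hypothesis, "1a")
  # the same peaks at >= 30% are real signal: not demoted
  strong <- classify_direct(q, p, minor_fraction = c(`4` = 0.45,
                                                     `16` = 0.45))
  expect_false(identical(strong$verdict, "pure"))
})

test_that("select_for_phylogeny keeps pures, drops hybrids, logs reasons", {
  p <- make_panel(PANEL_SEQS)
  seqs <- c(s1 = PANEL_SEQS[["sp1|1a"]],
            s2 = as.character(expected_sequence(p, c("1a", "2a"))),
            s3 = PANEL_SEQS[["sp2|1"]],
            s2cl = PANEL_SEQS[["sp1|2a"]])
  meta <- data.frame(sample_id = names(seqs), species = "unknown",
                     genotype = NA_character_,
                     role = c("direct", "direct", "direct", "clone"))
  aln <- make_aln(seqs, meta = meta)
  calls <- classify_alignment(aln, p)
  sel <- select_for_phylogeny(calls, aln, unique_clones = "s2cl")
  expect_setequal(names(sel$alignment$seqs), c("s1", "s3", "s2cl"))
  expect_equal(nrow(sel$log), 4L)
  expect_identical(sel$log$reason[sel$log$sample_id == "s2"],
                   "intraspecific_hybrid")
})
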