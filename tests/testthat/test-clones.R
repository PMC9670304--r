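test_that("unique clone substitutions are corrected to the direct base", {
  direct <- "ACGTACGTAC"
  clones <- make_aln(c(c1 = "ACGTACGTAC", c2 = "ACGTACGTAC",
                       c3 = "ACGTACGTAC", c4 = "ACTTACGTAC",
                       c5 = "ACGTACGTAC"))
  res <- correct_polymerase_errors(clones, direct)
  expect_equal(nrow(res$corrections), 1L)
  expect_identical(res$corrections$clone_id, "c4")
  expect_equal(res$corrections$column, 3L)
  expect_identical(unname(res$alignment$seqs[["c4"]]), direct)
})

test_that("polymorphic and shared deviations are never corrected", {
  # direct is ambiguous (W) at column 3: a clone differing there reflects
  # template variation, not polymerase error
  clones <- make_aln(c(c1 = "ACATAC", c2 = "ACTTAC", c3 = "ACATAC"))
  res <- correct_polymerase_errors(clones, "ACWTAC")
  expect_equal(nrow(res$corrections), 0L)
  # two clones share the deviant base: not unique, untouched
  clones2 <- make_aln(c(c1 = "ACGTAC", c2 = "ACTTAC", c3 = "ACTTAC",
                        c4 = "ACGTAC"))
  res2 <- correct_polymerase_errors(clones2, "ACGTAC")
  expect_equal(nrow(res2$corrections), 0L)
  # fewer than two clones: warning, input returned
  expect_warning(r1 <- correct_polymerase_errors(
    make_aln(c(c1 = "ACGTAC")), "ACGTAC"), "fewer than 2")
  expect_equal(nrow(r1$corrections), 0L)
})

test_that("assign_clones classifies parental, recombinant and foreign", {
  pA <- "ACGTACGTACGT"
  pB <- "ATGTACCTACGA" # informative columns 2, 7, 12
  clones <- make_aln(c(
    a1 = pA,
    b1 = pB,
    chim = "ATGTACGTACGT", # B at site 1, A at sites 2-3: 1|2 split
    far = "GGGGGGGGGGGG"))
  asg <- assign_clones(clones, pA, pB)
  expect_equal(attr(asg, "informative_columns"), c(2L, 7L, 12L))
  expect_identical(asg$class[asg$clone_id == "a1"], "parentA")
  expect_equal(asg$distance_to_nearest[asg$clone_id == "a1"], 0L)
  expect_identical(asg$class[asg$clone_id == "b1"], "parentB")
  # one discordant site out of three: suspect, not recombinant
  expect_identical(asg$class[asg$clone_id == "chim"], "parentA")
  expect_identical(asg$suspect_sites[asg$clone_id == "chim"], "2")
  expect_identical(asg$class[asg$clone_id == "far"], "unassigned")
  expect_error(assign_clones(clones, pA, pA), "zero informative")
})

test_that("true prefix/suffix chimeras with long blocks are recombinant", {
  pA <- "AAGGAAGGAAGGAAGG"
  pB <- "ATGGATGGATGGATGG" # informative columns 2, 6, 10, 14
  chim <- "AAGGAAGGATGGATGG" # A at sites 1-2, B at sites 3-4
  asg <- assign_clones(make_aln(c(x = chim, a = pA, b = pB)), pA, pB)
  expect_identical(asg$class[asg$clone_id == "x"], "recombinant")
  expect_identical(asg$breakpoints[asg$clone_id == "x"], "(6,10)")
})

test_that("detect_breakpoints matches the block rule on known strings", {
  bp <- detect_breakpoints("AABB")
  expect_true(attr(bp, "recombinant"))
  expect_equal(bp[[1]], c(2, 3))
  expect_false(attr(detect_breakpoints("AAAA"), "recombinant"))
  bp3 <- detect_breakpoints("ABAA")
  expect_false(attr(bp3, "recombinant"))
  expect_equal(attr(bp3, "suspect_sites"), 2L)
  # N sites are skipped, coordinates reported in the provided columns
  bp4 <- detect_breakpoints("AANBB", columns = c(10L, 20L, 30L, 40L, 50L))
  expect_true(attr(bp4, "recombinant"))
  expect_equal(bp4[[1]], c(20, 40))
  # short blocks on both sides: two suspects, no recombination
  expect_false(attr(detect_breakpoints("AB"), "recombinant"))
})

test_that("recombinant declaration matches the run oracle exhaustively", {
  # all state strings over {A,B} up to length 12
  for (len in 1:12) {
    grid <- expand.grid(rep(list(c("A", "B")), len),
                        stringsAsFactors = FALSE)
    strings <- do.call(paste0, grid)
    for (s in strings) {
      expect_identical(
        attr(detect_breakpoints(s), "recombinant"),
        oracle_recombinant(s),
        info = s)
    }
  }
})

test_that("recombinant declaration matches the oracle with N sites", {
  set.seed(30)
  for (i in 1:500) {
    len <- sample(1:12, 1)
    s <- paste(sample(c("A", "B", "N"), len, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2)), collapse = "")
    mb <- sample(1:3, 1)
    expect_identical(attr(detect_breakpoints(s, min_block = mb),
                          "recombinant"),
                     oracle_recombinant(s, min_block = mb), info = s)
  }
})

test_that("choose_representatives picks one clone per variant, max two", {
  pA <- "AAGGAAGGAAGGAAGG"
  pB <- "ATGGATGGATGGATGG"
  pAvar <- "AAGGAAGGAAGGAACG" # second variant of parent A (non-informative col)
  clones <- make_aln(c(a1 = pA, a2 = pA, a3 = pAvar, b2 = pB, b1 = pB,
                       r1 = "AAGGAAGGATGGATGG"))
  asg <- assign_clones(clones, pA, pB)
  reps <- choose_representatives(asg, clones)
  expect_setequal(reps$parentA, c("a1", "a3"))
  expect_identical(reps$parentB, "b1") # identical variants: first by id
  expect_false("r1" %in% unlist(reps)) # recombinants never representatives
})

test_that("a missing parent is inferred by peak subtraction", {
  p <- make_panel(PANEL_SEQS_CLONES <- c(
    `sp1|g1` = "ACGTACGTACGTACGT",
    `sp2|g2` = "ACCTACCTACGAACGT"))
  direct <- as.character(expected_sequence(p, c("g1", "g2")))
  inf <- infer_missing_parent(direct, panel_consensus(p, "g1"))
  expect_identical(as.character(inf), panel_consensus(p, "g2"))
  expect_true(attr(inf, "inferred"))
})

test_that("analyze_clones recovers both parents end to end", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_species = 2,
                    genotypes_per_species = c(2, 2),
                    seq_length = c(ITS = 150, `5S-NTS` = 100,
                                   `rpl20-rps12` = 100, `trnT-trnL` = 100))
  sim <- simulate_panel(cfg)
  s <- simulate_sample(cfg, sim, "interspecific_hybrid", "h1")
  p <- sim$panels[["ITS"]]
  rep <- analyze_clones(s$clones[["ITS"]], s$direct[["ITS"]],
                        parentA = panel_consensus(p, s$truth$genotype1),
                        parentB = panel_consensus(p, s$truth$genotype2),
                        panel = p, sample_id = "h1")
  expect_true(rep$parents_recovered)
  truth <- s$clone_truth[s$clone_truth$marker == "ITS", ]
  pred <- rep$assignments
  for (k in seq_len(nrow(truth))) {
    cls <- pred$class[pred$clone_id == truth$clone_id[k]]
    if (truth$source[k] == "chimera") expect_identical(cls, "recombinant")
    else expect_true(cls %in% c("parentA", "parentB"))
  }
})

test_that("de novo clustering recovers parents without references", {
  pA <- "ACGTACGTACGTACGTACGT"
  pB <- "ACCTACCAACGTACGAACGT" # 4 substitutions apart
  direct <- as.character(iupac_merge(
    strsplit(pA, "")[[1]], strsplit(pB, "")[[1]]))
  direct <- paste(direct, collapse = "")
  clones <- make_aln(c(c1 = pA, c2 = pA, c3 = pB, c4 = pB, c5 = pA))
  rep <- analyze_clones(clones, direct, sample_id = "x")
  expect_true(rep$parents_recovered)
  recovered <- sort(c(
    clones$seqs[[rep$representatives$parentA[1]]],
    clones$seqs[[rep$representatives$parentB[1]]]))
  expect_identical(unname(recovered), sort(c(pA, pB)))
})

test_that("representatives re-merge to the direct sequence at diagnostic
           columns", {
  set.seed(32)
  cfg <- sim_config(seed = 32, n_species = 2,
                    genotypes_per_species = c(1, 1),
                    seq_length = c(ITS = 120, `5S-NTS` = 80,
                                   `rpl20-rps12` = 80, `trnT-trnL` = 80),
                    clone_error_rate = 0, chimera_rate = 0)
  sim <- simulate_panel(cfg)
  s <- simulate_sample(cfg, sim, "interspecific_hybrid", "h1")
  p <- sim$panels[["ITS"]]
  rep <- analyze_clones(s$clones[["ITS"]], s$direct[["ITS"]],
                        parentA = panel_consensus(p, s$truth$genotype1),
                        parentB = panel_consensus(p, s$truth$genotype2))
  a <- strsplit(rep$corrected$seqs[[rep$representatives$parentA[1]]],
                "")[[1]]
  b <- strsplit(rep$corrected$seqs[[rep$representatives$parentB[1]]],
                "")[[1]]
  d <- strsplit(s$direct[["ITS"]], "")[[1]]
  ds <- diagnostic_sites(p, s$truth$genotype1, s$truth$genotype2)
  for (j in ds$sites$column) {
    expect_identical(iupac_merge(a[j], b[j]), d[j])
  }
})
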