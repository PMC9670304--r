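# plastid haplotype panel: spA has two haplotypes, spB one of its own plus
# one shared with spA (the shared Eurasian haplotype situation), spC distinct
PLASTID <- c(
  `spA|A-h1` = "ACGTACGTACGTACGTACGT",
  `spA|A-h2` = "ACGTACGTACGTACGAACGT",
  `spB|B-h1` = "ACGTACGTACGTACGTACGT", # identical to A-h1
  `spB|B-h2` = "TCGTACGTACGTACGTACCT",
  `spC|C-h1` = "ACGGACGTACTTACGTACGT")

test_that("a haplotype unique to one parent assigns the maternal species", {
  p <- make_panel(PLASTID, marker = "rpl20-rps12")
  call <- assign_maternal(PLASTID[["spB|B-h2"]], p,
                          parent_species = c("spA", "spB"), sample_id = "h1")
  expect_identical(call$call, "assigned")
  expect_identical(call$maternal, "spB")
  expect_identical(call$matched_haplotype, "B-h2")
  expect_equal(call$distance, 0L)
})

test_that("a haplotype shared by both parents is equivocal", {
  p <- make_panel(PLASTID, marker = "rpl20-rps12")
  call <- assign_maternal(PLASTID[["spA|A-h1"]], p,
                          parent_species = c("spA", "spB"))
  expect_identical(call$call, "equivocal")
  expect_true(is.na(call$maternal))
  expect_setequal(call$candidates, c("spA", "spB"))
  # same haplotype against a parent pair that does NOT share it: assigned
  call2 <- assign_maternal(PLASTID[["spA|A-h1"]], p,
                           parent_species = c("spA", "spC"))
  expect_identical(call2$call, "assigned")
  expect_identical(call2$maternal, "spA")
})

test_that("an unmatched haplotype reports derivation from its nearest", {
  p <- make_panel(PLASTID, marker = "rpl20-rps12")
  q <- PLASTID[["spA|A-h2"]]
  substr(q, 2, 2) <- "G" # one substitution off A-h2
  call <- assign_maternal(q, p, parent_species = c("spA", "spB"))
  expect_identical(call$call, "novel_haplotype")
  expect_equal(call$distance, 1L)
  expect_identical(call$derived_from, "A-h2")
  expect_identical(call$candidates, "spA")
  expect_error(assign_maternal(q, p, parent_species = c("spA", "spX")),
               "absent from plastid panel")
})

test_that("indel runs count as single events in haplotype distance", {
  p <- make_panel(c(`spA|h1` = "ACGTACGTAC", `spB|h2` = "ACG---GTAC"),
                  marker = "trnT-trnL")
  # query equals h2 except the gap: distance 1 event to h2's backbone
  call <- assign_maternal("ACGTACGTAC", p, parent_species = c("spA", "spB"))
  expect_identical(call$call, "assigned")
  expect_identical(call$maternal, "spA")
  # against h2 alone the distance is one indel event, not three columns
  call2 <- assign_maternal("ACGTACGTAC", p, parent_species = c("spB"))
  expect_identical(call2$call, "novel_haplotype")
  expect_equal(call2$distance, 1L)
})

test_that("maternal accuracy is exact where parental haplotypes differ", {
  # deterministic rule, exercised over many simulated hybrids: correct
  # species whenever haplotypes differ, equivocal whenever shared
  cfg <- sim_config(seed = 77, n_samples = 60,
                    sample_mix = c(pure = 0, intraspecific_hybrid = 0,
                                   interspecific_hybrid = 1),
                    seq_length = c(ITS = 200, `5S-NTS` = 120,
                                   `rpl20-rps12` = 200,
                                   `trnT-trnL` = 200))
  sim <- simulate_panel(cfg)
  p <- sim$panels[["rpl20-rps12"]]
  set.seed(78)
  n_eq <- 0L
  for (i in 1:200) {
    s <- simulate_sample(cfg, sim, "interspecific_hybrid", paste0("h", i))
    hap_seq <- s$plastid[["rpl20-rps12"]]
    parents <- c(s$truth$species1, s$truth$species2)
    other <- setdiff(parents, s$truth$maternal_species)
    other_haps <- vapply(
      p$labels[p$species[p$labels] == other],
      function(h) panel_consensus(p, h), character(1))
    shared <- any(other_haps == hap_seq)
    call <- assign_maternal(hap_seq, p, parent_species = parents,
                            sample_id = s$truth$sample_id)
    if (shared) {
      expect_identical(call$call, "equivocal")
      n_eq <- n_eq + 1L
    } else {
      expect_identical(call$call, "assigned")
      expect_identical(call$maternal, s$truth$maternal_species)
    }
  }
  expect_gt(n_eq, 0L) # the shared-haplotype species pair must be exercised
})

test_that("cross-marker resolution follows assigned > derivation > equivocal", {
  mk <- function(call, maternal = NA_character_, candidates = character(0),
                 derived = NA_character_, marker = "rpl20-rps12") {
    structure(list(sample_id = "s1", marker = marker, call = call,
                   maternal = maternal, candidates = candidates,
                   matched_haplotype = character(0), distance = 0L,
                   derived_from = derived), class = "maternal_call")
  }
  r1 <- cross_marker_resolve(list(mk("equivocal",
                                     candidates = c("spA", "spB")),
                                  mk("assigned", maternal = "spA",
                                     candidates = "spA",
                                     marker = "trnT-trnL")))
  expect_identical(r1$call, "assigned")
  expect_identical(r1$maternal, "spA")
  r2 <- cross_marker_resolve(list(mk("equivocal",
                                     candidates = c("spA", "spB")),
                                  mk("equivocal",
                                     candidates = c("spA", "spB"))))
  expect_identical(r2$call, "equivocal")
  # novel haplotype derived from a single species resolves by derivation
  r3 <- cross_marker_resolve(list(mk("equivocal",
                                     candidates = c("spA", "spB")),
                                  mk("novel_haplotype",
                                     candidates = "spB",
                                     derived = "B-h2")))
  expect_identical(r3$call, "assigned")
  expect_identical(r3$maternal, "spB")
  expect_true(isTRUE(attr(r3, "by_derivation")))
  # conflicting assignments across markers are an explicit conflict state
  r4 <- cross_marker_resolve(list(mk("assigned", maternal = "spA",
                                     candidates = "spA"),
                                  mk("assigned", maternal = "spB",
                                     candidates = "spB",
                                     marker = "trnT-trnL")))
  expect_identical(r4$call, "conflict")
  expect_setequal(r4$candidates, c("spA", "spB"))
  expect_error(cross_marker_resolve(list(
    mk("equivocal"),
    structure(list(sample_id = "s2", marker = "trnT-trnL",
                   call = "equivocal", maternal = NA_character_,
                   candidates = character(0),
                   matched_haplotype = character(0), distance = 0L,
                   derived_from = NA_character_),
              class = "maternal_call"))), "different samples")
})

test_that("independent origins are distinct maternal tuples, reciprocal
           crosses flagged", {
  samples <- data.frame(
    hybrid_type = c(rep("spA x spB", 6), rep("spA x spC", 3)),
    maternal = c("spA", "spA", "spB", "spB", "spA", "spB",
                 "spC", "spC", "spC"),
    haplotype = c("A-h1", "A-h2", "B-h1", "B-h1", "A-h1", "B-h2",
                  "C-h1", "C-h1", "C-h1"),
    stringsAsFactors = FALSE)
  out <- count_independent_origins(samples)
  ab <- out[out$hybrid_type == "spA x spB", ]
  expect_equal(ab$n_samples, 6L)
  expect_equal(ab$min_independent_origins, 4L) # distinct tuples
  expect_true(ab$reciprocal_cross)
  ac <- out[out$hybrid_type == "spA x spC", ]
  expect_equal(ac$min_independent_origins, 1L)
  expect_false(ac$reciprocal_cross)
  # invariants: reorder-invariant, never exceeds sample count
  perm <- samples[sample(nrow(samples)), ]
  out2 <- count_independent_origins(perm)
  expect_identical(out[order(out$hybrid_type), ],
                   out2[order(out2$hybrid_type), ])
  expect_true(all(out$min_independent_origins <= out$n_samples))
})
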