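#' Simulation configuration
#'
#' Defines the structure the simulator emulates: a small genus of hexaploid
#' aquatic plants split into two clades, species containing one to several
#' geographically structured genotypes separated by a handful of
#' substitutions and occasional short indels, nuclear direct sequences that
#' are IUPAC-additive superpositions of two ribotypes, clone sets
#' contaminated by per-base polymerase errors and single-breakpoint PCR
#' chimeras, and plastid haplotypes inherited from exactly one parent.
#'
#' @param seed Integer seed; all outputs are deterministic under it.
#' @param n_species Number of species (split evenly into two clades).
#' @param genotypes_per_species Integer vector (recycled) of genotypes per
#'   species.
#' @param seq_length Named lengths of the four markers.
#' @param interspecies_subst Substitutions between species consensuses of
#'   the same clade (clade stems carry twice this).
#' @param intragenotype_subst Expected substitutions between genotype 1 and
#'   the other genotypes of a species; realized counts are drawn uniformly
#'   from `1:(2*intragenotype_subst - 1)` unless `genotype_divergence` fixes
#'   them.
#' @param genotype_divergence Optional list (by species index) of integer
#'   vectors giving the exact substitution count of each further genotype
#'   from genotype 1 — used to calibrate the panel to printed genotype
#'   distances.
#' @param indel_prob Probability a genotype carries one internal gap run of
#'   length 1-6 (nuclear markers only).
#' @param clone_error_rate Per-base polymerase error probability per clone.
#' @param chimera_rate Per-clone probability of being a single-breakpoint
#'   chimera.
#' @param min_clones Clones drawn initially per cloned sample.
#' @param clone_cap Maximum clones drawn while searching for a missing copy
#'   type.
#' @param sample_mix Proportions of pure / intraspecific-hybrid /
#'   interspecific-hybrid samples (sums to 1).
#' @param n_samples Collection size.
#' @param plastid_haplotypes_per_species Haplotypes per species on plastid
#'   markers.
#' @param plastid_shared Optional list of species-index pairs `c(i, j)`:
#'   species `j` carries species `i`'s plastid haplotype (shared-haplotype
#'   case that makes maternal assignment equivocal).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 6L,
                       genotypes_per_species = c(7L, 2L, 2L, 2L, 1L, 1L),
                       seq_length = c(ITS = 700L, `5S-NTS` = 300L,
                                      `rpl20-rps12` = 700L,
                                      `trnT-trnL` = 1000L),
                       interspecies_subst = 10L,
                       intragenotype_subst = 3L,
                       genotype_divergence = NULL,
                       indel_prob = 0.15,
                       clone_error_rate = 0.002,
                       chimera_rate = 0.1,
                       min_clones = 5L,
                       clone_cap = 20L,
                       sample_mix = c(pure = 0.60,
                                      intraspecific_hybrid = 0.12,
                                      interspecific_hybrid = 0.28),
                       n_samples = 200L,
                       plastid_haplotypes_per_species = 2L,
                       plastid_shared = list(c(2L, 3L))) {
  genotypes_per_species <- rep_len(as.integer(genotypes_per_species),
                                   n_species)
  stopifnot(all(seq_length >= 50L),
            indel_prob >= 0, indel_prob <= 1,
            clone_error_rate >= 0, clone_error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            abs(sum(sample_mix) - 1) < 1e-9,
            min_clones >= 2L, clone_cap >= min_clones)
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    genotypes_per_species = genotypes_per_species,
    seq_length = seq_length,
    interspecies_subst = as.integer(interspecies_subst),
    intragenotype_subst = as.integer(intragenotype_subst),
    genotype_divergence = genotype_divergence,
    indel_prob = indel_prob, clone_error_rate = clone_error_rate,
    chimera_rate = chimera_rate, min_clones = as.integer(min_clones),
    clone_cap = as.integer(clone_cap), sample_mix = sample_mix,
    n_samples = as.integer(n_samples),
    plastid_haplotypes_per_species =
      as.integer(plastid_haplotypes_per_species),
    plastid_shared = plastid_shared), class = "sim_config")
}

.rand_seq <- function(L) sample(c(1L, 2L, 4L, 8L), L, replace = TRUE)

# mutate `n` columns of a mask vector, drawing columns from `pool` without
# replacement so that lineages never overwrite each other's substitutions
# and pairwise distances are exact sums of per-lineage counts
.mutate <- function(mask, n, pool) {
  if (n > length(pool))
    stop("infeasible: expected substitutions exceed available columns",
         call. = FALSE)
  cols <- if (n > 0L) sample(pool, n) else integer(0)
  for (j in cols) {
    alt <- setdiff(c(1L, 2L, 4L, 8L), mask[j])
    mask[j] <- sample(alt, 1L)
  }
  list(mask = mask, used = cols)
}

# evolve species consensuses and genotypes on one marker; returns masks and
# a label table
.evolve_marker <- function(cfg, L, n_variants_per_species, divergence,
                           with_indels) {
  pool <- seq_len(L)
  root <- .rand_seq(L)
  half <- ceiling(cfg$n_species / 2)
  clade_of <- ifelse(seq_len(cfg$n_species) <= half, 1L, 2L)
  clades <- list()
  for (cl in 1:2) {
    res <- .mutate(root, 2L * cfg$interspecies_subst, pool)
    pool <- setdiff(pool, res$used)
    clades[[cl]] <- res$mask
  }
  species_masks <- list()
  for (s in seq_len(cfg$n_species)) {
    res <- .mutate(clades[[clade_of[s]]],
                   ceiling(cfg$interspecies_subst / 2), pool)
    pool <- setdiff(pool, res$used)
    species_masks[[s]] <- res$mask
  }
  out <- list()
  labels <- data.frame(genotype = character(0), species = character(0),
                       stringsAsFactors = FALSE)
  for (s in seq_len(cfg$n_species)) {
    sp <- sprintf("sp%d", s)
    nv <- n_variants_per_species[s]
    for (g in seq_len(nv)) {
      if (g == 1L) {
        mask <- species_masks[[s]]
      } else {
        d <- divergence[[s]][g - 1L]
        res <- .mutate(species_masks[[s]], d, pool)
        pool <- setdiff(pool, res$used)
        mask <- res$mask
      }
      if (with_indels && stats::runif(1) < cfg$indel_prob) {
        # the gap run is placed on columns no lineage has mutated, so the
        # calibrated substitution distances stay exact by construction
        len <- sample(1:6, 1L)
        for (try in 1:50) {
          start <- sample(seq(2L, L - len - 1L), 1L)
          range <- start:(start + len - 1L)
          if (all(range %in% pool)) {
            mask[range] <- 0L
            pool <- setdiff(pool, range)
            break
          }
        }
      }
      lab <- sprintf("%s_gt%d", sp, g)
      out[[lab]] <- mask
      labels <- rbind(labels, data.frame(genotype = lab, species = sp,
                                         stringsAsFactors = FALSE))
    }
  }
  list(masks = out, labels = labels)
}

#' Simulate reference panels for all four markers
#'
#' Species consensuses are drawn by mutating a root sequence along a
#' two-clade species structure; genotypes by further mutation. Mutated
#' columns are drawn without replacement within a marker, so pairwise
#' genotype distances equal the sums of per-lineage substitution counts
#' exactly — calibration targets such as a printed six-substitution
#' distance hold by construction. Nuclear and plastid markers evolve on the
#' same species structure with independent mutations; plastid panels carry
#' haplotypes (optionally shared between designated species pairs) instead
#' of genotypes.
#'
#' @param cfg A `sim_config`.
#' @return List of class `sim_panel`: `panels` (named list of
#'   `genotype_panel` per marker), `truth` (genotype/haplotype label tables
#'   per marker), `cfg`.
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed)
  panels <- list()
  truth <- list()
  # realized genotype divergences (shared across nuclear markers so both
  # markers tell the same genotype story)
  divergence <- cfg$genotype_divergence
  if (is.null(divergence)) {
    hi <- max(1L, 2L * cfg$intragenotype_subst - 1L)
    divergence <- lapply(cfg$genotypes_per_species, function(nv)
      if (nv > 1L) sample(hi, nv - 1L, replace = TRUE) else integer(0))
  }
  for (mk in c("ITS", "5S-NTS")) {
    ev <- .evolve_marker(cfg, cfg$seq_length[[mk]],
                         cfg$genotypes_per_species, divergence,
                         with_indels = TRUE)
    aln <- marker_alignment(
      stats::setNames(vapply(ev$masks, .string_of_masks, character(1)),
                      names(ev$masks)),
      marker = mk,
      meta = data.frame(sample_id = names(ev$masks),
                        species = ev$labels$species,
                        genotype = ev$labels$genotype, role = "consensus"))
    panels[[mk]] <- build_panel(aln)
    truth[[mk]] <- ev$labels
  }
  n_hap <- rep_len(cfg$plastid_haplotypes_per_species, cfg$n_species)
  hap_div <- lapply(n_hap, function(nv)
    if (nv > 1L) sample(3L, nv - 1L, replace = TRUE) else integer(0))
  for (mk in c("rpl20-rps12", "trnT-trnL")) {
    ev <- .evolve_marker(cfg, cfg$seq_length[[mk]], n_hap, hap_div,
                         with_indels = FALSE)
    # shared plastid haplotypes: species j's first haplotype is a copy of
    # species i's (maternal assignment between them becomes equivocal)
    for (pr in cfg$plastid_shared) {
      src <- sprintf("sp%d_gt1", pr[1])
      dst <- sprintf("sp%d_gt1", pr[2])
      if (src %in% names(ev$masks) && dst %in% names(ev$masks))
        ev$masks[[dst]] <- ev$masks[[src]]
    }
    labs <- ev$labels
    labs$genotype <- sub("_gt", "_h", labs$genotype)
    names(ev$masks) <- sub("_gt", "_h", names(ev$masks))
    aln <- marker_alignment(
      stats::setNames(vapply(ev$masks, .string_of_masks, character(1)),
                      names(ev$masks)),
      marker = mk,
      meta = data.frame(sample_id = names(ev$masks),
                        species = labs$species,
                        genotype = labs$genotype, role = "consensus"))
    panels[[mk]] <- build_panel(aln)
    truth[[mk]] <- labs
  }
  structure(list(panels = panels, truth = truth, cfg = cfg),
            class = "sim_panel")
}

# draw one clone from two parental copies: chimera with single breakpoint
# (each side keeping >= 2 informative sites; switches closer to an end are
# observationally a parental clone and are generated as such), then
# per-base polymerase errors
.draw_clone <- function(copyA, copyB, info, cfg) {
  is_chimera <- FALSE
  breakpoint <- NA_integer_
  source <- sample(c("A", "B"), 1L)
  seq <- if (source == "A") copyA else copyB
  if (length(info) >= 4L && stats::runif(1) < cfg$chimera_rate) {
    # breakpoint between informative sites k and k+1, both sides >= 2 sites
    k <- sample(2:(length(info) - 2L), 1L)
    left <- sample(c("A", "B"), 1L)
    first <- if (left == "A") copyA else copyB
    second <- if (left == "A") copyB else copyA
    cut <- info[k] # switch right after this column
    seq <- c(first[seq_len(cut)], second[(cut + 1L):length(first)])
    is_chimera <- TRUE
    breakpoint <- cut
    source <- "chimera"
  }
  err_cols <- which(stats::runif(length(seq)) < cfg$clone_error_rate &
                      seq != 0L)
  for (j in err_cols) {
    seq[j] <- sample(setdiff(c(1L, 2L, 4L, 8L), seq[j]), 1L)
  }
  list(seq = seq, source = source, chimera = is_chimera,
       breakpoint = breakpoint, error_cols = err_cols)
}

#' Simulate one sample
#'
#' The direct sequence is the column-wise IUPAC merge of the chosen one or
#' two ribotypes (columns where exactly one copy is gapped become `N` in
#' the direct read — an indel polymorphism makes the trace unreadable from
#' that point, so no base call is available). Hybrid samples receive a
#' clone set drawn from the two copies with polymerase errors and
#' single-breakpoint chimeras, drawing `min_clones` and continuing until the
#' missing copy type is found (up to `clone_cap`); the plastid haplotype is
#' copied from the designated maternal parent.
#'
#' @param cfg A `sim_config`.
#' @param sim A `sim_panel` from [simulate_panel()].
#' @param truth_class `"pure"`, `"intraspecific_hybrid"` or
#'   `"interspecific_hybrid"`.
#' @param sample_id Sample id.
#' @return List with `direct` (named list of residue strings per nuclear
#'   marker), `clones` (per nuclear marker, a `marker_alignment` or NULL),
#'   `plastid` (named list per plastid marker), `truth` (a one-row truth
#'   data frame) and `clone_truth` (per-clone data frame).
#' @export
simulate_sample <- function(cfg, sim, truth_class, sample_id = "s1") {
  panels <- sim$panels
  its <- panels[["ITS"]]
  gt_species <- its$species
  if (truth_class == "pure") {
    g1 <- sample(its$labels, 1L)
    g2 <- NULL
  } else if (truth_class == "intraspecific_hybrid") {
    sp_ok <- names(which(table(gt_species) >= 2L))
    sp <- sample(sp_ok, 1L)
    gts <- sample(its$labels[gt_species == sp], 2L)
    g1 <- gts[1]; g2 <- gts[2]
  } else {
    sps <- sample(unique(unname(gt_species)), 2L)
    g1 <- sample(its$labels[gt_species == sps[1]], 1L)
    g2 <- sample(its$labels[gt_species == sps[2]], 1L)
  }
  maternal_gt <- if (is.null(g2)) g1 else sample(c(g1, g2), 1L)
  maternal_sp <- unname(gt_species[maternal_gt])

  direct <- list(); clones <- list(); clone_truth <- NULL
  for (mk in c("ITS", "5S-NTS")) {
    p <- panels[[mk]]
    cA <- .mask_string(panel_consensus(p, g1))
    if (is.null(g2)) {
      dm <- cA
      cB <- NULL
    } else {
      cB <- .mask_string(panel_consensus(p, g2))
      dm <- bitwOr(cA, cB)
      dm[cA == 0L & cB == 0L] <- 0L
      dm[(cA == 0L) != (cB == 0L)] <- 15L # indel polymorphism: no call
    }
    direct[[mk]] <- .string_of_masks(dm)
    if (!is.null(g2)) {
      info <- which(.mask_size(cA) == 1L & .mask_size(cB) == 1L & cA != cB)
      drawn <- list()
      repeat {
        drawn <- c(drawn, list(.draw_clone(cA, cB, info, cfg)))
        n <- length(drawn)
        src <- vapply(drawn, `[[`, character(1), "source")
        if (n >= cfg$min_clones &&
            (all(c("A", "B") %in% src) || n >= cfg$clone_cap)) break
      }
      cl_seqs <- vapply(drawn, function(d) .string_of_masks(d$seq),
                        character(1))
      cl_ids <- sprintf("%s_%s_cl%d", sample_id, mk, seq_along(drawn))
      clones[[mk]] <- marker_alignment(
        stats::setNames(cl_seqs, cl_ids), marker = mk,
        meta = data.frame(sample_id = cl_ids, species = "unknown",
                          genotype = NA_character_, role = "clone"))
      clone_truth <- rbind(clone_truth, data.frame(
        sample_id = sample_id, marker = mk, clone_id = cl_ids,
        source = vapply(drawn, `[[`, character(1), "source"),
        breakpoint = vapply(drawn, `[[`, integer(1), "breakpoint"),
        n_errors = vapply(drawn, function(d) length(d$error_cols),
                          integer(1)),
        error_cols = vapply(drawn, function(d)
          paste(d$error_cols, collapse = ","), character(1)),
        stringsAsFactors = FALSE))
    }
  }
  plastid <- list()
  plastid_hap <- list()
  for (mk in c("rpl20-rps12", "trnT-trnL")) {
    p <- panels[[mk]]
    haps <- p$labels[p$species[p$labels] == maternal_sp]
    hap <- sample(haps, 1L)
    plastid[[mk]] <- panel_consensus(p, hap)
    plastid_hap[[mk]] <- hap
  }
  truth <- data.frame(
    sample_id = sample_id, true_class = truth_class,
    genotype1 = g1, genotype2 = if (is.null(g2)) NA_character_ else g2,
    species1 = unname(gt_species[g1]),
    species2 = if (is.null(g2)) NA_character_ else unname(gt_species[g2]),
    maternal_species = maternal_sp,
    maternal_haplotype_rpl = plastid_hap[["rpl20-rps12"]],
    maternal_haplotype_trn = plastid_hap[["trnT-trnL"]],
    stringsAsFactors = FALSE)
  list(direct = direct, clones = clones, plastid = plastid, truth = truth,
       clone_truth = clone_truth)
}

#' Simulate a full sample collection
#'
#' @param cfg A `sim_config`.
#' @param sim Optional pre-built `sim_panel` (rebuilt from `cfg` otherwise).
#' @return List of class `sim_collection`: `panels`, per-marker direct
#'   `alignments`, `clones` (list per sample per marker), `truth` (one row
#'   per sample), `clone_truth`, `cfg`.
#' @export
simulate_collection <- function(cfg, sim = NULL) {
  if (is.null(sim)) sim <- simulate_panel(cfg)
  set.seed(cfg$seed + 1L)
  classes <- sample(names(cfg$sample_mix), cfg$n_samples, replace = TRUE,
                    prob = cfg$sample_mix)
  samples <- lapply(seq_len(cfg$n_samples), function(i)
    simulate_sample(cfg, sim, classes[i], sprintf("s%03d", i)))
  truth <- do.call(rbind, lapply(samples, `[[`, "truth"))
  clone_truth <- do.call(rbind, lapply(samples, `[[`, "clone_truth"))
  alignments <- list()
  for (mk in c("ITS", "5S-NTS", "rpl20-rps12", "trnT-trnL")) {
    nuclear <- mk %in% c("ITS", "5S-NTS")
    seqs <- vapply(samples, function(s)
      if (nuclear) s$direct[[mk]] else s$plastid[[mk]], character(1))
    names(seqs) <- truth$sample_id
    alignments[[mk]] <- marker_alignment(
      seqs, marker = mk,
      meta = data.frame(sample_id = truth$sample_id, species = "unknown",
                        genotype = NA_character_, role = "direct"))
  }
  clones <- lapply(samples, `[[`, "clones")
  names(clones) <- truth$sample_id
  structure(list(panels = sim$panels, alignments = alignments,
                 clones = clones, truth = truth,
                 clone_truth = clone_truth, cfg = cfg),
            class = "sim_collection")
}

#' Write a simulated collection to disk
#'
#' Emits per-marker FASTA of direct/plastid sequences, per-sample clone
#' FASTA, panel FASTA+TSV, a sample metadata TSV and the truth tables.
#' Regeneration under the same seed is byte-identical.
#'
#' @param collection A `sim_collection`.
#' @param dir Output directory (created).
#' @return Invisibly, the paths written.
#' @export
emit_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  safe <- function(mk) gsub("[^A-Za-z0-9]", "_", mk)
  for (mk in names(collection$alignments)) {
    p <- file.path(dir, paste0(safe(mk), ".fasta"))
    write_fasta(collection$alignments[[mk]], p)
    paths <- c(paths, p)
    pp <- file.path(dir, paste0("panel_", safe(mk), ".fasta"))
    pt <- file.path(dir, paste0("panel_", safe(mk), ".tsv"))
    write_panel(collection$panels[[mk]], pp, pt)
    paths <- c(paths, pp, pt)
  }
  clone_dir <- file.path(dir, "clones")
  dir.create(clone_dir, showWarnings = FALSE)
  for (sid in names(collection$clones)) {
    for (mk in names(collection$clones[[sid]])) {
      p <- file.path(clone_dir, paste0(sid, "_", safe(mk), ".fasta"))
      write_fasta(collection$clones[[sid]][[mk]], p)
      paths <- c(paths, p)
    }
  }
  meta <- data.frame(sample_id = collection$truth$sample_id,
                     species = "unknown", genotype = "", role = "direct",
                     stringsAsFactors = FALSE)
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(collection$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ctp <- file.path(dir, "clone_truth.tsv")
  if (!is.null(collection$clone_truth))
    utils::write.table(collection$clone_truth, ctp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(paths, mp, tp, ctp))
}
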