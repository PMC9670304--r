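#' Summarize hybrid genotype combinations and maternal directions
#'
#' Tabulates, per hybrid type (unordered species pair, lexicographically
#' sorted and printed `"A x B"`), the sample count, the distinct unordered
#' genotype combinations with their counts, the maternal direction counts
#' per parent species, whether both directions occur (reciprocal crosses)
#' and the lower bound on independent origins from distinct
#' (maternal species, haplotype) tuples.
#'
#' @param calls_df Data frame from [calls_table()] joined with species
#'   information, or a list of `additivity_call`s plus `panel`.
#' @param maternal_df Data frame with columns `sample_id`, `maternal`,
#'   `haplotype`, `call` (from [maternal_table()]).
#' @param panel Optional `genotype_panel` used to map genotype labels to
#'   species when `calls_df` is a call list.
#' @return A list of class `hybrid_summary`: `by_type` (data frame
#'   `hybrid_type`, `n_samples`, `n_combinations`,
#'   `maternal_counts`, `reciprocal_cross`, `min_independent_origins`),
#'   `combinations` (data frame `hybrid_type`, `combination`, `n`),
#'   `unjoined` (sample ids present on one side only).
#' @export
summarize_combinations <- function(calls_df, maternal_df = NULL,
                                   panel = NULL) {
  if (!is.data.frame(calls_df)) calls_df <- calls_table(calls_df)
  hyb <- calls_df[calls_df$verdict %in%
                    c("intraspecific_hybrid", "interspecific_hybrid"), ,
                  drop = FALSE]
  unjoined <- character(0)
  if (!is.null(maternal_df)) {
    unjoined <- c(setdiff(hyb$sample_id, maternal_df$sample_id))
  }
  if (nrow(hyb) == 0L) {
    return(structure(list(
      by_type = data.frame(), combinations = data.frame(),
      unjoined = unjoined), class = "hybrid_summary"))
  }
  gts <- strsplit(hyb$hypothesis, "+", fixed = TRUE)
  species_of <- function(g) {
    if (!is.null(panel)) unname(panel$species[g]) else
      sub("_gt.*$|_h.*$", "", g)
  }
  hyb$hybrid_type <- vapply(gts, function(g)
    paste(sort(species_of(g)), collapse = " x "), character(1))
  hyb$combination <- vapply(gts, function(g)
    paste(sort(g), collapse = " + "), character(1))
  if (!is.null(maternal_df)) {
    idx <- match(hyb$sample_id, maternal_df$sample_id)
    hyb$maternal <- maternal_df$maternal[idx]
    hyb$haplotype <- maternal_df$haplotype[idx]
  } else {
    hyb$maternal <- NA_character_
    hyb$haplotype <- NA_character_
  }
  comb <- as.data.frame(table(hybrid_type = hyb$hybrid_type,
                              combination = hyb$combination),
                        stringsAsFactors = FALSE)
  comb <- comb[comb$Freq > 0L, , drop = FALSE]
  names(comb)[3] <- "n"
  rownames(comb) <- NULL
  origins <- count_independent_origins(
    data.frame(hybrid_type = hyb$hybrid_type, maternal = hyb$maternal,
               haplotype = hyb$haplotype, stringsAsFactors = FALSE))
  by_type <- lapply(split(hyb, hyb$hybrid_type), function(d) {
    mat <- table(d$maternal[!is.na(d$maternal)])
    data.frame(
      hybrid_type = d$hybrid_type[1],
      n_samples = nrow(d),
      n_combinations = length(unique(d$combination)),
      maternal_counts = paste(sprintf("%s:%d", names(mat), mat),
                              collapse = ";"),
      stringsAsFactors = FALSE)
  })
  by_type <- do.call(rbind, by_type)
  by_type <- merge(by_type, origins[, c("hybrid_type", "reciprocal_cross",
                                        "min_independent_origins")],
                   by = "hybrid_type")
  rownames(by_type) <- NULL
  structure(list(by_type = by_type, combinations = comb,
                 unjoined = unjoined), class = "hybrid_summary")
}

#' @export
print.hybrid_summary <- function(x, ...) {
  if (nrow(x$by_type) == 0L) {
    cat("hybrid_summary: no hybrids\n")
    return(invisible(x))
  }
  cat("hybrid_summary:\n")
  print(x$by_type, row.names = FALSE)
  invisible(x)
}

#' Tabulate maternal calls
#'
#' @param calls List of `maternal_call`s.
#' @return Data frame `sample_id`, `marker`, `call`, `maternal`,
#'   `candidates`, `haplotype` (matched or nearest), `distance`,
#'   `equivocal` (asterisk-convention column: `"*"` for equivocal calls).
#' @export
maternal_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) data.frame(
    sample_id = x$sample_id, marker = x$marker, call = x$call,
    maternal = if (is.na(x$maternal)) NA_character_ else x$maternal,
    candidates = paste(x$candidates, collapse = ","),
    haplotype = paste(if (length(x$matched_haplotype))
      x$matched_haplotype else x$derived_from, collapse = ","),
    distance = x$distance,
    equivocal = if (x$call == "equivocal") "*" else "",
    stringsAsFactors = FALSE)))
}

#' Run the full hybrid-diagnosis pipeline on a simulated or read collection
#'
#' Stages, in order: nuclear classification of every direct sequence
#' against the ITS panel; clone analysis for every sample with a clone set;
#' maternal assignment of every hybrid from both plastid markers with
#' cross-marker resolution; selection and deduplication of pure sequences
#' with indel coding and NEXUS export; summary. Every stage writes TSV/
#' FASTA artifacts into `out_dir` (when given) plus a JSON manifest
#' (seed, thresholds, checksums); no sample is dropped silently.
#'
#' @param collection A `sim_collection` (or a list with the same elements
#'   built from files: `panels`, `alignments`, `clones`).
#' @param out_dir Optional output directory for artifacts.
#' @param tolerance,min_minor_fraction,min_block Thresholds, see
#'   [classify_direct()] and [detect_breakpoints()].
#' @return A list of class `pipeline_result`: `calls`, `calls_df`,
#'   `clone_reports`, `maternal`, `maternal_df`, `summary`
#'   (a `hybrid_summary`), `phylogeny` (selected alignment and exclusion
#'   log), `manifest`.
#' @export
run_pipeline <- function(collection, out_dir = NULL, tolerance = 0L,
                         min_minor_fraction = 0.30, min_block = 2L) {
  panels <- collection$panels
  its_aln <- collection$alignments[["ITS"]]
  its_panel <- panels[["ITS"]]

  # stage 1: classification
  calls <- classify_alignment(its_aln, its_panel, tolerance = tolerance,
                              min_minor_fraction = min_minor_fraction)
  calls_df <- calls_table(calls)

  # stage 2: clone analysis where clone sets exist
  clone_reports <- list()
  for (sid in names(collection$clones)) {
    for (mk in names(collection$clones[[sid]])) {
      cl <- collection$clones[[sid]][[mk]]
      if (is.null(cl) || length(cl$seqs) == 0L) next
      call <- calls[[sid]]
      pA <- pB <- NULL
      if (!is.null(call) && length(call$hypothesis) == 2L &&
          !anyNA(call$hypothesis) && mk %in% names(panels)) {
        pA <- panel_consensus(panels[[mk]], call$hypothesis[1])
        pB <- panel_consensus(panels[[mk]], call$hypothesis[2])
      }
      direct <- if (mk == "ITS") its_aln$seqs[[sid]] else
        collection$alignments[[mk]]$seqs[[sid]]
      clone_reports[[paste(sid, mk, sep = ":")]] <-
        analyze_clones(cl, direct, parentA = pA, parentB = pB,
                       panel = panels[[mk]], sample_id = sid,
                       min_block = min_block)
    }
  }

  # stage 3: maternal assignment for hybrid verdicts
  hybrid_ids <- calls_df$sample_id[calls_df$verdict == "interspecific_hybrid"]
  maternal <- list()
  for (sid in hybrid_ids) {
    pair_sp <- unique(unname(its_panel$species[calls[[sid]]$hypothesis]))
    per_marker <- list()
    for (mk in c("rpl20-rps12", "trnT-trnL")) {
      if (!mk %in% names(collection$alignments)) next
      seq <- collection$alignments[[mk]]$seqs[[sid]]
      if (is.null(seq)) next
      per_marker[[mk]] <- assign_maternal(
        seq, panels[[mk]], parent_species = pair_sp, sample_id = sid)
    }
    if (length(per_marker))
      maternal[[sid]] <- cross_marker_resolve(unname(per_marker))
  }
  maternal_df <- if (length(maternal)) maternal_table(maternal) else
    data.frame(sample_id = character(0), maternal = character(0),
               haplotype = character(0), stringsAsFactors = FALSE)

  # stage 4: selection, deduplication, indel coding, export
  sel <- select_for_phylogeny(calls, its_aln)
  dedup <- collapse_identical(sel$alignment)
  coded <- simple_indel_code(dedup$alignment)
  tree_matrix <- concatenate_with_indels(dedup$alignment, coded)

  # stage 5: summary
  summary <- summarize_combinations(calls_df, maternal_df,
                                    panel = its_panel)

  manifest <- list(
    package = "ribohybrid",
    version = as.character(utils::packageVersion("ribohybrid")),
    thresholds = list(tolerance = tolerance,
                      min_minor_fraction = min_minor_fraction,
                      min_block = min_block),
    n_samples = length(calls),
    n_hybrids = length(hybrid_ids),
    seed = collection$cfg$seed %||% NA)

  result <- structure(list(
    calls = calls, calls_df = calls_df, clone_reports = clone_reports,
    maternal = maternal, maternal_df = maternal_df, summary = summary,
    phylogeny = list(alignment = tree_matrix, classes = dedup$classes,
                     exclusion_log = sel$log, indels = coded),
    manifest = manifest), class = "pipeline_result")

  if (!is.null(out_dir)) .write_artifacts(result, out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(result$calls_df, "calls.tsv")
  if (nrow(result$maternal_df)) w(result$maternal_df, "maternal.tsv")
  w(result$phylogeny$exclusion_log, "exclusions.tsv")
  if (nrow(result$summary$by_type)) {
    w(result$summary$by_type, "hybrid_summary.tsv")
    w(result$summary$combinations, "genotype_combinations.tsv")
  }
  if (length(result$phylogeny$alignment$seqs)) {
    write_fasta(result$phylogeny$alignment,
                file.path(out_dir, "tree_matrix.fasta"))
    export_nexus(result$phylogeny$alignment,
                 file.path(out_dir, "tree_matrix.nex"))
  }
  manifest <- result$manifest
  manifest$artifact_checksums <- vapply(
    list.files(out_dir, full.names = TRUE), function(f)
      as.character(tools::md5sum(f)), character(1))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$calls_df), "samples;",
      sum(x$calls_df$verdict == "pure"), "pure,",
      sum(x$calls_df$verdict == "intraspecific_hybrid"), "intraspecific,",
      sum(x$calls_df$verdict == "interspecific_hybrid"),
      "interspecific hybrids\n")
  invisible(x)
}
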