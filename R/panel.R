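#' Build a genotype reference panel
#'
#' Collapses labelled sequences into one consensus per genotype label. The
#' consensus state of a column is the majority among unambiguous non-missing
#' states (gaps count as a state); ties between states are stored as their
#' IUPAC merge and flagged, and any within-genotype conflict among
#' unambiguous states is recorded as a warning rather than silently resolved.
#' Genotype consensuses that are identical over all non-gap, non-N columns
#' are merged under the lexicographically first label, with the others kept
#' as aliases.
#'
#' @param aln A `marker_alignment` of reference sequences.
#' @param labels Optional data frame `sample_id`, `species`, `genotype`;
#'   defaults to the alignment metadata. Every genotype must map to exactly
#'   one species.
#' @return An object of class `genotype_panel` with elements `marker`,
#'   `labels`, `species` (named by genotype label), `consensus` (named
#'   character vector), `aliases`, `warnings` (data frame genotype, column,
#'   states), `length`, and a cached vector `diagnostic_columns` of columns
#'   at which some genotype pair differs by unambiguous, disjoint states.
#' @export
build_panel <- function(aln, labels = NULL) {
  if (is.null(labels)) labels <- aln$meta
  labels <- labels[!is.na(labels$genotype) & labels$genotype != "", ,
                   drop = FALSE]
  labels <- labels[labels$sample_id %in% names(aln$seqs), , drop = FALSE]
  if (nrow(labels) == 0L) stop("empty label set", call. = FALSE)
  sp_by_gt <- tapply(labels$species, labels$genotype,
                     function(x) unique(x), simplify = FALSE)
  conflicting <- names(sp_by_gt)[lengths(sp_by_gt) > 1L]
  if (length(conflicting))
    stop("conflicting species assignment for genotype(s): ",
         paste(conflicting, collapse = ", "), call. = FALSE)

  gts <- sort(unique(labels$genotype))
  warnings <- data.frame(genotype = character(0), column = integer(0),
                         states = character(0), stringsAsFactors = FALSE)
  cons <- character(0)
  for (g in gts) {
    ids <- labels$sample_id[labels$genotype == g]
    m <- .mask_matrix(aln_char_matrix(aln_subset(aln, ids)))
    res <- .column_consensus(m)
    cons[g] <- res$consensus
    if (length(res$flagged)) {
      warnings <- rbind(warnings, data.frame(
        genotype = g, column = res$flagged, states = res$states,
        stringsAsFactors = FALSE))
    }
  }

  # merge same-species genotypes whose consensuses agree at every
  # informative column; identical consensuses in *different* species are
  # retained — a haplotype shared between species is a biological signal
  # (it is what makes a maternal call equivocal), not a redundancy
  gt_species <- vapply(sp_by_gt, `[[`, character(1), 1L)
  aliases <- list()
  keep <- character(0)
  for (g in gts) {
    dup <- NULL
    for (k in keep) {
      if (gt_species[[g]] == gt_species[[k]] &&
          .consensus_identical(cons[g], cons[k])) { dup <- k; break }
    }
    if (is.null(dup)) keep <- c(keep, g)
    else aliases[[dup]] <- c(aliases[[dup]], g)
  }
  species <- vapply(sp_by_gt[keep], `[[`, character(1), 1L)
  panel <- structure(
    list(marker = aln$marker, labels = keep, species = species,
         consensus = cons[keep], aliases = aliases, warnings = warnings,
         length = aln$length),
    class = "genotype_panel")
  panel$diagnostic_columns <- .panel_diag_columns(panel)
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", x$marker, "-", length(x$labels), "genotypes (",
      length(unique(x$species)), "species ),", x$length, "columns,",
      length(x$diagnostic_columns), "diagnostic columns\n")
  invisible(x)
}

# majority consensus of a mask matrix; ties merged and flagged
.column_consensus <- function(m) {
  L <- ncol(m)
  out <- integer(L)
  flagged <- integer(0)
  states <- character(0)
  for (j in seq_len(L)) {
    col <- m[, j]
    informative <- col[col == 0L | .mask_size(col) == 1L] # gap or unambiguous
    if (length(informative) == 0L) { out[j] <- 15L; next } # all ambiguous/N
    tab <- sort(table(informative), decreasing = TRUE)
    top <- as.integer(names(tab)[tab == tab[1]])
    if (length(top) == 1L) {
      out[j] <- top
      if (length(tab) > 1L) { # minority conflict among unambiguous states
        flagged <- c(flagged, j)
        states <- c(states, paste(.IUPAC_SYM[as.integer(names(tab)) + 1L],
                                  collapse = "/"))
      }
    } else {
      # tie: store IUPAC merge of tied non-gap states, flag the column
      nz <- top[top != 0L]
      out[j] <- if (length(nz)) Reduce(bitwOr, nz) else 0L
      flagged <- c(flagged, j)
      states <- c(states, paste(.IUPAC_SYM[top + 1L], collapse = "/"))
    }
  }
  list(consensus = .string_of_masks(out), flagged = flagged, states = states)
}

# identical over columns where both are neither gap nor N
.consensus_identical <- function(a, b) {
  ma <- .mask_string(a); mb <- .mask_string(b)
  use <- ma != 0L & ma != 15L & mb != 0L & mb != 15L
  all(ma[use] == mb[use])
}

.panel_diag_columns <- function(panel) {
  m <- do.call(rbind, lapply(panel$consensus, .mask_string))
  if (nrow(m) < 2L) return(integer(0))
  diag_col <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    u <- col[.mask_size(col) == 1L] # unambiguous, non-gap
    if (length(unique(u)) > 1L) diag_col[j] <- TRUE
  }
  which(diag_col)
}

#' Consensus sequence of a panel genotype
#'
#' @param panel A `genotype_panel`.
#' @param label Genotype label (aliases resolve to their representative).
#' @return The consensus residue string.
#' @export
panel_consensus <- function(panel, label) {
  if (label %in% panel$labels) return(unname(panel$consensus[label]))
  for (k in names(panel$aliases)) {
    if (label %in% panel$aliases[[k]]) return(unname(panel$consensus[k]))
  }
  stop("unknown genotype label: ", label, call. = FALSE)
}

#' Count substitution differences between two aligned sequences
#'
#' A column counts as a substitution when both sequences carry a non-gap
#' state and their IUPAC base sets are disjoint. Overlapping base sets count
#' as zero differences (a direct sequence with R is compatible with both an
#' A- and a G-genotype), and indel differences are never counted here — they
#' are reported separately by [diagnostic_sites()].
#'
#' @param a,b Residue strings of equal length (or genotype labels together
#'   with `panel`).
#' @param panel Optional `genotype_panel` to resolve labels.
#' @return Integer substitution count.
#' @export
pairwise_substitutions <- function(a, b, panel = NULL) {
  if (!is.null(panel)) {
    a <- panel_consensus(panel, a)
    b <- panel_consensus(panel, b)
  }
  ma <- .mask_string(a); mb <- .mask_string(b)
  if (length(ma) != length(mb))
    stop("length mismatch: ", length(ma), " vs ", length(mb), call. = FALSE)
  sum(ma != 0L & mb != 0L & bitwAnd(ma, mb) == 0L)
}

#' Diagnostic sites between two panel genotypes
#'
#' @param panel A `genotype_panel`.
#' @param g1,g2 Genotype labels in the panel.
#' @return A list of class `diagnostic_sites` with `pair`, `sites` (data
#'   frame `column` (1-based), `state_a`, `state_b`; both states unambiguous
#'   non-gap and different) and `indel_sites` (columns where exactly one
#'   genotype has a gap). Columns where either consensus is N or ambiguous
#'   are excluded from `sites`.
#' @export
diagnostic_sites <- function(panel, g1, g2) {
  ma <- .mask_string(panel_consensus(panel, g1))
  mb <- .mask_string(panel_consensus(panel, g2))
  both_unamb <- .mask_size(ma) == 1L & .mask_size(mb) == 1L
  site_cols <- which(both_unamb & ma != mb)
  indel_cols <- which((ma == 0L) != (mb == 0L))
  structure(list(
    pair = c(g1, g2),
    sites = data.frame(column = site_cols,
                       state_a = .IUPAC_SYM[ma[site_cols] + 1L],
                       state_b = .IUPAC_SYM[mb[site_cols] + 1L],
                       stringsAsFactors = FALSE),
    indel_sites = indel_cols), class = "diagnostic_sites")
}

#' Collapse identical sequences
#'
#' Groups sequences with identical residue strings under one representative
#' (the first by input order), as done when identical haplotypes are removed
#' before tree building and mapped back afterwards.
#'
#' @param aln A `marker_alignment`.
#' @return List with `alignment` (representatives only, input order) and
#'   `classes`, a named list representative id -> character vector of all
#'   member ids (including the representative).
#' @export
collapse_identical <- function(aln) {
  if (length(aln$seqs) == 0L)
    return(list(alignment = aln, classes = list()))
  key <- unname(aln$seqs)
  first <- !duplicated(key)
  reps <- names(aln$seqs)[first]
  classes <- lapply(which(first), function(i)
    names(aln$seqs)[key == key[i]])
  names(classes) <- reps
  list(alignment = aln_subset(aln, reps), classes = classes)
}

#' Serialize a panel to FASTA + TSV
#'
#' @param panel A `genotype_panel`.
#' @param fasta_path,tsv_path Output paths for consensus sequences and the
#'   label table (label, species, aliases, n_warnings).
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, fasta_path, tsv_path) {
  aln <- marker_alignment(panel$consensus, marker = panel$marker,
                          meta = data.frame(sample_id = panel$labels,
                                            species = unname(panel$species),
                                            genotype = panel$labels,
                                            role = "consensus"))
  write_fasta(aln, fasta_path)
  tab <- data.frame(
    genotype = panel$labels,
    species = unname(panel$species),
    aliases = vapply(panel$labels, function(g)
      paste(panel$aliases[[g]], collapse = ","), character(1)),
    n_warnings = vapply(panel$labels, function(g)
      sum(panel$warnings$genotype == g), integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, tsv_path))
}

#' Read a serialized panel
#'
#' @param fasta_path,tsv_path Paths written by [write_panel()].
#' @param marker Marker name.
#' @return A `genotype_panel`.
#' @export
read_panel <- function(fasta_path, tsv_path, marker = "other") {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  aln <- read_fasta(fasta_path, marker = marker)
  labels <- data.frame(sample_id = tab$genotype, species = tab$species,
                       genotype = tab$genotype, stringsAsFactors = FALSE)
  build_panel(aln, labels)
}
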