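#' Correct polymerase errors in a clone set
#'
#' A clone position is corrected to the direct sequence's base when (i) the
#' clone's state differs from every other clone at that column and (ii) the
#' direct sequence is unambiguous there. Unique substitutions in single
#' clones that do not correspond to polymorphisms in the direct sequence are
#' PCR polymerase artefacts, not template variation; truly polymorphic
#' columns (ambiguous in the direct read, or shared between clones) are
#' never touched.
#'
#' @param clones A `marker_alignment` of clones from one sample.
#' @param direct Residue string of the sample's direct sequence.
#' @return List with `alignment` (corrected clones) and `corrections`, a
#'   data frame `clone_id`, `column` (1-based), `from`, `to`.
#' @export
correct_polymerase_errors <- function(clones, direct) {
  corrections <- data.frame(clone_id = character(0), column = integer(0),
                            from = character(0), to = character(0),
                            stringsAsFactors = FALSE)
  dm <- .mask_string(direct)
  if (length(dm) != clones$length)
    stop("clones and direct sequence differ in length", call. = FALSE)
  if (length(clones$seqs) < 2L) {
    warning("fewer than 2 clones: uniqueness cannot be established, ",
            "no corrections applied")
    return(list(alignment = clones, corrections = corrections))
  }
  m <- aln_mask_matrix(clones)
  n <- nrow(m)
  direct_unamb <- .mask_size(dm) == 1L
  # only columns where the clones disagree can hold unique substitutions
  varies <- colSums(m != matrix(m[1L, ], nrow(m), ncol(m),
                                byrow = TRUE)) > 0L
  for (j in which(direct_unamb & varies)) {
    col <- m[, j]
    tab <- table(col)
    singletons <- as.integer(names(tab)[tab == 1L])
    for (s in setdiff(singletons, dm[j])) {
      i <- which(col == s)
      corrections <- rbind(corrections, data.frame(
        clone_id = rownames(m)[i], column = j,
        from = .IUPAC_SYM[s + 1L], to = .IUPAC_SYM[dm[j] + 1L],
        stringsAsFactors = FALSE))
      m[i, j] <- dm[j]
    }
  }
  seqs <- apply(m, 1L, .string_of_masks)
  out <- marker_alignment(stats::setNames(seqs, rownames(m)),
                          marker = clones$marker, meta = clones$meta)
  list(alignment = out, corrections = corrections)
}

#' Assign clones to parental copy classes
#'
#' Informative columns are those where the two parents carry different
#' unambiguous, non-gap states. Each clone is reduced to a state string over
#' `A`/`B`/`N` (matches parent A, parent B, or neither) at these columns;
#' breakpoint analysis ([detect_breakpoints()]) then separates true parental
#' clones from PCR-mediated recombinants.
#'
#' @param clones A `marker_alignment` of (error-corrected) clones.
#' @param parentA,parentB Residue strings of the two parental consensuses.
#' @param panel Optional `genotype_panel` used to report the nearest
#'   genotype for unassigned clones.
#' @param min_block Minimum informative-site block for recombinant
#'   declaration, see [detect_breakpoints()].
#' @return Data frame `clone_id`, `class` (`parentA`/`parentB`/
#'   `recombinant`/`unassigned`), `state_string`, `distance_to_nearest`,
#'   `nearest`, `breakpoints` (text intervals), `suspect_sites`; attribute
#'   `informative_columns` gives the 1-based alignment columns used.
#' @export
assign_clones <- function(clones, parentA, parentB, panel = NULL,
                          min_block = 2L) {
  am <- .mask_string(parentA)
  bm <- .mask_string(parentB)
  stopifnot(length(am) == clones$length, length(bm) == clones$length)
  info <- which(.mask_size(am) == 1L & .mask_size(bm) == 1L & am != bm)
  if (length(info) == 0L)
    stop("zero informative columns between parents", call. = FALSE)
  m <- aln_mask_matrix(clones)
  res <- lapply(seq_len(nrow(m)), function(i) {
    st <- ifelse(m[i, info] == am[info], "A",
                 ifelse(m[i, info] == bm[info], "B", "N"))
    ss <- paste(st, collapse = "")
    nA <- sum(st == "A"); nB <- sum(st == "B"); nO <- sum(st == "N")
    bp <- detect_breakpoints(ss, min_block = min_block,
                             columns = info)
    if (nO > nA + nB) {
      cls <- "unassigned"
    } else if (isTRUE(attr(bp, "recombinant"))) {
      cls <- "recombinant"
    } else if (nA >= nB) cls <- "parentA" else cls <- "parentB"
    dist_near <- NA_integer_; near <- NA_character_
    if (cls == "unassigned" && !is.null(panel)) {
      d <- vapply(panel$labels, function(g)
        pairwise_substitutions(.string_of_masks(m[i, ]),
                               panel_consensus(panel, g)), integer(1))
      dist_near <- min(d)
      near <- paste(panel$labels[d == dist_near], collapse = ",")
    } else if (cls %in% c("parentA", "parentB")) {
      p <- if (cls == "parentA") am else bm
      dist_near <- sum(m[i, ] != 0L & p != 0L & bitwAnd(m[i, ], p) == 0L)
      near <- cls
    }
    data.frame(clone_id = rownames(m)[i], class = cls, state_string = ss,
               distance_to_nearest = dist_near, nearest = near,
               breakpoints = paste(vapply(bp, function(iv)
                 paste0("(", iv[1], ",", iv[2], ")"), character(1)),
                 collapse = ";"),
               suspect_sites = paste(attr(bp, "suspect_sites"),
                                     collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "informative_columns") <- info
  out
}

#' Detect recombination breakpoints in a clone state string
#'
#' A clone is declared recombinant when its state string over informative
#' sites contains at least two maximal blocks of alternating parent
#' identity, each comprising at least `min_block` informative sites. Runs
#' shorter than `min_block` are reported as suspect sites (more
#' parsimoniously explained as polymerase errors than as crossovers), and
#' adjacent same-parent blocks separated only by suspect runs are merged.
#' Each breakpoint is the open interval between the flanking informative
#' sites of consecutive qualifying blocks.
#'
#' @param state_string String over `A`, `B`, `N` (`N` = uninformative at
#'   that site, skipped).
#' @param min_block Minimum block length (default 2).
#' @param columns Optional 1-based alignment columns of the informative
#'   sites; breakpoint intervals are reported in these coordinates (default:
#'   positions within the state string).
#' @return List of breakpoint intervals `c(left, right)` (open), with
#'   attributes `recombinant` (logical) and `suspect_sites` (positions of
#'   sub-`min_block` runs, in `columns` coordinates).
#' @export
detect_breakpoints <- function(state_string, min_block = 2L,
                               columns = NULL) {
  st <- strsplit(state_string, "", fixed = TRUE)[[1]]
  if (is.null(columns)) columns <- seq_along(st)
  stopifnot(length(columns) == length(st))
  keep <- st %in% c("A", "B")
  sym <- st[keep]
  pos <- columns[keep]
  out <- list()
  suspect <- integer(0)
  if (length(sym) == 0L) {
    attr(out, "recombinant") <- FALSE
    attr(out, "suspect_sites") <- suspect
    return(out)
  }
  r <- rle(sym)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qualifying <- r$lengths >= min_block
  # a short run matching the identity of its flanking qualifying block(s)
  # is absorbed into them; only short runs of conflicting identity are
  # suspect (candidate polymerase errors)
  suspect <- integer(0)
  for (k in which(!qualifying)) {
    left <- which(qualifying[seq_len(k - 1L)])
    right <- which(qualifying[-seq_len(k)]) + k
    neigh <- c(if (length(left)) r$values[max(left)],
               if (length(right)) r$values[min(right)])
    if (length(neigh) == 0L || any(neigh != r$values[k])) {
      suspect <- c(suspect, pos[starts[k]:ends[k]])
    }
  }
  qs <- which(qualifying)
  # merge consecutive qualifying blocks of the same identity
  if (length(qs)) {
    ident <- r$values[qs]
    blk_start <- starts[qs]; blk_end <- ends[qs]
    merged <- list(c(blk_start[1], blk_end[1], ident[1]))
    for (k in seq_along(qs)[-1]) {
      last <- merged[[length(merged)]]
      if (ident[k] == last[3]) {
        merged[[length(merged)]] <- c(last[1], blk_end[k], ident[k])
      } else {
        merged <- c(merged, list(c(blk_start[k], blk_end[k], ident[k])))
      }
    }
    if (length(merged) >= 2L) {
      for (k in seq_len(length(merged) - 1L)) {
        left <- pos[as.integer(merged[[k]][2])]
        right <- pos[as.integer(merged[[k + 1L]][1])]
        out <- c(out, list(c(left, right)))
      }
    }
    attr(out, "recombinant") <- length(merged) >= 2L
  } else {
    attr(out, "recombinant") <- FALSE
  }
  attr(out, "suspect_sites") <- suspect
  out
}

#' Choose representative clones per parent class
#'
#' One representative clone per parent (first by id when all members are
#' identical); when a parent class contains two sequence variants, one clone
#' per variant is chosen (at most two, the two most frequent variants).
#' Recombinant clones are never chosen.
#'
#' @param assignments Data frame from [assign_clones()].
#' @param clones The (corrected) clone `marker_alignment`.
#' @return Named list `parentA`, `parentB` of clone-id vectors (length 0-2).
#' @export
choose_representatives <- function(assignments, clones) {
  pick <- function(cls) {
    ids <- assignments$clone_id[assignments$class == cls]
    if (length(ids) == 0L) return(character(0))
    variants <- split(ids, unname(clones$seqs[ids]))
    variants <- variants[order(-lengths(variants),
                               vapply(variants, `[[`, character(1), 1L))]
    vapply(variants[seq_len(min(2L, length(variants)))],
           function(v) sort(v)[1], character(1), USE.NAMES = FALSE)
  }
  list(parentA = pick("parentA"), parentB = pick("parentB"))
}

#' Infer a missing parental copy by peak subtraction
#'
#' When only one parent is recovered among the clones (the other represented
#' only by recombinants, or not at all), the second copy is inferred by
#' subtracting the recovered parent from the sample's direct sequence. The
#' result is tagged inferred, not observed.
#'
#' @param direct Residue string of the direct sequence.
#' @param recovered Residue string of the recovered parental copy.
#' @return As [peak_subtract()], with attribute `inferred = TRUE`.
#' @export
infer_missing_parent <- function(direct, recovered) {
  out <- peak_subtract(direct, recovered)
  attr(out, "inferred") <- TRUE
  out
}

# complete-linkage clustering of clones at distance <= cutoff; the two
# largest clusters are taken as putative parents (de novo mode)
.denovo_parents <- function(clones, cutoff = 1L) {
  n <- length(clones$seqs)
  if (n < 2L) stop("need >= 2 clones for de novo parent recovery",
                   call. = FALSE)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- pairwise_substitutions(clones$seqs[[i]],
                                                 clones$seqs[[j]])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, h = cutoff)
  sizes <- sort(table(cl), decreasing = TRUE)
  if (length(sizes) < 2L)
    stop("clones form a single cluster at distance <= ", cutoff,
         call. = FALSE)
  top <- as.integer(names(sizes)[1:2])
  cons <- function(k) {
    ids <- names(clones$seqs)[cl == k]
    .column_consensus(aln_mask_matrix(aln_subset(clones, ids)))$consensus
  }
  list(parentA = cons(top[1]), parentB = cons(top[2]))
}

#' Analyze the clone set of one sample
#'
#' Full clone workflow: polymerase-error correction against the direct
#' sequence, assignment of clones to parental copy classes, recombinant
#' detection, representative choice, and — when one copy class is missing —
#' inference of the second parent by peak subtraction. When no parental
#' references are given, clones are clustered de novo (complete linkage at
#' substitution distance <= 1) and the two largest clusters taken as
#' putative parents.
#'
#' @param clones A `marker_alignment` of clones from one sample.
#' @param direct Residue string of the sample's direct sequence.
#' @param parentA,parentB Optional parental consensus strings (e.g. panel
#'   genotypes from [classify_direct()]'s hypothesis).
#' @param panel Optional panel for nearest-genotype reporting.
#' @param sample_id Sample id for the report.
#' @param min_block Passed to [detect_breakpoints()].
#' @return An object of class `clone_report`: `sample_id`, `assignments`,
#'   `corrections`, `representatives`, `parents_recovered`,
#'   `inferred_parent` (residue string or `NA`), `corrected` (the corrected
#'   clone alignment).
#' @export
analyze_clones <- function(clones, direct, parentA = NULL, parentB = NULL,
                           panel = NULL, sample_id = "sample",
                           min_block = 2L) {
  if (is.null(parentA) || is.null(parentB)) {
    de <- .denovo_parents(clones)
    parentA <- de$parentA
    parentB <- de$parentB
  }
  corr <- correct_polymerase_errors(clones, direct)
  asg <- assign_clones(corr$alignment, parentA, parentB, panel = panel,
                       min_block = min_block)
  reps <- choose_representatives(asg, corr$alignment)
  haveA <- length(reps$parentA) > 0L
  haveB <- length(reps$parentB) > 0L
  inferred <- NA_character_
  inferred_for <- NA_character_
  if (xor(haveA, haveB)) {
    recovered_id <- if (haveA) reps$parentA[1] else reps$parentB[1]
    inferred <- tryCatch(
      infer_missing_parent(direct, corr$alignment$seqs[[recovered_id]]),
      error = function(e) NA_character_)
    inferred_for <- if (haveA) "parentB" else "parentA"
  }
  structure(list(
    sample_id = sample_id, assignments = asg,
    corrections = corr$corrections, representatives = reps,
    parents_recovered = (haveA && haveB) ||
      (xor(haveA, haveB) && !is.na(inferred)),
    inferred_parent = inferred, inferred_for = inferred_for,
    corrected = corr$alignment), class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat("clone_report:", x$sample_id, "-",
      nrow(x$assignments), "clones;",
      sum(x$assignments$class == "recombinant"), "recombinant;",
      nrow(x$corrections), "corrections; parents recovered:",
      x$parents_recovered, "\n")
  invisible(x)
}
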