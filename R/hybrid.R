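#' Expected direct sequence under a genotype hypothesis
#'
#' For a single genotype the expectation is its consensus; for a pair it is
#' the column-wise IUPAC merge of the two consensuses — the superposition a
#' direct read of a hybrid would show. Columns where exactly one parent is
#' gapped cannot be expressed in IUPAC; they are marked indel-additive and
#' excluded from base matching.
#'
#' @param panel A `genotype_panel`.
#' @param hypothesis A single genotype label or a character vector of two.
#' @return Residue string with attribute `indel_additive`, the 1-based
#'   columns where exactly one parent carries a gap (such columns hold the
#'   non-gap parent's state in the returned string, flagged rather than
#'   merged).
#' @export
expected_sequence <- function(panel, hypothesis) {
  hypothesis <- as.character(hypothesis)
  if (length(hypothesis) == 1L) {
    out <- panel_consensus(panel, hypothesis)
    attr(out, "indel_additive") <- integer(0)
    return(out)
  }
  stopifnot(length(hypothesis) == 2L)
  ma <- .mask_string(panel_consensus(panel, hypothesis[1]))
  mb <- .mask_string(panel_consensus(panel, hypothesis[2]))
  indel <- which((ma == 0L) != (mb == 0L))
  merged <- bitwOr(ma, mb)
  merged[ma == 0L & mb == 0L] <- 0L
  out <- .string_of_masks(merged)
  attr(out, "indel_additive") <- indel
  out
}

# demote ambiguities whose minor-peak fraction is below threshold to the
# panel's modal unambiguous state at that column (the major sequence)
.demote_minor_signals <- function(qmask, minor_fraction, panel_masks,
                                  min_minor_fraction) {
  if (is.null(minor_fraction) || min_minor_fraction <= 0) return(qmask)
  pos <- as.integer(names(minor_fraction))
  for (k in seq_along(pos)) {
    j <- pos[k]
    if (j < 1L || j > length(qmask)) next
    if (.mask_size(qmask[j]) < 2L) next
    if (minor_fraction[k] >= min_minor_fraction) next
    col <- panel_masks[, j]
    u <- col[.mask_size(col) == 1L]
    u <- u[bitwAnd(u, qmask[j]) != 0L]
    if (length(u) == 0L) next
    major <- as.integer(names(sort(table(u), decreasing = TRUE))[1])
    qmask[j] <- major
  }
  qmask
}

#' Classify a direct sequence against a genotype panel
#'
#' Scores every single-genotype and every unordered-pair hypothesis. A
#' diagnostic column (a column at which some panel pair differs by
#' unambiguous disjoint states) matches a hypothesis when the query's IUPAC
#' base set equals the expected set exactly — a hybrid must show the full
#' additive ambiguity, a plain parental base at an additive site counts as a
#' violation. The hypothesis score is its number of violated diagnostic
#' sites; the best hypothesis must score at most `tolerance`, otherwise the
#' verdict is `novel`. At equal qualifying score a single genotype is
#' preferred over a pair (parsimony); ties among pairs give verdict
#' `ambiguous` with all tied pairs listed. Ambiguities at non-diagnostic
#' columns are reported as extra polymorphic sites and never penalized.
#'
#' When per-site minor-signal fractions are available for the sample,
#' ambiguities whose minor peak is below `min_minor_fraction` are demoted to
#' the major state before classification (small extra peaks are ignored and
#' only the major sequence is interpreted).
#'
#' @param query An id present in `aln`, or a residue string; alternatively
#'   pass a one-sequence `marker_alignment`.
#' @param panel A `genotype_panel` of the same marker/length.
#' @param tolerance Maximum violated diagnostic sites for a call (default 0;
#'   1 can absorb one miscalled Sanger peak).
#' @param min_minor_fraction Demotion threshold for minor peaks (default
#'   0.30).
#' @param minor_fraction Optional named numeric vector (names = 1-based
#'   positions) of minor-peak fractions for this sample.
#' @param sample_id Sample id used in the report.
#' @return An object of class `additivity_call`: `sample_id`, `verdict`
#'   (`pure`, `intraspecific_hybrid`, `interspecific_hybrid`, `novel`,
#'   `ambiguous`), `hypothesis` (label or pair), `score`, `violated_sites`,
#'   `explained_sites` (data frames column/observed/expected),
#'   `extra_polymorphic_sites`, `indel_polymorphic_sites`,
#'   `tied_hypotheses`.
#' @export
classify_direct <- function(query, panel, tolerance = 0L,
                            min_minor_fraction = 0.30,
                            minor_fraction = NULL, sample_id = NULL) {
  if (inherits(query, "marker_alignment")) {
    stopifnot(length(query$seqs) == 1L)
    sample_id <- names(query$seqs)
    minor_fraction <- query$minor_fraction[[sample_id]]
    query <- query$seqs[[1]]
  }
  if (is.null(sample_id)) sample_id <- "query"
  if (length(panel$labels) == 0L) stop("empty panel", call. = FALSE)
  qmask <- .mask_string(query)
  if (length(qmask) != panel$length)
    stop("length mismatch: query ", length(qmask), " vs panel ",
         panel$length, call. = FALSE)

  pm <- do.call(rbind, lapply(panel$consensus, .mask_string))
  qmask <- .demote_minor_signals(qmask, minor_fraction, pm,
                                 min_minor_fraction)

  D <- panel$diagnostic_columns
  q_missing <- qmask == 0L | qmask == 15L # gap or N: no evidence either way

  G <- panel$labels
  hyps <- c(as.list(G), if (length(G) > 1L) utils::combn(G, 2L, simplify = FALSE))
  score <- integer(length(hyps))
  viol <- vector("list", length(hyps))
  indel_cols <- vector("list", length(hyps))
  exp_mask <- vector("list", length(hyps))
  for (i in seq_along(hyps)) {
    e <- expected_sequence(panel, hyps[[i]])
    em <- .mask_string(e)
    ia <- attr(e, "indel_additive")
    usable <- !q_missing & em != 0L & em != 15L
    usable[ia] <- FALSE
    v <- intersect(D[usable[D]], which(qmask != em))
    score[i] <- length(v)
    viol[[i]] <- v
    indel_cols[[i]] <- ia
    exp_mask[[i]] <- em
  }

  best <- min(score)
  is_pair <- lengths(hyps) == 2L
  q_ambig <- which(.mask_size(qmask) >= 2L & qmask != 15L)
  extra <- setdiff(q_ambig, D)

  if (best > tolerance) {
    return(.additivity_call(sample_id, "novel", NA_character_,
                            best, viol[[which.min(score)]], qmask,
                            exp_mask[[which.min(score)]], extra,
                            integer(0), list(),
                            nearest = hyps[[which.min(score)]]))
  }
  qualifying <- which(score <= tolerance)
  pure_q <- qualifying[!is_pair[qualifying]]
  if (length(pure_q)) {
    # parsimony: prefer single genotypes; break ties among pures by score
    i <- pure_q[which.min(score[pure_q])]
    tied <- pure_q[score[pure_q] == score[i]]
    if (length(tied) > 1L) {
      return(.additivity_call(sample_id, "ambiguous", NA_character_,
                              score[i], viol[[i]], qmask, exp_mask[[i]],
                              extra, integer(0), hyps[tied]))
    }
    return(.additivity_call(sample_id, "pure", hyps[[i]], score[i],
                            viol[[i]], qmask, exp_mask[[i]], extra,
                            integer(0), list()))
  }
  pair_q <- qualifying[is_pair[qualifying]]
  i <- pair_q[which.min(score[pair_q])]
  tied <- pair_q[score[pair_q] == score[i]]
  if (length(tied) > 1L) {
    return(.additivity_call(sample_id, "ambiguous", NA_character_, score[i],
                            viol[[i]], qmask, exp_mask[[i]], extra,
                            indel_cols[[i]], hyps[tied]))
  }
  pair <- hyps[[i]]
  sp <- panel$species[pair]
  verdict <- if (sp[1] == sp[2]) "intraspecific_hybrid" else
    "interspecific_hybrid"
  .additivity_call(sample_id, verdict, pair, score[i], viol[[i]], qmask,
                   exp_mask[[i]], extra, indel_cols[[i]], list())
}

.additivity_call <- function(sample_id, verdict, hypothesis, score,
                             violated, qmask, emask, extra, indel_cols,
                             tied, nearest = NULL) {
  site_df <- function(cols) data.frame(
    column = cols,
    observed = .IUPAC_SYM[qmask[cols] + 1L],
    expected = .IUPAC_SYM[emask[cols] + 1L],
    stringsAsFactors = FALSE)
  explained <- integer(0)
  if (verdict %in% c("pure", "intraspecific_hybrid", "interspecific_hybrid")) {
    D_match <- which(qmask == emask & .mask_size(qmask) >= 2L & qmask != 15L)
    explained <- D_match
  }
  structure(list(
    sample_id = sample_id, verdict = verdict,
    hypothesis = if (is.null(hypothesis) || all(is.na(hypothesis)))
      NA_character_ else as.character(hypothesis),
    score = score,
    violated_sites = site_df(violated),
    explained_sites = site_df(explained),
    extra_polymorphic_sites = extra,
    indel_polymorphic_sites = as.integer(indel_cols),
    tied_hypotheses = tied,
    nearest_hypothesis = if (is.null(nearest)) NA_character_ else
      as.character(nearest)),
    class = "additivity_call")
}

#' @export
print.additivity_call <- function(x, ...) {
  hyp <- if (all(is.na(x$hypothesis))) "-" else
    paste(x$hypothesis, collapse = " x ")
  cat(sprintf("%s: %s [%s] violated=%d extra=%d\n", x$sample_id, x$verdict,
              hyp, nrow(x$violated_sites),
              length(x$extra_polymorphic_sites)))
  invisible(x)
}

#' Classify every direct sequence of an alignment
#'
#' @param aln A `marker_alignment`; sequences with role `direct` are
#'   classified.
#' @inheritParams classify_direct
#' @return Named list of `additivity_call` objects.
#' @export
classify_alignment <- function(aln, panel, tolerance = 0L,
                               min_minor_fraction = 0.30) {
  ids <- aln$meta$sample_id[aln$meta$role == "direct"]
  calls <- lapply(ids, function(id)
    classify_direct(aln$seqs[[id]], panel, tolerance = tolerance,
                    min_minor_fraction = min_minor_fraction,
                    minor_fraction = aln$minor_fraction[[id]],
                    sample_id = id))
  stats::setNames(calls, ids)
}

#' Tabulate additivity calls
#'
#' @param calls List of `additivity_call` objects.
#' @return Data frame with one row per call (columns `sample_id`, `verdict`,
#'   `hypothesis`, `n_violated`, `n_extra`, `tied`, `indel_sites`).
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) data.frame(
    sample_id = x$sample_id, verdict = x$verdict,
    hypothesis = if (all(is.na(x$hypothesis))) "" else
      paste(sort(x$hypothesis), collapse = "+"),
    n_violated = nrow(x$violated_sites),
    n_extra = length(x$extra_polymorphic_sites),
    tied = paste(vapply(x$tied_hypotheses, paste, character(1),
                        collapse = "+"), collapse = ";"),
    indel_sites = paste(x$indel_polymorphic_sites, collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Infer the second parental copy by peak subtraction
#'
#' Per column: where the query is ambiguous and the known parent's base set
#' is contained in the query's, the parent's set is subtracted; where the
#' query is unambiguous, the query base is kept (both copies agree).
#' Columns where subtraction still leaves more than one base remain
#' ambiguous and are flagged.
#'
#' @param query Residue string of the direct sequence.
#' @param parent Residue string of the known parental copy.
#' @return Residue string of the inferred second copy, with attribute
#'   `still_ambiguous` (1-based columns left ambiguous).
#' @export
peak_subtract <- function(query, parent) {
  qm <- .mask_string(query)
  pm <- .mask_string(parent)
  if (length(qm) != length(pm))
    stop("length mismatch", call. = FALSE)
  # check compatibility where both carry bases
  both <- qm != 0L & pm != 0L
  incompat <- which(both & bitwAnd(qm, pm) == 0L)
  if (length(incompat))
    stop("parent base absent from query ambiguity set at column(s) ",
         paste(incompat, collapse = ", "), call. = FALSE)
  out <- qm
  sub_cols <- which(.mask_size(qm) >= 2L & qm != 15L & pm != 0L &
                      bitwAnd(qm, pm) == pm) # N columns stay missing data
  diff <- bitwAnd(qm[sub_cols], bitwXor(15L, pm[sub_cols]))
  keep_parent <- diff == 0L
  diff[keep_parent] <- pm[sub_cols][keep_parent]
  out[sub_cols] <- diff
  flagged <- which(.mask_size(out) >= 2L & out != 15L)
  res <- .string_of_masks(out)
  attr(res, "still_ambiguous") <- flagged
  res
}

#' Select sequences for phylogenetic analysis
#'
#' Retains pure-verdict samples and drops hybrid, ambiguous and novel direct
#' sequences; clone or allele sequences explicitly marked as representing a
#' unique genotype are kept even when their sample's direct sequence is a
#' hybrid. Every exclusion is logged with a reason — no silent drops.
#'
#' @param calls List of `additivity_call` (one per direct sequence).
#' @param aln The `marker_alignment` the calls refer to.
#' @param unique_clones Character vector of sequence ids (role `clone`)
#'   carrying panel-absent, unique genotypes to retain.
#' @return List with `alignment` (retained sequences) and `log`, a data
#'   frame `sample_id`, `action` (`kept`/`excluded`), `reason`.
#' @export
select_for_phylogeny <- function(calls, aln, unique_clones = character(0)) {
  log <- data.frame(sample_id = character(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  keep <- character(0)
  for (id in names(aln$seqs)) {
    role <- aln$meta$role[aln$meta$sample_id == id]
    if (role == "clone") {
      if (id %in% unique_clones) {
        keep <- c(keep, id)
        log <- rbind(log, data.frame(sample_id = id, action = "kept",
                                     reason = "unique-genotype clone"))
      } else {
        log <- rbind(log, data.frame(sample_id = id, action = "excluded",
                                     reason = "clone (not unique-genotype)"))
      }
      next
    }
    call <- calls[[id]]
    if (is.null(call)) stop("no call for sequence ", id, call. = FALSE)
    if (call$verdict == "pure") {
      keep <- c(keep, id)
      log <- rbind(log, data.frame(sample_id = id, action = "kept",
                                   reason = "pure genotype"))
    } else {
      log <- rbind(log, data.frame(sample_id = id, action = "excluded",
                                   reason = call$verdict))
    }
  }
  list(alignment = aln_subset(aln, keep), log = log)
}
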