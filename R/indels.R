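# maximal gap runs of one mask vector as a matrix of (start, end),
# half-open 0-based [start, end)
.gap_runs <- function(mask) {
  r <- rle(mask == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel coding of an alignment
#'
#' Implements the simple indel-coding method: every distinct maximal gap run
#' (identical start and end columns) in the alignment becomes one additional
#' presence/absence character. Per sequence the character is `C` (present)
#' when the sequence has a gap exactly spanning the range, `N`
#' (inapplicable/missing) when one of its own gap runs strictly contains the
#' range or the range lies inside its leading/trailing missing data, and `A`
#' (absent) otherwise — partially overlapping gaps of different coordinates
#' code `A` for each other's characters. Leading and trailing gap runs are
#' ragged sequencing ends, treated as missing data and never as indel
#' events.
#'
#' @param aln A `marker_alignment`.
#' @return An object of class `indel_matrix`: `gap_ranges` (data frame
#'   `start`, `end`, half-open 0-based, sorted), `codes` (named character
#'   vector of `A`/`C`/`N` strings, one position per range), `provenance`
#'   (list range index -> ids exhibiting the run).
#' @export
simple_indel_code <- function(aln) {
  n <- length(aln$seqs)
  L <- aln$length
  masks <- lapply(aln$seqs, .mask_string)
  runs <- lapply(masks, .gap_runs)
  # terminal runs (touching column 1 or L) are missing data, not events
  internal <- lapply(runs, function(r)
    r[r[, "start"] > 0L & r[, "end"] < L, , drop = FALSE])
  terminal <- lapply(runs, function(r)
    r[r[, "start"] == 0L | r[, "end"] == L, , drop = FALSE])
  all_ranges <- unique(do.call(rbind, c(internal,
                                        list(cbind(start = integer(0),
                                                   end = integer(0))))))
  if (nrow(all_ranges)) {
    all_ranges <- all_ranges[order(all_ranges[, "start"],
                                   all_ranges[, "end"]), , drop = FALSE]
  }
  K <- nrow(all_ranges)
  codes <- matrix("A", nrow = n, ncol = K)
  provenance <- vector("list", K)
  for (i in seq_len(n)) {
    own <- internal[[i]]
    term <- terminal[[i]]
    for (k in seq_len(K)) {
      s <- all_ranges[k, "start"]; e <- all_ranges[k, "end"]
      exact <- any(own[, "start"] == s & own[, "end"] == e)
      if (exact) {
        codes[i, k] <- "C"
        provenance[[k]] <- c(provenance[[k]], names(aln$seqs)[i])
      } else if (any(own[, "start"] <= s & own[, "end"] >= e &
                       (own[, "start"] < s | own[, "end"] > e))) {
        codes[i, k] <- "N" # strictly containing gap
      } else if (nrow(term) &&
                 any(term[, "start"] <= s & term[, "end"] >= e)) {
        codes[i, k] <- "N" # inside leading/trailing missing data
      }
    }
  }
  structure(list(
    gap_ranges = as.data.frame(all_ranges),
    codes = stats::setNames(apply(codes, 1L, paste, collapse = ""),
                            names(aln$seqs)),
    provenance = provenance), class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat("indel_matrix:", nrow(x$gap_ranges), "coded indel character(s),",
      length(x$codes), "sequences\n")
  invisible(x)
}

#' Concatenate indel characters to an alignment
#'
#' Appends each sequence's `A`/`C`/`N` indel code string to its residues, as
#' done before likelihood analyses; the boundary between residue and indel
#' blocks is recorded for partitioning.
#'
#' @param aln A `marker_alignment`.
#' @param m An `indel_matrix` from [simple_indel_code()] on the same ids.
#' @return A `marker_alignment` of length `aln$length + n_characters`, with
#'   attribute `indel_block` = `c(first, last)` 1-based columns of the
#'   appended block (or `NULL` when the matrix is empty).
#' @export
concatenate_with_indels <- function(aln, m) {
  if (!setequal(names(aln$seqs), names(m$codes)))
    stop("sequence ids of alignment and indel matrix differ",
         call. = FALSE)
  K <- nrow(m$gap_ranges)
  if (K == 0L) return(aln)
  seqs <- paste0(aln$seqs, m$codes[names(aln$seqs)])
  out <- marker_alignment(stats::setNames(seqs, names(aln$seqs)),
                          marker = aln$marker, meta = aln$meta)
  attr(out, "indel_block") <- c(aln$length + 1L, aln$length + K)
  out
}

#' Concatenate several marker alignments by sample id
#'
#' Markers are joined in the given order; a sample absent from a marker gets
#' a run of `missing_fill` of that marker's length (a region that did not
#' amplify is missing data, not a gap). Partition boundaries are recorded.
#'
#' @param alns Non-empty list of `marker_alignment`s.
#' @param missing_fill Fill symbol for absent markers (default `"N"`).
#' @return A `marker_alignment` (marker `"other"`) with attribute
#'   `partitions`, a data frame `marker`, `first`, `last` (1-based columns).
#' @export
concatenate_markers <- function(alns, missing_fill = "N") {
  if (length(alns) == 0L) stop("empty marker list", call. = FALSE)
  ids <- unique(unlist(lapply(alns, function(a) names(a$seqs))))
  if (length(ids) == 0L) stop("no samples in any marker", call. = FALSE)
  parts <- data.frame(marker = character(0), first = integer(0),
                      last = integer(0), stringsAsFactors = FALSE)
  seqs <- stats::setNames(rep("", length(ids)), ids)
  offset <- 0L
  for (a in alns) {
    fill <- strrep(missing_fill, a$length)
    piece <- stats::setNames(rep(fill, length(ids)), ids)
    present <- intersect(ids, names(a$seqs))
    piece[present] <- unname(a$seqs[present])
    seqs <- paste0(seqs, piece)
    names(seqs) <- ids
    parts <- rbind(parts, data.frame(marker = a$marker,
                                     first = offset + 1L,
                                     last = offset + a$length,
                                     stringsAsFactors = FALSE))
    offset <- offset + a$length
  }
  out <- marker_alignment(seqs, marker = "other")
  attr(out, "partitions") <- parts
  out
}

#' Export an alignment as a NEXUS matrix
#'
#' Writes a DATA block (`datatype=DNA`, `gap=-`, `missing=N`) through
#' \pkg{ape}, plus a SETS block with one charset per partition. Labels
#' containing whitespace are quoted. Indel code characters (`A`/`C`/`N`)
#' are valid under the DNA datatype, matching how coded indel matrices are
#' concatenated for likelihood software.
#'
#' @param aln A `marker_alignment` (possibly with `partitions` /
#'   `indel_block` attributes, which are exported as charsets).
#' @param path Output path.
#' @param partitions Optional data frame `marker`, `first`, `last`
#'   overriding the alignment's `partitions` attribute.
#' @return `path`, invisibly.
#' @export
export_nexus <- function(aln, path, partitions = NULL) {
  if (is.null(partitions)) partitions <- attr(aln, "partitions")
  ib <- attr(aln, "indel_block")
  labels <- names(aln$seqs)
  quoted <- grepl("\\s", labels)
  labels[quoted] <- paste0("'", labels[quoted], "'")
  x <- stats::setNames(strsplit(unname(aln$seqs), "", fixed = TRUE), labels)
  ape::write.nexus.data(x, file = path, format = "dna",
                        interleaved = FALSE, gap = "-", missing = "N")
  # drop the writer's timestamp comment so identical inputs give
  # byte-identical artifacts
  lines <- readLines(path)
  writeLines(lines[!grepl("^\\[Data written by", lines)], path)
  sets <- character(0)
  if (!is.null(partitions) && nrow(partitions)) {
    sets <- c(sets, sprintf("\tcharset %s = %d-%d;",
                            gsub("[^A-Za-z0-9_]", "_", partitions$marker),
                            partitions$first, partitions$last))
  }
  if (!is.null(ib)) {
    sets <- c(sets, sprintf("\tcharset indels = %d-%d;", ib[1], ib[2]))
  }
  if (length(sets)) {
    cat("BEGIN SETS;\n", paste(sets, collapse = "\n"), "\nEND;\n",
        sep = "", file = path, append = TRUE)
  }
  invisible(path)
}

#' Export an alignment in relaxed PHYLIP format
#'
#' @param aln A `marker_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln$seqs), aln$length), con)
  writeLines(sprintf("%s  %s", gsub("\\s", "_", names(aln$seqs)),
                     unname(aln$seqs)), con)
  invisible(path)
}
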