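.MARKERS <- c("ITS", "5S-NTS", "rpl20-rps12", "trnT-trnL", "other")
.ROLES <- c("direct", "clone", "consensus")

#' Construct a marker alignment
#'
#' The central container: a set of equal-length, pre-aligned sequences of one
#' marker, with per-sequence metadata (species, genotype, role) and optional
#' per-site minor-signal fractions emulating electropherogram peak ratios.
#'
#' @param seqs Named character vector of residue strings (names = sample ids).
#' @param marker One of `"ITS"`, `"5S-NTS"`, `"rpl20-rps12"`, `"trnT-trnL"`,
#'   `"other"`.
#' @param meta Optional data frame with columns `sample_id`, `species`,
#'   `genotype`, `role`; missing rows default to species `"unknown"`, role
#'   `"direct"`.
#' @param minor_fraction Optional named list (by sample id) of numeric vectors
#'   named by 1-based position, giving the minor-peak fraction at ambiguous
#'   sites.
#' @return An object of class `marker_alignment`.
#' @export
marker_alignment <- function(seqs, marker = "other", meta = NULL,
                             minor_fraction = NULL) {
  marker <- match.arg(marker, .MARKERS)
  ids <- names(seqs)
  if (is.null(ids)) {
    if (length(seqs) > 0L)
      stop("sequences must be named by sample id", call. = FALSE)
    ids <- character(0)
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  lens <- nchar(seqs)
  if (length(seqs) > 0L && length(unique(lens)) > 1L) {
    stop("alignment-length error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  # validate symbols, reporting record and 1-based column
  for (i in seq_along(seqs)) {
    m <- .IUPAC_MASK[strsplit(seqs[[i]], "", fixed = TRUE)[[1]]]
    if (anyNA(m)) {
      stop("parse error: illegal symbol in record '", ids[i],
           "' at column ", which(is.na(m))[1], call. = FALSE)
    }
  }
  meta <- .normalize_meta(meta, ids)
  structure(
    list(marker = marker, seqs = seqs, meta = meta,
         minor_fraction = minor_fraction,
         length = if (length(seqs)) unname(lens[1]) else 0L),
    class = "marker_alignment"
  )
}

.normalize_meta <- function(meta, ids) {
  out <- data.frame(sample_id = ids,
                    species = rep_len("unknown", length(ids)),
                    genotype = rep_len(NA_character_, length(ids)),
                    role = rep_len("direct", length(ids)),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    stopifnot("sample_id" %in% names(meta))
    idx <- match(ids, meta$sample_id)
    for (col in c("species", "genotype", "role")) {
      if (col %in% names(meta)) {
        val <- meta[[col]][idx]
        keep <- !is.na(idx) & !is.na(val) & val != ""
        out[[col]][keep] <- val[keep]
      }
    }
    bad <- setdiff(out$role, .ROLES)
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  out
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("marker_alignment:", x$marker, "-", length(x$seqs), "sequences x",
      x$length, "columns\n")
  invisible(x)
}

#' @export
length.marker_alignment <- function(x) length(x$seqs)

# residues as character matrix (rows = sequences)
aln_char_matrix <- function(aln) {
  if (length(aln$seqs) == 0L)
    return(matrix(character(0), nrow = 0, ncol = aln$length))
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

# residues as integer mask matrix
aln_mask_matrix <- function(aln) .mask_matrix(aln_char_matrix(aln))

# subset an alignment by sequence ids (keeps metadata rows)
aln_subset <- function(aln, ids) {
  marker_alignment(aln$seqs[ids], marker = aln$marker,
                   meta = aln$meta[match(ids, aln$meta$sample_id), ,
                                   drop = FALSE],
                   minor_fraction = aln$minor_fraction[
                     intersect(names(aln$minor_fraction), ids)])
}

#' Read an aligned FASTA file
#'
#' Residues are uppercased and `U` is mapped to `T` on ingest; any symbol
#' outside the 16-letter IUPAC+gap alphabet is a parse error naming the
#' record and column. All records must have identical length (the input is
#' expected to be pre-aligned).
#'
#' @param path Path to a (multi-)FASTA file.
#' @param marker Marker name, see [marker_alignment()].
#' @param metadata Optional metadata data frame or path to a TSV with columns
#'   `sample_id`, `species`, `genotype`, `marker`, `role`; when given, every
#'   FASTA id must appear in it.
#' @return A `marker_alignment`.
#' @export
read_fasta <- function(path, marker = "other", metadata = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss)) # id = first token
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  if (!is.null(metadata)) {
    missing <- setdiff(names(seqs), metadata$sample_id)
    if (length(missing))
      stop("FASTA ids absent from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if ("marker" %in% names(metadata))
      metadata <- metadata[is.na(metadata$marker) |
                             metadata$marker == marker, , drop = FALSE]
  }
  marker_alignment(seqs, marker = marker, meta = metadata)
}

#' Write an alignment to FASTA
#'
#' Residues are written verbatim (gaps preserved); a FASTA round-trip
#' reproduces ids and residues exactly. An empty alignment yields an empty
#' file.
#'
#' @param aln A `marker_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  if (length(aln$seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `species`, `genotype`, `marker`,
#'   `role` (extra columns are kept).
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
}

#' Read per-site minor-signal fractions
#'
#' @param path TSV with columns `sample_id`, `position` (1-based), `fraction`.
#' @return Named list by sample id of numeric vectors named by position.
#' @export
read_minor_fractions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "position", "fraction") %in% names(df)))
  if (any(df$fraction < 0 | df$fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  lapply(split(df, df$sample_id), function(d) {
    stats::setNames(d$fraction, d$position)
  })
}

#' Trim uninformative alignment ends
#'
#' Removes leading and trailing columns whose fraction of missing residues
#' (`N` or gap) exceeds `max_missing_frac`. Internal columns are never
#' touched. Direct Sanger reads have ragged, N-padded or truncated ends;
#' trimming avoids overestimating variation from those regions.
#'
#' @param aln A `marker_alignment`.
#' @param max_missing_frac Threshold in `[0, 1]`; a terminal column is
#'   dropped while its missing fraction exceeds this value.
#' @return A list with `alignment` (trimmed) and `kept_columns`, the 1-based
#'   original column indices retained (the column-offset map).
#' @export
trim_uninformative_ends <- function(aln, max_missing_frac = 0.5) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  n <- length(aln$seqs)
  if (n == 0L || aln$length == 0L)
    return(list(alignment = aln, kept_columns = integer(0)))
  m <- aln_char_matrix(aln)
  missing_frac <- colMeans(m == "N" | m == "-")
  bad <- missing_frac > max_missing_frac
  first <- 1L
  while (first <= aln$length && bad[first]) first <- first + 1L
  last <- aln$length
  while (last >= first && bad[last]) last <- last - 1L
  kept <- if (first > last) integer(0) else first:last
  seqs <- vapply(aln$seqs, function(s)
    if (length(kept)) substr(s, first, last) else "", character(1))
  out <- marker_alignment(seqs, marker = aln$marker, meta = aln$meta,
                          minor_fraction = aln$minor_fraction)
  list(alignment = out, kept_columns = kept)
}
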