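# Independent IUPAC base-set table used as the enumeration oracle.
# Written out literally (not derived from package internals).
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# symbol whose base set equals `bases` (oracle-side lookup by set equality)
oracle_symbol <- function(bases) {
  for (s in names(ORACLE_SETS)) {
    if (setequal(ORACLE_SETS[[s]], bases)) return(s)
  }
  stop("no symbol for base set ", paste(bases, collapse = ""))
}

# a small alignment from residue strings
make_aln <- function(seqs, marker = "other", meta = NULL, ...) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%d", seq_along(seqs))
  marker_alignment(seqs, marker = marker, meta = meta, ...)
}

# panel from labelled residue strings: names are "species|genotype"
make_panel <- function(seqs, marker = "other") {
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  meta <- data.frame(
    sample_id = vapply(parts, `[[`, character(1), 2L),
    species = vapply(parts, `[[`, character(1), 1L),
    genotype = vapply(parts, `[[`, character(1), 2L),
    role = "consensus", stringsAsFactors = FALSE)
  names(seqs) <- meta$sample_id
  build_panel(make_aln(seqs, marker = marker, meta = meta))
}

# brute-force simple indel coding oracle: scans each sequence for gap runs
# character by character, then applies the three-state rule per range
oracle_indel_code <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  L <- length(chars[[1]])
  runs_of <- function(v) {
    out <- list()
    j <- 1L
    while (j <= L) {
      if (v[j] == "-") {
        k <- j
        while (k < L && v[k + 1L] == "-") k <- k + 1L
        out <- c(out, list(c(j, k))) # 1-based inclusive
        j <- k + 1L
      } else j <- j + 1L
    }
    out
  }
  all_runs <- lapply(chars, runs_of)
  internal <- lapply(all_runs, function(rs)
    Filter(function(r) r[1] > 1L && r[2] < L, rs))
  terminal <- lapply(all_runs, function(rs)
    Filter(function(r) r[1] == 1L || r[2] == L, rs))
  ranges <- unique(do.call(c, internal))
  if (length(ranges) == 0L) {
    return(list(ranges = list(),
                codes = stats::setNames(rep("", length(seqs)),
                                        names(seqs))))
  }
  ord <- order(vapply(ranges, `[[`, numeric(1), 1L),
               vapply(ranges, `[[`, numeric(1), 2L))
  ranges <- ranges[ord]
  codes <- vapply(seq_along(seqs), function(i) {
    paste(vapply(ranges, function(r) {
      own <- internal[[i]]
      if (any(vapply(own, function(o) o[1] == r[1] && o[2] == r[2],
                     logical(1)))) return("C")
      if (any(vapply(own, function(o)
        o[1] <= r[1] && o[2] >= r[2] && !(o[1] == r[1] && o[2] == r[2]),
        logical(1)))) return("N")
      if (any(vapply(terminal[[i]], function(o)
        o[1] <= r[1] && o[2] >= r[2], logical(1)))) return("N")
      "A"
    }, character(1)), collapse = "")
  }, character(1))
  list(ranges = ranges, codes = stats::setNames(codes, names(seqs)))
}

# random gapped alignment for indel-coding property tests
random_gapped_alignment <- function(n_seq, len, n_gap_runs = 2L) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (k in seq_len(sample(0:n_gap_runs, 1L))) {
      gl <- sample(1:5, 1L)
      start <- sample(len - gl + 1L, 1L)
      v[start:(start + gl - 1L)] <- "-"
    }
    paste(v, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%d", seq_len(n_seq))
  seqs
}

# independent recombination oracle: a state string is recombinant iff both
# parents appear among its maximal runs of length >= min_block (N skipped)
oracle_recombinant <- function(state_string, min_block = 2L) {
  st <- strsplit(state_string, "", fixed = TRUE)[[1]]
  st <- st[st != "N"]
  if (length(st) == 0L) return(FALSE)
  qualifying <- character(0)
  i <- 1L
  while (i <= length(st)) {
    j <- i
    while (j < length(st) && st[j + 1L] == st[i]) j <- j + 1L
    if (j - i + 1L >= min_block) qualifying <- c(qualifying, st[i])
    i <- j + 1L
  }
  length(unique(qualifying)) >= 2L
}
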