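# substitution + indel-event distance between two aligned haplotypes;
# a contiguous gap run present in exactly one sequence counts as a single
# mutational event, not one per column
.haplotype_distance <- function(a, b, count_indels = TRUE) {
  subs <- pairwise_substitutions(a, b)
  if (!count_indels) return(subs)
  ma <- .mask_string(a); mb <- .mask_string(b)
  one_gap <- (ma == 0L) != (mb == 0L)
  runs <- rle(one_gap)
  subs + sum(runs$values)
}

#' Assign the maternal parent of a hybrid from a plastid haplotype
#'
#' Plastid genomes are assumed maternally inherited; the hybrid's plastid
#' haplotype therefore identifies its maternal parent. The haplotype is
#' compared against every panel haplotype of the two (nuclear-marker
#' determined) parent species: identity to haplotypes of exactly one species
#' gives an assigned call; identity to a haplotype carried by both species
#' gives an equivocal call (the asterisk cases); a haplotype matching no
#' panel entry is reported as novel, derived from its nearest haplotype(s).
#'
#' @param hybrid_seq Residue string of the hybrid's plastid marker.
#' @param plastid_panel A `genotype_panel` of plastid haplotypes (labels =
#'   haplotype names, species from metadata).
#' @param parent_species Character vector of the two candidate parent
#'   species; use `NULL` for open-panel mode (all panel species considered,
#'   for hybrids whose second parent is unknown).
#' @param count_indels Count each contiguous gap-run difference as one
#'   event (default TRUE).
#' @param sample_id Sample id for the report.
#' @param marker Marker name for the report.
#' @return An object of class `maternal_call`: `sample_id`, `marker`,
#'   `call` (`assigned`/`equivocal`/`novel_haplotype`), `maternal` (species
#'   or `NA`), `candidates`, `matched_haplotype`, `distance`,
#'   `derived_from`.
#' @export
assign_maternal <- function(hybrid_seq, plastid_panel,
                            parent_species = NULL, count_indels = TRUE,
                            sample_id = "sample", marker = NULL) {
  if (is.null(marker)) marker <- plastid_panel$marker
  if (is.null(parent_species)) {
    labels <- plastid_panel$labels
  } else {
    absent <- setdiff(parent_species, plastid_panel$species)
    if (length(absent))
      stop("parent species absent from plastid panel: ",
           paste(absent, collapse = ", "), call. = FALSE)
    labels <- plastid_panel$labels[
      plastid_panel$species[plastid_panel$labels] %in% parent_species]
  }
  d <- vapply(labels, function(h)
    .haplotype_distance(hybrid_seq, panel_consensus(plastid_panel, h),
                        count_indels = count_indels), numeric(1))
  dmin <- min(d)
  best <- labels[d == dmin]
  best_species <- unique(unname(plastid_panel$species[best]))
  if (dmin == 0) {
    if (length(best_species) == 1L) {
      call <- "assigned"; maternal <- best_species
    } else {
      call <- "equivocal"; maternal <- NA_character_
    }
    matched <- best
    derived <- NA_character_
  } else {
    call <- "novel_haplotype"
    maternal <- NA_character_
    matched <- character(0)
    derived <- best
  }
  structure(list(
    sample_id = sample_id, marker = marker, call = call,
    maternal = maternal, candidates = best_species,
    matched_haplotype = matched, distance = as.integer(dmin),
    derived_from = derived), class = "maternal_call")
}

#' @export
print.maternal_call <- function(x, ...) {
  cat(sprintf("%s [%s]: %s%s (distance %d)\n", x$sample_id, x$marker,
              x$call,
              if (!is.na(x$maternal)) paste0(" -> ", x$maternal) else
                paste0(" {", paste(x$candidates, collapse = ","), "}"),
              x$distance))
  invisible(x)
}

#' Resolve maternal calls across plastid markers
#'
#' One sample may be typed with several plastid markers of different
#' resolution. An assigned call from any marker wins; conflicting assigned
#' calls across markers are an explicit conflict state, never silently
#' resolved. Failing an assignment, a novel haplotype derived from the
#' haplotypes of a single species resolves the sample to that species
#' (assigned by derivation); otherwise the sample stays equivocal.
#'
#' @param calls List of `maternal_call` for one sample.
#' @return A single `maternal_call`; `call` may additionally be
#'   `"conflict"`, and attribute `by_derivation` marks derivation-based
#'   assignments.
#' @export
cross_marker_resolve <- function(calls) {
  stopifnot(length(calls) >= 1L)
  ids <- unique(vapply(calls, `[[`, character(1), "sample_id"))
  if (length(ids) != 1L)
    stop("calls belong to different samples: ",
         paste(ids, collapse = ", "), call. = FALSE)
  assigned <- Filter(function(x) x$call == "assigned", calls)
  if (length(assigned)) {
    maternal <- unique(vapply(assigned, `[[`, character(1), "maternal"))
    if (length(maternal) > 1L) {
      out <- assigned[[1]]
      out$call <- "conflict"
      out$maternal <- NA_character_
      out$candidates <- maternal
      return(out)
    }
    return(assigned[[1]])
  }
  novel <- Filter(function(x) x$call == "novel_haplotype", calls)
  for (x in novel) {
    sp <- unique(x$candidates)
    if (length(sp) == 1L) {
      x$call <- "assigned"
      x$maternal <- sp
      attr(x, "by_derivation") <- TRUE
      return(x)
    }
  }
  # all equivocal (or novel with multi-species derivation)
  out <- calls[[1]]
  out$call <- "equivocal"
  out$maternal <- NA_character_
  out$candidates <- unique(unlist(lapply(calls, `[[`, "candidates")))
  out
}

#' Lower bound on independent origins per hybrid type
#'
#' Counts, per hybrid type, the distinct (maternal species, maternal
#' haplotype) combinations among its samples — each distinct combination
#' requires a separate hybridization event, so the count is a lower bound on
#' the number of independent origins. A hybrid type whose samples include
#' both parent species as maternal parent is flagged as formed by reciprocal
#' crosses.
#'
#' @param samples Data frame with columns `hybrid_type` (e.g. `"spA x
#'   spB"`), `maternal` (species or `NA`), `haplotype` (matched or derived
#'   haplotype label), and optionally `parents` columns.
#' @return Data frame `hybrid_type`, `n_samples`, `min_independent_origins`,
#'   `reciprocal_cross`.
#' @export
count_independent_origins <- function(samples) {
  stopifnot(all(c("hybrid_type", "maternal", "haplotype") %in%
                  names(samples)))
  out <- lapply(split(samples, samples$hybrid_type), function(d) {
    known <- d[!is.na(d$maternal), , drop = FALSE]
    tuples <- unique(paste(known$maternal, known$haplotype, sep = "\r"))
    data.frame(hybrid_type = d$hybrid_type[1], n_samples = nrow(d),
               min_independent_origins = max(length(tuples),
                                             if (nrow(d)) 1L else 0L),
               reciprocal_cross = length(unique(known$maternal)) >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
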