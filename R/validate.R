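#' Collapse clone records into candidate alleles
#'
#' Candidates are defined by exact sequence identity after uppercasing
#' (cloned molecules are single templates, so no ambiguity-code merging is
#' attempted). Tallies the clones and the set of individuals supporting
#' each distinct sequence.
#'
#' @param clones Data frame with columns `individual`, `clone`,
#'   `sequence`. Sequences must be non-empty strings over `A,C,G,T,N`.
#' @return Data frame of candidates: `sequence`, `individuals`
#'   (comma-separated, sorted), `n_individuals`, `clone_count`, ordered by
#'   decreasing clone count then sequence.
#' @export
collapse_clones <- function(clones) {
  if (nrow(clones) == 0L) {
    return(data.frame(sequence = character(0), individuals = character(0),
                      n_individuals = integer(0), clone_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- toupper(clones$sequence)
  bad <- grepl("[^ACGTN]", seqs) | nchar(seqs) == 0L
  if (any(bad)) {
    ids <- sprintf("%s/%s", clones$individual[bad], clones$clone[bad])
    stop("clone record(s) with characters outside {A,C,G,T,N} or empty: ",
         paste(head(ids, 5L), collapse = ", "))
  }
  sp <- split(clones$individual, seqs)
  cand <- data.frame(
    sequence = names(sp),
    individuals = vapply(sp, function(x) paste(sort(unique(x)), collapse = ","), ""),
    n_individuals = vapply(sp, function(x) length(unique(x)), 0L),
    clone_count = lengths(sp),
    stringsAsFactors = FALSE
  )
  cand <- cand[order(-cand$clone_count, cand$sequence), ]
  rownames(cand) <- NULL
  cand
}

#' Apply the two-or-more-individuals acceptance rule
#'
#' A candidate sequence is accepted as a putative allele only if it was
#' observed in at least `min_individuals` individuals; within-individual
#' clone replication alone never qualifies, which screens out PCR point
#' errors and chimeras (each arises in a single amplification).
#'
#' @param candidates From [collapse_clones()].
#' @param min_individuals Minimum distinct individuals (default 2).
#' @return The candidates with a `status` column, `accepted` or
#'   `excluded`.
#' @export
apply_acceptance_rule <- function(candidates, min_individuals = 2L) {
  candidates$status <- ifelse(candidates$n_individuals >= min_individuals,
                              "accepted", "excluded")
  candidates
}

# Per-site divergence between two sequences. Equal lengths: Hamming /
# length. Lengths differing by a multiple of 3 (in-frame indel): the gap
# block is slid over every codon boundary of the shorter sequence, each
# gapped codon counts as 3 differences, the denominator is the aligned
# (longer) length, and the minimum over placements is returned. Other
# length mismatches (frameshift-like) fall back to end-padding.
pairwise_divergence <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    ca <- seq_to_chars(a); cb <- seq_to_chars(b)
    return(sum(ca != cb) / nchar(a))
  }
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  d <- nchar(b) - nchar(a)
  if (d %% 3L == 0L) {
    cb <- seq_to_chars(b)
    best <- Inf
    for (at in 0:(nchar(a) %/% 3L)) {   # gap inserted after codon `at` of a
      ca <- c(seq_to_chars(substring(a, 1L, at * 3L)), rep("-", d),
              seq_to_chars(substring(a, at * 3L + 1L, nchar(a))))
      best <- min(best, (sum(ca != cb & ca != "-") + d) / nchar(b))
    }
    return(best)
  }
  ca <- c(seq_to_chars(a), rep("-", d))
  (sum(ca != seq_to_chars(b))) / nchar(b)
}

#' Rescue screen for excluded sequences
#'
#' Single-individual sequences are normally excluded as putative PCR
#' artefacts, but a sequence highly divergent from every accepted allele
#' is unlikely to be an artefact of any of them. This screen flags
#' excluded sequences whose minimum divergence to all accepted alleles is
#' strictly greater than `threshold` (default 1.5%, about 3 bp on a
#' 159-bp amplicon). Flagged sequences are reported for inspection only;
#' they are never promoted to the accepted set.
#'
#' @param excluded Data frame of excluded candidates (needs `sequence`).
#' @param accepted Data frame of accepted candidates (needs `sequence`);
#'   must be non-empty.
#' @param threshold Proportion of differing sites (strict `>` rule).
#' @return `excluded` with columns `min_divergence` and `rescue_flagged`.
#' @export
rescue_screen <- function(excluded, accepted, threshold = 0.015) {
  if (nrow(accepted) == 0L) stop("accepted set is empty; nothing to screen against")
  if (nrow(excluded) == 0L) {
    excluded$min_divergence <- numeric(0)
    excluded$rescue_flagged <- logical(0)
    return(excluded)
  }
  excluded$min_divergence <- vapply(excluded$sequence, function(s) {
    min(vapply(accepted$sequence, pairwise_divergence, 0, a = s))
  }, 0, USE.NAMES = FALSE)
  excluded$rescue_flagged <- excluded$min_divergence > threshold
  excluded
}

#' Classify an allele as functional or pseudogene-like
#'
#' An allele is pseudogene-like if its fixed-frame translation contains a
#' stop codon, or if its length differs from the reference amplicon
#' length by a non-multiple of 3 (frameshift). In-frame insertions or
#' deletions (multiples of 3, e.g. a two-codon insert turning 159 bp into
#' 165 bp) leave the allele functional.
#'
#' @param sequence Nucleotide string.
#' @param frame Reading-frame offset in `0:2`.
#' @param amplicon_length Reference amplicon length in bp (default 159).
#' @return `"functional"` or `"pseudogene_like"`.
#' @export
classify_functionality <- function(sequence, frame = 0L, amplicon_length = 159L) {
  if (nchar(sequence) - frame < 3L) {
    stop("sequence shorter than one codon in frame ", frame)
  }
  if ((nchar(sequence) - amplicon_length) %% 3L != 0L) return("pseudogene_like")
  aa <- translate_frame(sequence, frame)
  if (grepl("*", aa, fixed = TRUE)) "pseudogene_like" else "functional"
}

#' Name accepted alleles
#'
#' Ranks accepted alleles by descending total clone count, breaking ties
#' by lexicographic sequence order, and assigns `prefix` + zero-padded
#' rank (width at least 2), e.g. `Neso01 ... Neso23`.
#'
#' @param accepted Data frame of accepted candidates (needs `sequence`,
#'   `clone_count`).
#' @param prefix Name prefix.
#' @return `accepted` with a `name` column, in rank order.
#' @export
name_alleles <- function(accepted, prefix = "All") {
  if (nrow(accepted) == 0L) {
    accepted$name <- character(0)
    return(accepted)
  }
  ord <- order(-accepted$clone_count, accepted$sequence)
  accepted <- accepted[ord, , drop = FALSE]
  width <- max(2L, nchar(nrow(accepted)))
  accepted$name <- sprintf("%s%0*d", prefix, width, seq_len(nrow(accepted)))
  rownames(accepted) <- NULL
  accepted
}

#' Validate a clone library end to end
#'
#' Collapse, acceptance rule, rescue screen, functionality classification
#' and naming in one call.
#'
#' @param clones Data frame `individual`, `clone`, `sequence`.
#' @param min_individuals Acceptance rule threshold (default 2).
#' @param rescue_threshold Divergence threshold for the rescue screen.
#' @param frame Reading-frame offset.
#' @param amplicon_length Reference amplicon length in bp.
#' @param prefix Allele name prefix.
#' @return List of class `allele_validation`: `alleles` (named accepted
#'   alleles with `functional_flag`), `candidates` (all candidates with
#'   status and rescue columns), `summary` (raw clone count, candidate
#'   counts by class).
#' @export
validate_clones <- function(clones, min_individuals = 2L,
                            rescue_threshold = 0.015, frame = 0L,
                            amplicon_length = 159L, prefix = "All") {
  cand <- apply_acceptance_rule(collapse_clones(clones), min_individuals)
  acc <- cand[cand$status == "accepted", , drop = FALSE]
  exc <- cand[cand$status == "excluded", , drop = FALSE]
  if (nrow(acc) > 0L && nrow(exc) > 0L) {
    exc <- rescue_screen(exc, acc, rescue_threshold)
    exc$status[exc$rescue_flagged] <- "rescue_flagged"
  } else if (nrow(exc) > 0L) {
    exc$min_divergence <- NA_real_
    exc$rescue_flagged <- FALSE
  }
  acc <- name_alleles(acc, prefix)
  if (nrow(acc) > 0L) {
    acc$functional_flag <- vapply(acc$sequence, classify_functionality, "",
                                  frame = frame,
                                  amplicon_length = amplicon_length,
                                  USE.NAMES = FALSE)
  } else {
    acc$functional_flag <- character(0)
  }
  structure(list(
    alleles = acc,
    candidates = cand,
    excluded = exc,
    summary = data.frame(
      raw_clones = nrow(clones),
      candidates = nrow(cand),
      accepted = nrow(acc),
      excluded = nrow(exc),
      rescue_flagged = if (nrow(exc) > 0L) sum(exc$rescue_flagged) else 0L
    )
  ), class = "allele_validation")
}
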