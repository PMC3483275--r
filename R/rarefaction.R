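#' Minimum number of duplicated loci
#'
#' With every locus heterozygous, one individual can carry at most two
#' distinct alleles per locus, so the largest per-individual count of
#' distinct functional alleles implies at least `ceiling(max / 2)` loci.
#'
#' @param counts Integer vector of per-individual distinct functional
#'   allele counts (each >= 1).
#' @return Integer minimum locus number.
#' @export
min_locus_count <- function(counts) {
  if (length(counts) == 0L) stop("no per-individual allele counts supplied")
  if (any(counts < 1L)) stop("allele counts must be >= 1")
  as.integer(ceiling(max(counts) / 2))
}

#' Allele-accumulation (rarefaction) curve for one individual
#'
#' Draws, for each subset size, `reps` random subsets of the individual's
#' clone records without replacement and counts the distinct validated
#' alleles in each subset. If sampling has saturated the individual's
#' allele repertoire, the mean count plateaus with increasing subset
#' size. Subset sizes exceeding the clone count are dropped with a
#' message (sampling is restricted by the number of sequences obtained).
#'
#' @param assignments Character vector: the validated allele assigned to
#'   each clone of one individual (artefact clones excluded upstream).
#' @param subset_sizes Integer vector of subset sizes.
#' @param reps Replicates per size (default 100).
#' @param seed Seed.
#' @return Object of class `rarefaction_curve`: data frame `size`,
#'   `mean`, `sd`, plus attributes `reps`, `seed`, `n_clones`,
#'   `n_alleles`, `dropped_sizes`.
#' @export
rarefaction_curve <- function(assignments, subset_sizes = c(5L, 10L, 15L, 20L, 25L),
                              reps = 100L, seed = 1L) {
  assignments <- assignments[!is.na(assignments)]
  if (length(assignments) == 0L) stop("no validated alleles for this individual")
  total <- length(assignments)
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  drop <- subset_sizes[subset_sizes > total]
  if (length(drop) > 0L) {
    message("dropping subset size(s) ", paste(drop, collapse = ", "),
            " larger than the clone library (", total, " clones)")
    subset_sizes <- subset_sizes[subset_sizes <= total]
  }
  if (length(subset_sizes) == 0L) stop("no subset size within the clone count")
  res <- with_seed(seed, {
    lapply(subset_sizes, function(k) {
      counts <- vapply(seq_len(reps), function(r) {
        length(unique(assignments[sample.int(total, k)]))
      }, 0L)
      c(mean = mean(counts), sd = sd(counts))
    })
  })
  curve <- data.frame(size = subset_sizes,
                      mean = vapply(res, `[[`, 0, "mean"),
                      sd = vapply(res, `[[`, 0, "sd"))
  structure(curve, class = c("rarefaction_curve", "data.frame"),
            reps = reps, seed = seed, n_clones = total,
            n_alleles = length(unique(assignments)), dropped_sizes = drop)
}

#' Plateau test on a rarefaction curve
#'
#' `method = "increment"` (default): the curve has plateaued when the
#' mean gain in distinct alleles between the last two subset sizes is
#' strictly below `epsilon` alleles. `method = "slope"`: the least-squares
#' slope over the last two points (gain per additional clone) must be
#' strictly below `epsilon` per clone.
#'
#' @param curve A [rarefaction_curve()].
#' @param epsilon Strict threshold (alleles per step, or per clone for
#'   `"slope"`).
#' @param method `"increment"` or `"slope"`.
#' @return Logical: `TRUE` if the curve has plateaued.
#' @export
plateau_test <- function(curve, epsilon = 0.25, method = c("increment", "slope")) {
  method <- match.arg(method)
  if (nrow(curve) < 2L) stop("plateau test needs a curve with at least 2 subset sizes")
  m <- nrow(curve)
  gain <- curve$mean[m] - curve$mean[m - 1L]
  if (method == "slope") gain <- gain / (curve$size[m] - curve$size[m - 1L])
  gain < epsilon
}

#' Rarefaction summary across individuals
#'
#' @param clone_alleles Data frame `individual`, `allele` (one row per
#'   validated clone).
#' @param subset_sizes,reps,seed,epsilon Passed through.
#' @return Data frame, one row per individual: clone and allele totals,
#'   plateau verdict; curves attached as attribute `curves`.
#' @export
rarefaction_summary <- function(clone_alleles, subset_sizes = c(5L, 10L, 15L, 20L, 25L),
                                reps = 100L, seed = 1L, epsilon = 0.25) {
  inds <- unique(clone_alleles$individual)
  curves <- list()
  rows <- lapply(seq_along(inds), function(i) {
    a <- clone_alleles$allele[clone_alleles$individual == inds[i]]
    cv <- rarefaction_curve(a, subset_sizes, reps, derive_seed(seed, i))
    curves[[inds[i]]] <<- cv
    data.frame(individual = inds[i], n_clones = attr(cv, "n_clones"),
               n_alleles = attr(cv, "n_alleles"),
               plateau = if (nrow(cv) >= 2L) plateau_test(cv, epsilon) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
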