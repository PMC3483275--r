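#' Build an allele x population incidence matrix from observations
#'
#' An entry is 1 when the allele was observed in at least one individual
#' of the population (presence/absence, not frequency-weighted).
#'
#' @param observations Data frame `allele`, `individual` (one row per
#'   observation; duplicates fine).
#' @param population_map Data frame `individual`, `population`; every
#'   observed individual must be mapped to exactly one population.
#' @return Binary matrix, alleles in rows, populations in columns.
#' @export
build_incidence <- function(observations, population_map) {
  dup <- population_map$individual[duplicated(population_map$individual)]
  if (length(dup) > 0L) stop("individual(s) mapped to several populations: ",
                             paste(unique(dup), collapse = ", "))
  pop <- population_map$population[match(observations$individual,
                                         population_map$individual)]
  if (anyNA(pop)) {
    stop("individual(s) missing from the population map: ",
         paste(unique(observations$individual[is.na(pop)]), collapse = ", "))
  }
  incidence_from_lists(split(observations$allele, pop),
                       populations = unique(population_map$population))
}

#' Build an incidence matrix from per-population allele lists
#'
#' @param lists Named list: population -> character vector of allele
#'   names observed there.
#' @param populations Optional population order (default: list names);
#'   populations absent from `lists` get all-zero columns.
#' @return Binary matrix, alleles in rows (sorted), populations in
#'   columns.
#' @export
incidence_from_lists <- function(lists, populations = names(lists)) {
  alleles <- sort(unique(unlist(lists, use.names = FALSE)))
  m <- matrix(0L, nrow = length(alleles), ncol = length(populations),
              dimnames = list(alleles, populations))
  for (p in intersect(populations, names(lists))) {
    m[unique(lists[[p]]), p] <- 1L
  }
  m
}

#' Allele-sharing summary
#'
#' Cross-population sharing of identical alleles is the signature of
#' retained ancestral (trans-species) polymorphism. Reports per-population
#' allele totals, the union, pairwise shared counts, and alleles private
#' to a single population.
#'
#' @param incidence Binary allele x population matrix.
#' @return List of class `sharing_summary`: `totals` (column sums),
#'   `union` (alleles observed anywhere), `shared` (symmetric pairwise
#'   shared-count matrix), `private` (per population, alleles found only
#'   there), `private_alleles` (named list).
#' @export
sharing_summary <- function(incidence) {
  storage.mode(incidence) <- "integer"
  if (any(incidence != 0L & incidence != 1L)) stop("incidence matrix must be binary")
  shared <- t(incidence) %*% incidence
  rowsum1 <- rowSums(incidence)
  priv <- lapply(colnames(incidence), function(p) {
    rownames(incidence)[incidence[, p] == 1L & rowsum1 == 1L]
  })
  names(priv) <- colnames(incidence)
  structure(list(
    totals = colSums(incidence),
    union = sum(rowsum1 > 0L),
    shared = shared,
    private = lengths(priv),
    private_alleles = priv
  ), class = "sharing_summary")
}

#' Count alleles shared between one population and a set of others
#'
#' E.g. alleles shared between an outgroup island and the union of the
#' ingroup islands.
#'
#' @param incidence Binary incidence matrix.
#' @param pop Single population (column name).
#' @param others Character vector of other populations.
#' @return Integer count of alleles present in `pop` and in at least one
#'   of `others`.
#' @export
shared_with_group <- function(incidence, pop, others) {
  sum(incidence[, pop] == 1L & rowSums(incidence[, others, drop = FALSE]) > 0L)
}
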