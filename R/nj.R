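# Distance-based phylogeny: p/JC distances, an exact Saitou-Nei
# neighbour-joining implementation with a deterministic tie rule, column
# bootstrap and majority-rule consensus with supports.

#' Pairwise distance matrix from an alignment
#'
#' p-distance (mismatches over compared sites) or its Jukes-Cantor
#' correction; gap/N positions are excluded pairwise.
#'
#' @param seqs Named character vector of aligned sequences (>= 3 for
#'   downstream tree building).
#' @param model `"p"` (default; uniform rates, homogeneous substitution
#'   pattern) or `"JC"`.
#' @return Symmetric distance matrix with a `model` attribute.
#' @export
pairwise_distances <- function(seqs, model = c("p", "JC")) {
  model <- match.arg(model)
  st <- pairwise_diff_stats(seqs)
  n <- st$n
  labels <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  pairs <- combn(n, 2L)
  p <- st$diffs / st$compared
  if (model == "JC") {
    bad <- p >= 0.75
    if (any(bad)) {
      j <- which(bad)[1]
      stop("Jukes-Cantor distance undefined (p >= 3/4) for pair ",
           labels[pairs[1, j]], " / ", labels[pairs[2, j]])
    }
    p <- -0.75 * log(1 - (4 / 3) * p)
  }
  for (j in seq_len(ncol(pairs))) {
    D[pairs[1, j], pairs[2, j]] <- D[pairs[2, j], pairs[1, j]] <- p[j]
  }
  attr(D, "model") <- model
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion with the standard
#' branch-length formulas. Ties in Q are broken by the lexicographically
#' smallest pair of cluster labels (each cluster labelled by its smallest
#' leaf), so the result is deterministic. Negative branch-length
#' estimates are clamped to zero (with a message unless `quiet`). Exact
#' on additive distance matrices.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param quiet Suppress the negative-branch message (used by the
#'   bootstrap).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(D, quiet = FALSE) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  # each active cluster: newick fragment + smallest leaf label (tie key)
  frag <- labels
  key <- labels
  Dm <- unname(D)
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(Dm)
    # Q matrix; pick the minimising pair, ties by lexicographic key pair
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * Dm[i, j] - r[i] - r[j]
      kp <- sort(c(key[i], key[j]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (kp[1] < best$kp[1] || (kp[1] == best$kp[1] && kp[2] < best$kp[2])))) {
        best <- list(q = q, i = i, j = j, kp = kp)
      }
    }
    i <- best$i; j <- best$j
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  # final three-point resolution
  la <- clamp((Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2)
  lb <- clamp((Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2)
  lc <- clamp((Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", frag[1], la, frag[2], lb,
                 frag[3], lc)
  if (n_clamped > 0L && !quiet) {
    message(n_clamped, " negative NJ branch length(s) clamped to 0")
  }
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an unrooted tree, each canonicalised as the
# sorted tip-label set on the side *not* containing the alphabetically
# first taxon, serialised as a single string.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ref <- min(tips)
  n <- length(tips)
  out <- character(0)
  bp <- ape::prop.part(tree)
  for (part in bp) {
    side <- sort(tips[part])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- sort(setdiff(tips, side))
    if (length(side) <= 1L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap NJ tree with majority-rule consensus
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, tallies bipartition frequencies, and returns the consensus
#' retaining bipartitions at frequency >= `cutoff`, with supports (in
#' percent) attached as internal node labels. Replicates whose resampled
#' alignment yields an undefined Jukes-Cantor distance are dropped with a
#' message; if more than 10% drop, the run aborts.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param model `"p"` or `"JC"`.
#' @param reps Bootstrap replicates.
#' @param cutoff Consensus frequency cut-off in `[0.5, 1]` (default
#'   0.75).
#' @param seed Seed.
#' @return List of class `bootstrap_consensus`: `consensus` (phylo with
#'   node labels = support %), `nj` (the full-data NJ tree), `splits`
#'   (data frame `split`, `count`, `support`), `reps_used`,
#'   `reps_dropped`.
#' @export
bootstrap_consensus <- function(seqs, model = c("p", "JC"), reps = 1000L,
                                cutoff = 0.75, seed = 1L) {
  model <- match.arg(model)
  stopifnot(reps >= 1L, cutoff >= 0.5, cutoff <= 1)
  m <- alignment_matrix(seqs)
  full <- nj_tree(pairwise_distances(seqs, model), quiet = TRUE)
  tally <- new.env(parent = emptyenv())
  dropped <- 0L
  trees <- vector("list", reps)
  used <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(ncol(m), replace = TRUE)
      boot_seqs <- setNames(apply(m[, idx, drop = FALSE], 1L, paste, collapse = ""),
                            rownames(m))
      tr <- tryCatch(nj_tree(pairwise_distances(boot_seqs, model), quiet = TRUE),
                     error = function(e) NULL)
      if (is.null(tr)) { dropped <- dropped + 1L; next }
      used <- used + 1L
      trees[[used]] <- tr
      for (s in tree_splits(tr)) {
        tally[[s]] <- (if (is.null(tally[[s]])) 0L else tally[[s]]) + 1L
      }
    }
  })
  if (dropped > 0L) message(dropped, " bootstrap replicate(s) dropped ",
                            "(undefined distance)")
  if (dropped > 0.10 * reps) {
    stop("more than 10% of bootstrap replicates dropped (", dropped, "/", reps, ")")
  }
  trees <- trees[seq_len(used)]
  splits <- data.frame(
    split = ls(tally),
    count = vapply(ls(tally), function(s) tally[[s]], 0L),
    stringsAsFactors = FALSE)
  splits$support <- 100 * splits$count / used
  splits <- splits[order(-splits$count, splits$split), ]
  rownames(splits) <- NULL

  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = cutoff, check.labels = TRUE)
  cons <- attach_supports(cons, splits, used)
  structure(list(consensus = cons, nj = full, splits = splits,
                 reps_used = used, reps_dropped = dropped, cutoff = cutoff,
                 model = model),
            class = "bootstrap_consensus")
}

# Attach bootstrap supports (percent) to the internal nodes of a
# consensus tree by matching each node's bipartition in the tally.
attach_supports <- function(tree, splits, reps_used) {
  tips <- tree$tip.label
  ref <- min(tips)
  n <- length(tips)
  bp <- ape::prop.part(tree)
  lab <- rep(NA_character_, tree$Nnode)
  for (i in seq_along(bp)) {
    side <- sort(tips[bp[[i]]])
    if (length(side) >= n - 1L) { lab[i] <- ""; next }  # root/full split
    if (ref %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    hit <- match(key, splits$split)
    lab[i] <- if (is.na(hit)) "" else sprintf("%.0f", splits$support[hit])
  }
  tree$node.label <- lab
  tree
}

#' Simulate a random additive (tree) distance matrix
#'
#' Draws a random unrooted binary topology with positive branch lengths
#' and returns its path-length (additive) distance matrix together with
#' the generating tree; NJ must recover both exactly.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param seed Optional seed.
#' @return List with `tree` (phylo) and `D` (additive distance matrix).
#' @export
random_additive_matrix <- function(n_taxa, seed = NULL) {
  with_seed(seed, {
    tree <- ape::rtree(n_taxa, rooted = FALSE,
                       br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tree)
    D <- D[order(rownames(D)), order(colnames(D))]
    list(tree = tree, D = D)
  })
}
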