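# Frequency-spectrum summaries of an alignment. Alignment = named
# character vector of equal-length sequences over {A,C,G,T,-,N}; gap and
# N positions are excluded pairwise (pi, k) or sitewise (S, eta).

valid_base <- function(m) m %in% DNA_BASES

# Mean pairwise differences (k) and per-site diversity (pi), pairwise
# deletion of non-ACGT positions.
pairwise_diff_stats <- function(seqs) {
  m <- alignment_matrix(seqs)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  ok <- matrix(valid_base(m), nrow = n)
  pairs <- combn(n, 2L)
  diffs <- numeric(ncol(pairs))
  comp <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    use <- ok[i1, ] & ok[i2, ]
    comp[j] <- sum(use)
    diffs[j] <- sum(m[i1, use] != m[i2, use])
  }
  if (any(comp == 0)) stop("sequence pair with no comparable sites")
  list(k = mean(diffs), pi = mean(diffs / comp), n = n,
       diffs = diffs, compared = comp)
}

#' Nucleotide diversity
#'
#' Average over all unordered sequence pairs of the proportion of
#' differing sites, with gap/N positions excluded pairwise.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return `pi`, a single number in `[0, 1]`.
#' @export
nucleotide_diversity <- function(seqs) {
  pairwise_diff_stats(seqs)$pi
}

# Site-wise variant summary: S = segregating sites, eta = total number of
# mutations (alleles - 1 per site), eta_s = singletons (bases observed in
# exactly one sequence at a segregating site).
site_spectrum <- function(seqs) {
  m <- alignment_matrix(seqs)
  S <- 0L; eta <- 0L; eta_s <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[valid_base(col)]
    if (length(col) < 2L) next
    tab <- table(col)
    if (length(tab) > 1L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      # singletons: bases carried by exactly one sequence; capped at the
      # number of mutations at the site (relevant when every base at the
      # site is a singleton, e.g. two sequences only)
      s_here <- sum(tab == 1L)
      if (s_here == length(tab)) s_here <- length(tab) - 1L
      eta_s <- eta_s + s_here
    }
  }
  list(S = S, eta = eta, eta_s = eta_s, n = nrow(m))
}

# Tajima (1989) constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the 1989 constants;
#' positive values indicate an excess of intermediate-frequency variants
#' (balancing selection or population contraction), negative values an
#' excess of rare variants. The p-value uses the beta-distribution
#' approximation to the null density of D.
#'
#' @param seqs Named character vector of aligned sequences (n >= 4).
#' @return List of class `neutrality_stat`: `statistic`, `S`, `k`, `n`,
#'   `p_value`, `significance` (a class such as `"p > 0.10"`). With
#'   `S = 0` the statistic is `NA` ("undefined"), not 0.
#' @export
tajimas_d <- function(seqs) {
  sp <- site_spectrum(seqs)
  n <- sp$n
  if (n < 4L) stop("Tajima's D needs at least 4 sequences")
  if (sp$S == 0L) {
    return(structure(list(statistic = NA_real_, S = 0L, k = 0, n = n,
                          p_value = NA_real_, significance = "undefined (S = 0)"),
                     class = "neutrality_stat"))
  }
  k <- pairwise_diff_stats(seqs)$k
  cst <- tajima_constants(n)
  D <- (k - sp$S / cst$a1) / sqrt(cst$e1 * sp$S + cst$e2 * sp$S * (sp$S - 1))
  p <- tajima_beta_p(D, n)
  structure(list(statistic = D, S = sp$S, k = k, n = n, p_value = p,
                 significance = p_class(p)),
            class = "neutrality_stat")
}

# Two-tailed p for Tajima's D under the beta approximation (Tajima 1989):
# D is bounded in [Dmin, Dmax] and (D - Dmin)/(Dmax - Dmin) is treated as
# Beta(b, a) with shape chosen so D has mean 0, variance 1.
tajima_beta_p <- function(D, n) {
  cst <- tajima_constants(n)
  Dmin <- (2 / n - 1 / cst$a1) / sqrt(cst$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / cst$a1) / sqrt(cst$e2)
  tmp1 <- 1 + Dmin * Dmax
  tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2
  b <- tmp1 * Dmin / tmp2
  p <- pbeta((D - Dmin) / tmp2, b, a)
  if (is.na(p)) return(NA_real_)
  if (p < 0.5) 2 * p else 2 * (1 - p)
}

p_class <- function(p) {
  if (is.na(p)) "undefined"
  else if (p < 0.01) "p < 0.01"
  else if (p < 0.05) "p < 0.05"
  else if (p < 0.10) "p < 0.10"
  else "p > 0.10"
}

# Fu & Li (1993) starred-statistic weights, with the corrections of
# Simonsen, Churchill & Aquadro (1995); an, bn are the usual harmonic
# sums, an1 = a_{n+1}.
fu_li_star_constants <- function(n) {
  i <- seq_len(n - 1L)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, cn = cn, dn = dn,
       uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu & Li's D* and F* (no outgroup)
#'
#' Contrast the total number of mutations (eta) and the singleton count
#' (eta_s) with the scaled diversity; negative values indicate a
#' singleton excess. Significance, when requested, comes from neutral
#' coalescent simulation conditional on the observed number of
#' segregating sites.
#'
#' @param seqs Named character vector of aligned sequences (n >= 4).
#' @param p_reps Coalescent replicates for the empirical two-tailed
#'   p-values; 0 skips the significance step.
#' @param seed Seed for the significance simulations.
#' @return List of class `fu_li_stars`: `D_star`, `F_star`, `eta`,
#'   `eta_s`, `k`, `n`, and (when simulated) `p_D_star`, `p_F_star` with
#'   significance classes. Undefined (all `NA`) when `S = 0`.
#' @export
fu_li_star_tests <- function(seqs, p_reps = 0L, seed = 1L) {
  sp <- site_spectrum(seqs)
  n <- sp$n
  if (n < 4L) stop("Fu & Li's D*/F* need at least 4 sequences")
  if (sp$S == 0L) {
    return(structure(list(D_star = NA_real_, F_star = NA_real_, eta = 0L,
                          eta_s = 0L, k = 0, n = n, p_D_star = NA_real_,
                          p_F_star = NA_real_,
                          significance_D = "undefined (S = 0)",
                          significance_F = "undefined (S = 0)"),
                     class = "fu_li_stars"))
  }
  k <- pairwise_diff_stats(seqs)$k
  st <- fu_li_stars_from_counts(n, sp$eta, sp$eta_s, k)
  out <- c(st, list(eta = sp$eta, eta_s = sp$eta_s, k = k, n = n))
  if (p_reps > 0L) {
    null <- with_seed(seed, {
      vapply(seq_len(p_reps), function(r) {
        sim <- sim_coalescent_alignment(n, S = sp$S)
        spn <- site_spectrum(sim)
        kn <- if (spn$S > 0) pairwise_diff_stats(sim)$k else 0
        if (spn$S == 0) return(c(NA_real_, NA_real_))
        stn <- fu_li_stars_from_counts(n, spn$eta, spn$eta_s, kn)
        c(stn$D_star, stn$F_star)
      }, numeric(2))
    })
    out$p_D_star <- empirical_two_tail(st$D_star, null[1, ])
    out$p_F_star <- empirical_two_tail(st$F_star, null[2, ])
    out$significance_D <- p_class(out$p_D_star)
    out$significance_F <- p_class(out$p_F_star)
  }
  structure(out, class = "fu_li_stars")
}

fu_li_stars_from_counts <- function(n, eta, eta_s, k) {
  cst <- fu_li_star_constants(n)
  Dst <- ((n / (n - 1)) * eta - cst$an * eta_s) /
    sqrt(cst$uD * eta + cst$vD * eta^2)
  Fst <- (k - ((n - 1) / n) * eta_s) /
    sqrt(cst$uF * eta + cst$vF * eta^2)
  list(D_star = Dst, F_star = Fst)
}

empirical_two_tail <- function(x, null) {
  null <- null[!is.na(null)]
  if (length(null) == 0L) return(NA_real_)
  lo <- (sum(null <= x) + 1) / (length(null) + 1)
  hi <- (sum(null >= x) + 1) / (length(null) + 1)
  min(1, 2 * min(lo, hi))
}

#' Simulate a neutral coalescent alignment
#'
#' Standard neutral coalescent for a constant-size panmictic population:
#' exponential coalescence times with rate `choose(k, 2)` (time in 2N
#' generations), infinite-sites mutations either thrown as a Poisson
#' process with rate `theta / 2` per lineage per unit time, or, when `S`
#' is given, a fixed number of mutations placed multinomially along the
#' branches. Each mutation yields one biallelic alignment column
#' (ancestral `A`, derived `G`).
#'
#' @param n Sample size.
#' @param theta Population mutation rate `4 N mu` (per locus); ignored
#'   when `S` is given.
#' @param S Fixed number of segregating sites (conditional simulation).
#' @param seed Optional seed.
#' @return Character vector of `n` sequences (length = number of
#'   mutations; a single constant `A` column when no mutation arose).
#' @export
sim_coalescent_alignment <- function(n, theta = NULL, S = NULL, seed = NULL) {
  stopifnot(n >= 2L, !is.null(theta) || !is.null(S))
  run <- function() {
    # genealogy: vector of lineages, each the set of descendant tips
    lineages <- as.list(seq_len(n))
    branch_tips <- list()   # per branch segment: tips below it
    branch_len <- numeric(0)
    t_now <- 0
    active_since <- rep(0, n)
    while (length(lineages) > 1L) {
      kk <- length(lineages)
      t_now <- t_now + rexp(1L, rate = kk * (kk - 1) / 2)
      pick <- sample.int(kk, 2L)
      for (p in pick) {
        branch_tips[[length(branch_tips) + 1L]] <- lineages[[p]]
        branch_len <- c(branch_len, t_now - active_since[p])
      }
      merged <- c(lineages[[pick[1]]], lineages[[pick[2]]])
      lineages <- c(lineages[-pick], list(merged))
      active_since <- c(active_since[-pick], t_now)
    }
    n_mut <- if (!is.null(S)) S else rpois(1L, (theta / 2) * sum(branch_len))
    if (n_mut == 0L) return(matrix("A", nrow = n, ncol = 1L))
    br <- sample.int(length(branch_len), n_mut, replace = TRUE,
                     prob = branch_len)
    cols <- matrix("A", nrow = n, ncol = n_mut)
    for (j in seq_len(n_mut)) cols[branch_tips[[br[j]]], j] <- "G"
    cols
  }
  m <- with_seed(seed, run())
  setNames(apply(m, 1L, paste, collapse = ""), paste0("t", seq_len(n)))
}
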