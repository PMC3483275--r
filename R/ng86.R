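# Nei & Gojobori (1986) synonymous/nonsynonymous counting with
# Jukes-Cantor correction, codon bootstrap and z-test, partitioned by a
# peptide-binding-region site mask.

#' Build a PBR site mask
#'
#' Partitions the codons of an alignment into peptide-binding-region
#' (PBR) and non-PBR sites under a named scheme. The PBR codon
#' coordinates are supplied by the user (they derive from alignment of
#' the amplicon to a human HLA-DRB structure-based map and are not a
#' property of the alignment itself).
#'
#' @param n_codons Number of codons in the alignment.
#' @param pbr Integer vector of 1-based codon indices designated PBR
#'   (may be empty).
#' @param scheme Scheme name (e.g. `"brown"`, `"tong"`, `"custom"`).
#' @return List of class `site_mask`: `scheme`, `pbr`, `non_pbr`,
#'   `n_codons`.
#' @export
build_site_mask <- function(n_codons, pbr = integer(0), scheme = "custom") {
  pbr <- sort(unique(as.integer(pbr)))
  bad <- pbr < 1L | pbr > n_codons
  if (any(bad)) {
    stop("PBR codon position(s) outside the alignment (1..", n_codons, "): ",
         paste(pbr[bad], collapse = ", "))
  }
  structure(list(scheme = scheme, pbr = pbr,
                 non_pbr = setdiff(seq_len(n_codons), pbr),
                 n_codons = as.integer(n_codons)),
            class = "site_mask")
}

#' Read a site mask from a TSV of codon indices
#'
#' @param path Two-column TSV (`scheme`, `codon`) or one-column list of
#'   codon indices.
#' @param n_codons Number of codons in the target alignment.
#' @param scheme Scheme name override; default taken from the file.
#' @return A [build_site_mask()] object.
#' @export
read_site_mask <- function(path, n_codons, scheme = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if ("codon" %in% names(tab)) {
    codons <- tab$codon
    if (is.null(scheme) && "scheme" %in% names(tab)) scheme <- tab$scheme[1]
  } else {
    codons <- tab[[1]]
  }
  build_site_mask(n_codons, codons, scheme = if (is.null(scheme)) "custom" else scheme)
}

# --- codon-level machinery -------------------------------------------------

ng86_cache <- new.env(parent = emptyenv())

is_stop <- function(codon) identical(GENETIC_CODE_TABLE[[codon]], "*")

codon_ok <- function(codon) {
  !is.na(GENETIC_CODE_TABLE[codon]) && !is_stop(codon)
}

# Potential synonymous sites of one codon: at each position, the fraction
# of the three possible changes that leave the amino acid unchanged.
# Changes creating a stop codon count as nonsynonymous (they change the
# protein).
syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  hit <- ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- GENETIC_CODE_TABLE[[codon]]
  ch <- seq_to_chars(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, ch[pos])) {
      alt <- ch; alt[pos] <- b
      if (identical(GENETIC_CODE_TABLE[[chars_to_seq(alt)]], aa)) s <- s + 1 / 3
    }
  }
  ng86_cache[[key]] <- s
  s
}

# Observed synonymous/nonsynonymous differences between two codons:
# average over all minimal mutational pathways (orderings of the
# differing positions), weighting pathways equally. Pathways passing
# through a stop codon are excluded; if every pathway does, all are kept
# (steps into/out of a stop count as nonsynonymous).
codon_path_diffs <- function(a, b) {
  key <- paste0("d_", a, b)
  hit <- ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(seq_to_chars(a) != seq_to_chars(b))
  out <- if (length(pos) == 0L) c(sd = 0, nd = 0) else {
    perms <- permutations_of(pos)
    step_counts <- function(allow_stops) {
      res <- matrix(NA_real_, nrow = length(perms), ncol = 2L)
      for (i in seq_along(perms)) {
        cur <- seq_to_chars(a)
        tgt <- seq_to_chars(b)
        sdd <- ndd <- 0
        ok <- TRUE
        for (p in perms[[i]]) {
          nxt <- cur; nxt[p] <- tgt[p]
          c1 <- chars_to_seq(cur); c2 <- chars_to_seq(nxt)
          if (!allow_stops && (is_stop(c1) || is_stop(c2))) { ok <- FALSE; break }
          if (identical(GENETIC_CODE_TABLE[[c1]], GENETIC_CODE_TABLE[[c2]])) {
            sdd <- sdd + 1
          } else ndd <- ndd + 1
          cur <- nxt
        }
        if (ok) res[i, ] <- c(sdd, ndd)
      }
      res[!is.na(res[, 1]), , drop = FALSE]
    }
    valid <- step_counts(allow_stops = FALSE)
    if (nrow(valid) == 0L) valid <- step_counts(allow_stops = TRUE)
    c(sd = mean(valid[, 1]), nd = mean(valid[, 2]))
  }
  ng86_cache[[key]] <- out
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Per-pair, per-codon NG86 contributions for an alignment: four
# (n_pairs x n_codons) matrices of potential sites (averaged over the two
# sequences) and observed differences; codons where either sequence has a
# gap, an ambiguous base or a stop codon contribute zero to both.
ng86_arrays <- function(seqs) {
  seqs <- toupper(seqs)
  codons <- lapply(seqs, split_codons)
  nc <- unique(lengths(codons))
  if (length(nc) != 1L) stop("sequences must be aligned to equal codon length")
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  pairs <- combn(n, 2L)
  np <- ncol(pairs)
  Smat <- Nmat <- SDmat <- NDmat <- matrix(0, nrow = np, ncol = nc)
  for (j in seq_len(np)) {
    ca <- codons[[pairs[1, j]]]
    cb <- codons[[pairs[2, j]]]
    for (c_i in seq_len(nc)) {
      a <- ca[c_i]; b <- cb[c_i]
      if (!codon_ok(a) || !codon_ok(b)) next
      sa <- syn_sites(a); sb <- syn_sites(b)
      Smat[j, c_i] <- (sa + sb) / 2
      Nmat[j, c_i] <- 3 - (sa + sb) / 2
      d <- codon_path_diffs(a, b)
      SDmat[j, c_i] <- d[["sd"]]
      NDmat[j, c_i] <- d[["nd"]]
    }
  }
  list(S = Smat, N = Nmat, SD = SDmat, ND = NDmat, pairs = pairs,
       n_codons = nc, labels = names(seqs))
}

jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

# Mean over sequence pairs of JC-corrected pairwise dN and dS, restricted
# to codon columns `idx`.
ng86_estimate <- function(arr, idx) {
  S <- rowSums(arr$S[, idx, drop = FALSE])
  N <- rowSums(arr$N[, idx, drop = FALSE])
  SD <- rowSums(arr$SD[, idx, drop = FALSE])
  ND <- rowSums(arr$ND[, idx, drop = FALSE])
  pS <- ifelse(S > 0, SD / S, 0)
  pN <- ifelse(N > 0, ND / N, 0)
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  c(dN = mean(dN), dS = mean(dS))
}

#' Nei-Gojobori dN/dS with Jukes-Cantor correction and codon bootstrap
#'
#' Counts potential synonymous/nonsynonymous sites per NG86 (fractional
#' site counting, averaged over the two sequences of each pair) and
#' observed differences by equal-weight averaging over all minimal
#' mutational pathways; applies the Jukes-Cantor correction to the
#' per-pair proportions; reports the mean over all sequence pairs
#' (overall average). Standard errors come from resampling codon columns
#' with replacement; the z-test contrasts dN and dS against strict
#' neutrality (dN = dS).
#'
#' @param seqs Named character vector of aligned coding sequences
#'   (length divisible by 3; gaps only as whole-codon `---`).
#' @param mask Optional [build_site_mask()]; required for `partition`
#'   `"PBR"`/`"non-PBR"`.
#' @param partition `"all"`, `"PBR"` or `"non-PBR"`.
#' @param bootstrap_reps Codon-bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @param tail `"two"` (default) or `"one"` (positive selection,
#'   dN > dS) for the z-test p-value.
#' @return List of class `selection_report`: `partition`, `scheme`,
#'   `n_seq`, `n_codons`, `dN`, `dS`, `se_dN`, `se_dS`, `omega`
#'   (`NA` when `dS = 0`), `z`, `p_value`, `tail`, and
#'   `undefined` = TRUE with a `diagnostic` if any pairwise proportion
#'   reached the Jukes-Cantor divergence ceiling (p >= 3/4).
#' @export
nei_gojobori <- function(seqs, mask = NULL, partition = c("all", "PBR", "non-PBR"),
                         bootstrap_reps = 1000L, seed = 1L,
                         tail = c("two", "one")) {
  partition <- match.arg(partition)
  tail <- match.arg(tail)
  arr <- ng86_arrays(seqs)
  idx <- switch(partition,
    "all" = seq_len(arr$n_codons),
    "PBR" = {
      if (is.null(mask)) stop("partition \"PBR\" needs a site mask")
      if (mask$n_codons != arr$n_codons) stop("mask built for ", mask$n_codons,
                                              " codons, alignment has ", arr$n_codons)
      mask$pbr
    },
    "non-PBR" = {
      if (is.null(mask)) stop("partition \"non-PBR\" needs a site mask")
      if (mask$n_codons != arr$n_codons) stop("mask built for ", mask$n_codons,
                                              " codons, alignment has ", arr$n_codons)
      mask$non_pbr
    })
  if (length(idx) == 0L) stop("empty codon partition \"", partition, "\"")
  est <- ng86_estimate(arr, idx)
  undefined <- anyNA(est)
  boot <- with_seed(seed, {
    vapply(seq_len(bootstrap_reps), function(r) {
      ng86_estimate(arr, idx[sample.int(length(idx), replace = TRUE)])
    }, numeric(2))
  })
  se_dN <- sd(boot["dN", ], na.rm = TRUE)
  se_dS <- sd(boot["dS", ], na.rm = TRUE)
  zt <- codon_z_test(est[["dN"]], est[["dS"]],
                     var(boot["dN", ], na.rm = TRUE),
                     var(boot["dS", ], na.rm = TRUE), tail = tail)
  structure(list(
    partition = partition,
    scheme = if (is.null(mask)) NA_character_ else mask$scheme,
    n_seq = length(seqs), n_codons = length(idx),
    dN = est[["dN"]], dS = est[["dS"]], se_dN = se_dN, se_dS = se_dS,
    omega = if (undefined || est[["dS"]] == 0) NA_real_ else est[["dN"]] / est[["dS"]],
    z = zt$z, p_value = zt$p, tail = tail,
    bootstrap_reps = bootstrap_reps,
    undefined = undefined,
    diagnostic = if (undefined)
      "pairwise proportion >= 3/4: Jukes-Cantor distance undefined" else NA_character_
  ), class = "selection_report")
}

#' z-test of dN against dS
#'
#' `z = (dN - dS) / sqrt(var(dN) + var(dS))` with bootstrap variances; p
#' from the standard normal. `tail = "one"` tests for positive selection
#' (dN > dS), `"two"` for any departure from dN = dS. When both
#' variances are zero and dN = dS, z = 0 and p = 1.
#'
#' @param dN,dS Point estimates.
#' @param var_dN,var_dS Bootstrap variances.
#' @param tail `"two"` or `"one"`.
#' @return List with `z` and `p`.
#' @export
codon_z_test <- function(dN, dS, var_dN, var_dS, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (is.na(dN) || is.na(dS)) return(list(z = NA_real_, p = NA_real_))
  v <- var_dN + var_dS
  if (v == 0) {
    if (dN == dS) return(list(z = 0, p = 1))
    return(list(z = sign(dN - dS) * Inf, p = 0))
  }
  z <- (dN - dS) / sqrt(v)
  p <- if (tail == "two") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
  list(z = z, p = p)
}

#' Selection report over partitions and schemes
#'
#' Convenience wrapper running [nei_gojobori()] on `all`, `PBR` and
#' `non-PBR` partitions for each supplied mask, returning one tidy row
#' per partition x scheme.
#'
#' @param seqs Aligned coding sequences.
#' @param masks A single [build_site_mask()] or a list of them.
#' @param ... Passed to [nei_gojobori()].
#' @return Data frame with one row per (scheme, partition).
#' @export
selection_table <- function(seqs, masks, ...) {
  if (inherits(masks, "site_mask")) masks <- list(masks)
  rows <- list()
  add <- function(rep) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scheme = rep$scheme, partition = rep$partition, n_seq = rep$n_seq,
      n_codons = rep$n_codons, dN = rep$dN, se_dN = rep$se_dN,
      dS = rep$dS, se_dS = rep$se_dS, omega = rep$omega, z = rep$z,
      p_value = rep$p_value, stringsAsFactors = FALSE)
  }
  for (m in masks) {
    add(nei_gojobori(seqs, m, "PBR", ...))
    add(nei_gojobori(seqs, m, "non-PBR", ...))
  }
  add(nei_gojobori(seqs, partition = "all", ...))
  do.call(rbind, rows)
}
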