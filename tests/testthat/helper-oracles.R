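# Independent oracles used across the suite.

GC <- as.character(Biostrings::GENETIC_CODE)
names(GC) <- names(Biostrings::GENETIC_CODE)

# Brute-force NG86 pathway oracle: depth-first enumeration of every
# ordering of the differing positions between two codons, classifying
# each single-base step as synonymous iff the amino acid is unchanged.
# Paths visiting a stop codon are discarded; if all paths are discarded
# the stop-visiting paths are used with steps classified normally.
oracle_codon_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  paths_ok <- list(); paths_all <- list()
  walk <- function(cur, remaining, syn, non, hit_stop) {
    if (length(remaining) == 0) {
      rec <- c(syn, non)
      paths_all[[length(paths_all) + 1]] <<- rec
      if (!hit_stop) paths_ok[[length(paths_ok) + 1]] <<- rec
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      step_syn <- GC[[cur]] == GC[[nxt]]
      walk(nxt, setdiff(remaining, p),
           syn + step_syn, non + !step_syn,
           hit_stop || GC[[cur]] == "*" || GC[[nxt]] == "*")
    }
  }
  walk(a, pos, 0, 0, FALSE)
  use <- if (length(paths_ok) > 0) paths_ok else paths_all
  colMeans(do.call(rbind, use))
}

# Oracle for potential synonymous sites of a codon (fraction of the nine
# single-base changes that preserve the amino acid).
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (bb in setdiff(c("A", "C", "G", "T"), ch[p])) {
    alt <- ch; alt[p] <- bb
    if (GC[[paste(alt, collapse = "")]] == GC[[codon]]) s <- s + 1 / 3
  }
  s
}

random_sense_codon <- function() {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (GC[[cd]] != "*") return(cd)
  }
}

# Expected number of distinct alleles in a size-k subset drawn without
# replacement from a library with per-allele clone multiplicities m.
hypergeom_expected_alleles <- function(m, k) {
  total <- sum(m)
  sum(1 - choose(total - m, k) / choose(total, k))
}

# Small deterministic clone set: three individuals sharing two true
# alleles, plus a private singleton sequence.
tiny_clone_set <- function() {
  a1 <- paste(rep("ATGGCT", 10), collapse = "")   # 60 nt
  a2 <- sub("GCT", "GTT", a1, fixed = TRUE)
  solo <- sub("ATG", "CTG", a1, fixed = TRUE)
  data.frame(
    individual = c("i1", "i1", "i2", "i2", "i3", "i3"),
    clone = paste0("C", 1:6),
    sequence = c(a1, a2, a1, a2, a1, solo),
    stringsAsFactors = FALSE
  )
}
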