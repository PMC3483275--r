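#' Configuration for the clone-library simulator
#'
#' Describes the study design the simulator emulates: a pool of alleles at
#' several duplicated MHC class II beta loci shared across island
#' populations, per-individual clone libraries of plasmid-cloned PCR
#' molecules, and the two PCR artefact classes (point errors and single
#' break-point chimeras). Defaults mirror a small passerine clone-library
#' study: a 53-codon (159-bp) exon-2 amplicon, 4 functional loci, two
#' pseudogene-like alleles at a separate pseudogene locus, one allele
#' carrying an in-frame two-codon insertion, three populations of 10, 4
#' and 2 individuals, and 12-29 clones sequenced per individual.
#'
#' @param n_loci Number of functional duplicated loci.
#' @param alleles_per_locus Alleles segregating at each functional locus.
#' @param seq_codons Amplicon length in codons (159 bp = 53 codons).
#' @param n_populations Number of populations (islands).
#' @param individuals_per_population Integer vector (recycled to
#'   `n_populations`) of individuals sampled per population.
#' @param clones_per_individual Length-2 integer range; each individual's
#'   clone count is drawn uniformly from it.
#' @param pcr_error_rate Per-base substitution probability per clone.
#' @param chimera_rate Per-clone probability of a PCR chimera.
#' @param pseudogene_count Pseudogene-like alleles (internal stop codon),
#'   placed at one additional pseudogene locus.
#' @param insert_allele_count Functional alleles carrying one in-frame
#'   two-codon insertion (165 bp on a 159-bp amplicon).
#' @param sharing_fraction Minimum fraction of pool alleles that must be
#'   carried by individuals of at least two populations (retained
#'   ancestral polymorphism).
#' @param locus_divergence Substitutions separating each locus ancestor
#'   from the shared root sequence.
#' @param allele_divergence Substitutions separating each allele from its
#'   locus ancestor.
#' @param seed Master seed; every random draw in the simulator derives
#'   deterministically from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 4L,
                       alleles_per_locus = 6L,
                       seq_codons = 53L,
                       n_populations = 3L,
                       individuals_per_population = c(10L, 4L, 2L),
                       clones_per_individual = c(12L, 29L),
                       pcr_error_rate = 5e-4,
                       chimera_rate = 0.05,
                       pseudogene_count = 2L,
                       insert_allele_count = 1L,
                       sharing_fraction = 0.65,
                       locus_divergence = 12L,
                       allele_divergence = 4L,
                       seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    seq_codons = as.integer(seq_codons),
    n_populations = as.integer(n_populations),
    individuals_per_population =
      rep_len(as.integer(individuals_per_population), as.integer(n_populations)),
    clones_per_individual = as.integer(clones_per_individual),
    pcr_error_rate = pcr_error_rate,
    chimera_rate = chimera_rate,
    pseudogene_count = as.integer(pseudogene_count),
    insert_allele_count = as.integer(insert_allele_count),
    sharing_fraction = sharing_fraction,
    locus_divergence = as.integer(locus_divergence),
    allele_divergence = as.integer(allele_divergence),
    seed = as.integer(seed)
  )
  rates <- c(pcr_error_rate = cfg$pcr_error_rate,
             chimera_rate = cfg$chimera_rate,
             sharing_fraction = cfg$sharing_fraction)
  bad <- rates < 0 | rates > 1 | !is.finite(rates)
  if (any(bad)) {
    stop("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", "))
  }
  if (cfg$seq_codons < 10L) stop("seq_codons must be >= 10")
  if (cfg$n_loci < 1L) stop("n_loci must be >= 1")
  if (cfg$alleles_per_locus < 1L) stop("alleles_per_locus must be >= 1")
  if (length(cfg$clones_per_individual) != 2L ||
      any(cfg$clones_per_individual < 1L) ||
      cfg$clones_per_individual[1] > cfg$clones_per_individual[2]) {
    stop("clones_per_individual must be an increasing range of two positive integers")
  }
  if (cfg$insert_allele_count > cfg$n_loci * cfg$alleles_per_locus) {
    stop("insert_allele_count exceeds the number of functional alleles")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Random in-frame sequence with no internal stop codon.
random_orf <- function(n_codons) {
  repeat {
    codons <- replicate(n_codons, paste(sample(DNA_BASES, 3L, replace = TRUE),
                                        collapse = ""))
    if (!any(GENETIC_CODE_TABLE[codons] == "*")) return(paste(codons, collapse = ""))
  }
}

# Apply `k` random substitutions; when avoid_stops, resample any draw that
# creates an in-frame stop codon.
mutate_seq <- function(seq, k, avoid_stops = TRUE, max_tries = 1000L) {
  chars <- seq_to_chars(seq)
  done <- 0L
  tries <- 0L
  while (done < k) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place ", k, " substitutions without stop codons")
    pos <- sample.int(length(chars), 1L)
    new <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
    cand <- chars
    cand[pos] <- new
    if (avoid_stops) {
      cod <- (pos - 1L) %/% 3L
      codon <- paste(cand[(cod * 3L + 1L):(cod * 3L + 3L)], collapse = "")
      if (identical(GENETIC_CODE_TABLE[[codon]], "*")) next
    }
    chars <- cand
    done <- done + 1L
  }
  chars_to_seq(chars)
}

#' Simulate the true allele pool
#'
#' Generates `n_loci * alleles_per_locus` distinct functional in-frame
#' alleles (one shared root sequence, per-locus ancestors at
#' `locus_divergence` substitutions, alleles at `allele_divergence`
#' substitutions from their ancestor) plus `pseudogene_count`
#' pseudogene-like alleles carrying an internal stop codon, assigned to a
#' dedicated pseudogene locus. `insert_allele_count` functional alleles
#' receive one in-frame two-codon insertion at a random interior codon
#' boundary.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `name`, `locus`, `sequence`,
#'   `is_pseudogene`, `has_insert`; one row per pool allele.
#' @export
simulate_allele_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    L <- config$seq_codons * 3L
    if (config$allele_divergence == 0L && config$alleles_per_locus > 1L) {
      stop("distinct alleles unattainable with allele_divergence = 0")
    }
    root <- random_orf(config$seq_codons)
    pool <- list()
    for (l in seq_len(config$n_loci)) {
      anc <- mutate_seq(root, config$locus_divergence)
      seqs <- character(0)
      for (a in seq_len(config$alleles_per_locus)) {
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 200L) {
            stop("could not generate distinct alleles: sequence space too small ",
                 "for the requested pool (increase seq_codons or allele_divergence)")
          }
          s <- mutate_seq(anc, config$allele_divergence)
          if (!s %in% seqs && !s %in% vapply(pool, `[[`, "", "sequence")) break
        }
        seqs <- c(seqs, s)
        pool[[length(pool) + 1L]] <- list(locus = paste0("L", l), sequence = s)
      }
    }
    pool <- data.frame(
      locus = vapply(pool, `[[`, "", "locus"),
      sequence = vapply(pool, `[[`, "", "sequence"),
      stringsAsFactors = FALSE
    )
    pool$is_pseudogene <- FALSE
    pool$has_insert <- FALSE

    # In-frame two-codon insertion (6 nt at a codon boundary) in the first
    # insert_allele_count functional alleles, one per locus where possible.
    if (config$insert_allele_count > 0L) {
      idx <- seq_len(config$insert_allele_count)
      for (i in idx) {
        at <- sample.int(config$seq_codons - 1L, 1L)  # after codon `at`
        ins <- random_orf(2L)
        s <- pool$sequence[i]
        pool$sequence[i] <- paste0(substring(s, 1L, at * 3L), ins,
                                   substring(s, at * 3L + 1L, nchar(s)))
        pool$has_insert[i] <- TRUE
      }
    }

    # Pseudogene-like alleles: derived from the root, then one internal
    # codon forced to TAA. Housed at their own locus "psi".
    if (config$pseudogene_count > 0L) {
      ps <- character(0)
      for (p in seq_len(config$pseudogene_count)) {
        repeat {
          s <- mutate_seq(root, config$locus_divergence + config$allele_divergence)
          cod <- sample(2:(config$seq_codons - 1L), 1L)
          s <- paste0(substring(s, 1L, (cod - 1L) * 3L), "TAA",
                      substring(s, cod * 3L + 1L, nchar(s)))
          if (!s %in% ps && !s %in% pool$sequence) break
        }
        ps <- c(ps, s)
      }
      pool <- rbind(pool, data.frame(locus = "psi", sequence = ps,
                                     is_pseudogene = TRUE, has_insert = FALSE))
    }
    pool$name <- sprintf("Sim%02d", seq_len(nrow(pool)))
    rownames(pool) <- NULL
    pool[, c("name", "locus", "sequence", "is_pseudogene", "has_insert")]
  })
}

#' Assign multi-locus genotypes with cross-population allele sharing
#'
#' Each individual receives exactly two allele slots per locus (homozygous
#' when both slots draw the same allele). A fraction of at least
#' `sharing_fraction` of pool alleles is forced to occur in two or more
#' populations, emulating retained ancestral polymorphism; the remaining
#' alleles are private to one home population.
#'
#' @param pool Allele pool from [simulate_allele_pool()].
#' @param config The same [sim_config()].
#' @return Data frame with columns `individual`, `population`, `locus`,
#'   `allele`; two rows per individual x locus.
#' @export
assign_genotypes <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    pops <- paste0("P", seq_len(config$n_populations))
    inds <- unlist(lapply(seq_along(pops), function(p) {
      sprintf("%s_I%02d", pops[p], seq_len(config$individuals_per_population[p]))
    }))
    ind_pop <- setNames(rep(pops, config$individuals_per_population), inds)

    n_shared <- ceiling(config$sharing_fraction * nrow(pool))
    if (config$n_populations < 2L && n_shared > 0L) {
      stop("sharing_fraction > 0 is infeasible with a single population")
    }
    shared <- pool$name[sample.int(nrow(pool), n_shared)]
    home <- setNames(sample(pops, nrow(pool), replace = TRUE), pool$name)

    # Two slots per individual per locus, filled from the alleles of that
    # locus available to the individual's population.
    geno <- expand.grid(individual = inds, locus = unique(pool$locus),
                        slot = 1:2, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    geno$population <- ind_pop[geno$individual]
    geno$allele <- NA_character_
    for (i in seq_len(nrow(geno))) {
      here <- pool$name[pool$locus == geno$locus[i]]
      avail <- here[here %in% shared | home[here] == geno$population[i]]
      if (length(avail) == 0L) avail <- here
      geno$allele[i] <- avail[sample.int(length(avail), 1L)]
    }

    # Repair pass: force every designated shared allele into >= 2
    # populations by overwriting slots (keeps the <= 2 per locus rule).
    obs_pops <- function(a) unique(geno$population[geno$allele == a])
    for (iter in seq_len(50L)) {
      deficits <- shared[vapply(shared, function(a) length(obs_pops(a)) < 2L, TRUE)]
      if (length(deficits) == 0L) break
      if (iter == 50L) {
        stop("infeasible sharing_fraction: could not place every shared ",
             "allele in two populations")
      }
      for (a in deficits) {
        while (length(obs_pops(a)) < 2L) {
          loc <- pool$locus[pool$name == a]
          cand <- which(geno$locus == loc & !(geno$population %in% obs_pops(a)))
          if (length(cand) == 0L) {
            stop("infeasible sharing_fraction: no free slot for allele ", a,
                 " in a second population")
          }
          geno$allele[cand[sample.int(length(cand), 1L)]] <- a
        }
      }
    }
    geno <- geno[order(geno$individual, geno$locus, geno$slot),
                 c("individual", "population", "locus", "allele")]
    rownames(geno) <- NULL
    geno
  })
}

#' Sample per-individual clone libraries with PCR artefacts
#'
#' Each clone is one plasmid-cloned PCR molecule: with probability
#' `chimera_rate` a single-break-point chimera of two distinct genotype
#' alleles (prefix of parent A up to a uniform interior codon boundary,
#' suffix of parent B), otherwise a copy of one genotype allele with
#' i.i.d. per-base substitutions at `pcr_error_rate`. Chimeras requested
#' for individuals carrying a single distinct allele fall back to a
#' faithful copy.
#'
#' @param genotypes From [assign_genotypes()].
#' @param pool From [simulate_allele_pool()].
#' @param config The same [sim_config()].
#' @return List with `clones` (data frame `individual`, `clone`,
#'   `sequence`) and `provenance` (per-clone origin: type
#'   `faithful`/`point_error`/`chimera`, source allele or parents,
#'   error positions, break-point codon).
#' @export
sample_clone_library <- function(genotypes, pool, config) {
  stopifnot(inherits(config, "sim_config"))
  seq_of <- setNames(pool$sequence, pool$name)
  inds <- unique(genotypes$individual)
  clones <- list()
  prov <- list()
  for (k in seq_along(inds)) {
    ind <- inds[k]
    with_seed(derive_seed(config$seed, 100L + k), {
      alleles <- genotypes$allele[genotypes$individual == ind]  # multiset, 2/locus
      lo <- config$clones_per_individual[1]
      hi <- config$clones_per_individual[2]
      n <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      for (j in seq_len(n)) {
        id <- sprintf("C%03d", j)
        is_chim <- runif(1) < config$chimera_rate
        if (is_chim && length(unique(seq_of[alleles])) >= 2L) {
          repeat {
            par2 <- alleles[sample.int(length(alleles), 2L)]
            if (seq_of[par2[1]] != seq_of[par2[2]]) break
          }
          sa <- seq_of[[par2[1]]]
          sb <- seq_of[[par2[2]]]
          ncod <- min(nchar(sa), nchar(sb)) %/% 3L
          bp <- sample.int(ncod - 1L, 1L)  # after codon bp
          s <- paste0(substring(sa, 1L, bp * 3L),
                      substring(sb, bp * 3L + 1L, nchar(sb)))
          prov[[length(prov) + 1L]] <- data.frame(
            individual = ind, clone = id, type = "chimera",
            source = NA_character_, parent_a = par2[1], parent_b = par2[2],
            breakpoint_codon = bp, error_positions = NA_character_,
            stringsAsFactors = FALSE)
        } else {
          a <- alleles[sample.int(length(alleles), 1L)]
          s <- seq_of[[a]]
          hits <- which(runif(nchar(s)) < config$pcr_error_rate)
          if (length(hits) > 0L) {
            ch <- seq_to_chars(s)
            for (p in hits) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
            s <- chars_to_seq(ch)
          }
          prov[[length(prov) + 1L]] <- data.frame(
            individual = ind, clone = id,
            type = if (length(hits) > 0L) "point_error" else "faithful",
            source = a, parent_a = NA_character_, parent_b = NA_character_,
            breakpoint_codon = NA_integer_,
            error_positions = if (length(hits) > 0L)
              paste(hits, collapse = ",") else NA_character_,
            stringsAsFactors = FALSE)
        }
        clones[[length(clones) + 1L]] <- data.frame(
          individual = ind, clone = id, sequence = s, stringsAsFactors = FALSE)
      }
    })
  }
  list(clones = do.call(rbind, clones), provenance = do.call(rbind, prov))
}

#' Run the full simulator
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `pool`, `genotypes`, `clones`,
#'   `provenance`, `population_map` (individual -> population), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  pool <- simulate_allele_pool(config)
  geno <- assign_genotypes(pool, config)
  lib <- sample_clone_library(geno, pool, config)
  pop_map <- unique(geno[, c("individual", "population")])
  rownames(pop_map) <- NULL
  structure(list(pool = pool, genotypes = geno, clones = lib$clones,
                 provenance = lib$provenance, population_map = pop_map,
                 config = config),
            class = "sim_dataset")
}

#' Write clone records as FASTA
#'
#' Headers follow the convention `IND:<individual>|CLONE:<clone>`.
#'
#' @param clones Data frame with `individual`, `clone`, `sequence`.
#' @param path Output file.
#' @export
write_clone_fasta <- function(clones, path) {
  x <- Biostrings::DNAStringSet(clones$sequence)
  names(x) <- sprintf("IND:%s|CLONE:%s", clones$individual, clones$clone)
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Read clone records from FASTA
#'
#' Accepts the `IND:<id>|CLONE:<id>` header convention; other headers are
#' taken as clone IDs of a single unknown individual unless `id_map` (a
#' data frame `record` -> `individual`) is given.
#'
#' @param path FASTA file.
#' @param id_map Optional data frame with columns `record`, `individual`.
#' @return Data frame `individual`, `clone`, `sequence`.
#' @export
read_clone_fasta <- function(path, id_map = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  m <- regmatches(hdr, regexec("^IND:([^|]+)\\|CLONE:(.+)$", hdr))
  ok <- lengths(m) == 3L
  ind <- clone <- character(length(hdr))
  ind[ok] <- vapply(m[ok], `[[`, "", 2L)
  clone[ok] <- vapply(m[ok], `[[`, "", 3L)
  if (any(!ok)) {
    clone[!ok] <- hdr[!ok]
    if (!is.null(id_map)) {
      ind[!ok] <- id_map$individual[match(hdr[!ok], id_map$record)]
      if (anyNA(ind[!ok])) stop("records missing from id_map: ",
                                paste(hdr[!ok][is.na(ind[!ok])], collapse = ", "))
    } else {
      ind[!ok] <- "unknown"
    }
  }
  data.frame(individual = ind, clone = clone,
             sequence = toupper(as.character(x)), stringsAsFactors = FALSE)
}
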