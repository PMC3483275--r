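test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(pcr_error_rate = 1.5), "rates")
  expect_error(sim_config(sharing_fraction = -0.1), "rates")
  expect_error(sim_config(seq_codons = 5), "seq_codons")
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(clones_per_individual = c(10, 5)), "range")
})

test_that("allele pool has the requested structure", {
  cfg <- sim_config(n_loci = 4, alleles_per_locus = 6, pseudogene_count = 2,
                    insert_allele_count = 1, seed = 11)
  pool <- simulate_allele_pool(cfg)
  expect_equal(nrow(pool), 4 * 6 + 2)
  expect_equal(sum(pool$is_pseudogene), 2)
  # pseudogenes carry an internal stop in the fixed frame
  for (s in pool$sequence[pool$is_pseudogene]) {
    expect_true(grepl("*", translate_frame(s), fixed = TRUE))
  }
  # functional alleles translate cleanly
  for (s in pool$sequence[!pool$is_pseudogene]) {
    expect_false(grepl("*", translate_frame(s), fixed = TRUE))
  }
  # exactly one insert-carrying allele of 165 nt, all others 159
  lens <- nchar(pool$sequence)
  expect_equal(sum(lens == 165), 1)
  expect_equal(sum(lens == 159), nrow(pool) - 1)
  expect_true(pool$has_insert[lens == 165])
  # all sequences distinct; within-locus alleles differ
  expect_equal(anyDuplicated(pool$sequence), 0L)
})

test_that("pool generation rejects unattainable distinctness", {
  expect_error(simulate_allele_pool(sim_config(allele_divergence = 0,
                                               alleles_per_locus = 3)),
               "distinct")
})

test_that("simulator output is seed-deterministic", {
  d1 <- simulate_dataset(sim_config(seed = 42))
  d2 <- simulate_dataset(sim_config(seed = 42))
  expect_identical(d1$pool, d2$pool)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$clones, d2$clones)
  expect_identical(d1$provenance, d2$provenance)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_clone_fasta(d1$clones, f1); write_clone_fasta(d2$clones, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- simulate_dataset(sim_config(seed = 43))
  expect_false(identical(d1$clones$sequence, d3$clones$sequence))
})

test_that("genotypes respect locus and sharing constraints", {
  cfg <- sim_config(seed = 5)
  pool <- simulate_allele_pool(cfg)
  geno <- assign_genotypes(pool, cfg)
  # every assigned allele exists in the pool
  expect_true(all(geno$allele %in% pool$name))
  # at most 2 alleles per locus per individual (exactly 2 slots)
  per <- table(geno$individual, geno$locus)
  expect_true(all(per == 2))
  # distinct functional alleles per individual within [n_loci, 2 n_loci]
  fun <- geno[geno$allele %in% pool$name[!pool$is_pseudogene], ]
  counts <- tapply(fun$allele, fun$individual, function(x) length(unique(x)))
  expect_true(all(counts >= cfg$n_loci & counts <= 2 * cfg$n_loci))
  # sharing fraction respected
  pops_of <- tapply(geno$population, geno$allele, function(x) length(unique(x)))
  assigned <- names(pops_of)
  expect_gte(sum(pops_of >= 2) / nrow(pool), cfg$sharing_fraction)
})

test_that("sharing_fraction = 1 forces every allele into >= 2 populations", {
  cfg <- sim_config(sharing_fraction = 1, seed = 8)
  pool <- simulate_allele_pool(cfg)
  geno <- assign_genotypes(pool, cfg)
  pops_of <- tapply(geno$population, geno$allele, function(x) length(unique(x)))
  expect_true(all(pool$name %in% names(pops_of)))
  expect_true(all(pops_of >= 2))
})

test_that("infeasible sharing is an explicit error", {
  cfg <- sim_config(n_populations = 1, individuals_per_population = 2,
                    sharing_fraction = 0.5, seed = 1)
  pool <- simulate_allele_pool(cfg)
  expect_error(assign_genotypes(pool, cfg), "infeasible|single population")
})

test_that("artefact-free clone libraries copy genotypes exactly", {
  cfg <- sim_config(pcr_error_rate = 0, chimera_rate = 0, seed = 3,
                    individuals_per_population = 2,
                    clones_per_individual = c(200, 200))
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$provenance$type == "faithful"))
  seq_of <- setNames(ds$pool$sequence, ds$pool$name)
  for (ind in unique(ds$clones$individual)) {
    got <- sort(unique(ds$clones$sequence[ds$clones$individual == ind]))
    want <- sort(unique(unname(
      seq_of[ds$genotypes$allele[ds$genotypes$individual == ind]])))
    # 200 clones over <= 10 genotype slots: every allele is sampled
    expect_identical(got, want)
  }
  # conservation: clone totals within configured range, per individual
  tab <- table(ds$clones$individual)
  expect_true(all(tab == 200))
  expect_equal(nrow(ds$clones), sum(tab))
})

test_that("chimeras are single-breakpoint codon-boundary splices of genotype alleles", {
  cfg <- sim_config(chimera_rate = 0.5, pcr_error_rate = 0, seed = 21)
  ds <- simulate_dataset(cfg)
  chim <- ds$provenance[ds$provenance$type == "chimera", ]
  expect_gt(nrow(chim), 0)
  seq_of <- setNames(ds$pool$sequence, ds$pool$name)
  for (r in seq_len(nrow(chim))) {
    with(chim[r, ], {
      # parents belong to that individual's genotype
      g <- ds$genotypes$allele[ds$genotypes$individual == individual]
      expect_true(parent_a %in% g && parent_b %in% g)
      sa <- seq_of[[parent_a]]; sb <- seq_of[[parent_b]]
      s <- ds$clones$sequence[ds$clones$individual == individual &
                                ds$clones$clone == clone]
      expect_identical(s, paste0(substr(sa, 1, breakpoint_codon * 3),
                                 substr(sb, breakpoint_codon * 3 + 1, nchar(sb))))
    })
  }
})

test_that("point-error counts match the binomial expectation", {
  # one individual, 10,000 clones at 1e-3/base on 159 nt: mean errors per
  # clone ~ Binomial(159, 1e-3) expectation 0.159, checked within 3 SDs
  cfg <- sim_config(n_populations = 1, individuals_per_population = 1,
                    n_loci = 1, alleles_per_locus = 2, pseudogene_count = 0,
                    insert_allele_count = 0, sharing_fraction = 0,
                    clones_per_individual = c(10000, 10000),
                    pcr_error_rate = 1e-3, chimera_rate = 0, seed = 13)
  ds <- simulate_dataset(cfg)
  n_err <- ifelse(is.na(ds$provenance$error_positions), 0,
                  lengths(strsplit(ds$provenance$error_positions, ",")))
  expect_equal(nrow(ds$provenance), 10000)
  expected <- 159 * 1e-3
  se3 <- 3 * sqrt(159 * 1e-3 * (1 - 1e-3) / 10000)
  expect_lt(abs(mean(n_err) - expected), se3)
})

test_that("chimera breakpoints are uniform over interior codon boundaries", {
  cfg <- sim_config(n_populations = 2, individuals_per_population = 1,
                    n_loci = 1, alleles_per_locus = 2, pseudogene_count = 0,
                    insert_allele_count = 0, sharing_fraction = 1,
                    clones_per_individual = c(5000, 5000),
                    pcr_error_rate = 0, chimera_rate = 1, seed = 17)
  ds <- simulate_dataset(cfg)
  bp <- ds$provenance$breakpoint_codon[ds$provenance$type == "chimera"]
  expect_gte(length(bp), 9000)
  expect_true(all(bp >= 1 & bp <= 52))
  gof <- chisq.test(table(factor(bp, levels = 1:52)))
  expect_gt(gof$p.value, 0.01)
})

test_that("clone FASTA round-trips with the header convention", {
  ds <- simulate_dataset(sim_config(seed = 2, individuals_per_population = 2))
  f <- tempfile(fileext = ".fasta")
  write_clone_fasta(ds$clones, f)
  back <- read_clone_fasta(f)
  expect_equal(back, ds$clones, ignore_attr = TRUE)
})
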