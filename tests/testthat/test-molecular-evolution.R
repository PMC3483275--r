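test_that("nucleotide diversity matches its definition", {
  same <- setNames(rep(strrep("ACGT", 10), 4), paste0("s", 1:4))
  expect_equal(nucleotide_diversity(same), 0)
  a <- paste(c(rep("A", 98), "C", "G"), collapse = "")
  b <- paste(rep("A", 100), collapse = "")
  expect_equal(nucleotide_diversity(c(x = a, y = b)), 0.02)
  expect_error(nucleotide_diversity(c(x = a)), "at least 2")
  # gapped positions excluded pairwise
  g1 <- "AC-TAC"
  g2 <- "ACGTAC"
  g3 <- "ACGTAG"
  # pairs: (g1,g2): 0/5; (g1,g3): 1/5; (g2,g3): 1/6
  expect_equal(nucleotide_diversity(c(a = g1, b = g2, c = g3)),
               mean(c(0, 1 / 5, 1 / 6)))
})

test_that("Tajima's D matches direct evaluation of the published formula", {
  # n = 4, three singleton columns: S = 3, k = 1.5
  aln <- c(a = "AAA", b = "GAA", c = "AGA", d = "AAG")
  td <- tajimas_d(aln)
  n <- 4; S <- 3; k <- 1.5
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  expect_equal(td$statistic, (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
  expect_equal(td$S, 3L)
  expect_equal(td$k, 1.5)
})

test_that("Tajima's D is positive for intermediate-frequency variants and undefined at S = 0", {
  # every segregating site splits the n = 4 sample 2|2
  aln <- c(a = "AAAA", b = "AAAA", c = "GGGG", d = "GGGG")
  expect_gt(tajimas_d(aln)$statistic, 0)
  mono <- setNames(rep("ACGTACGT", 5), paste0("s", 1:5))
  td <- tajimas_d(mono)
  expect_true(is.na(td$statistic))
  expect_match(td$significance, "undefined")
  expect_error(tajimas_d(c(a = "A", b = "C", c = "G")), "at least 4")
})

test_that("Fu & Li's D*/F* match direct evaluation and sign expectations", {
  # n = 5, eta = 4, eta_s = 1: three 2|3 sites plus one singleton site
  aln <- c(s1 = "AAAG", s2 = "AAAA", s3 = "GGGA", s4 = "GGGA", s5 = "AAAA")
  sp <- mhcclone:::site_spectrum(aln)
  expect_equal(sp$eta, 4L)
  expect_equal(sp$eta_s, 1L)
  fl <- fu_li_star_tests(aln)
  n <- 5; eta <- 4; eta_s <- 1
  k <- fl$k
  an <- sum(1 / (1:4)); bn <- sum(1 / (1:4)^2); an1 <- an + 1 / 5
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  expect_equal(fl$D_star,
               ((n / (n - 1)) * eta - an * eta_s) / sqrt(uD * eta + vD * eta^2))
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  expect_equal(fl$F_star,
               (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2))
  # all-singleton alignment: singleton excess drives D* negative
  sing <- c(a = "AAAA", b = "GAAA", c = "AGAA", d = "AAGA", e = "AAAG")
  expect_lt(fu_li_star_tests(sing)$D_star, 0)
  # undefined at S = 0
  expect_true(is.na(fu_li_star_tests(setNames(rep("AAAA", 5),
                                              letters[1:5]))$D_star))
})

test_that("neutral coalescent alignments centre the neutrality statistics near zero", {
  set.seed(400)
  stats <- vapply(1:80, function(i) {
    a <- sim_coalescent_alignment(15, theta = 5, seed = 4000 + i)
    td <- tajimas_d(a)
    fl <- fu_li_star_tests(a)
    c(td$statistic, fl$D_star, fl$F_star)
  }, numeric(3))
  expect_lt(abs(mean(stats[1, ], na.rm = TRUE)), 0.25)
  expect_lt(abs(mean(stats[2, ], na.rm = TRUE)), 0.35)
  expect_lt(abs(mean(stats[3, ], na.rm = TRUE)), 0.35)
})

test_that("site masks partition the codons exhaustively", {
  expect_equal(build_site_mask(10)$non_pbr, 1:10)
  full <- build_site_mask(10, 1:10, "all-pbr")
  expect_equal(full$pbr, 1:10)
  expect_length(full$non_pbr, 0)
  m1 <- build_site_mask(53, c(3, 9, 20), "a")
  m2 <- build_site_mask(53, c(5, 9, 40, 41), "b")
  for (m in list(m1, m2)) {
    expect_length(intersect(m$pbr, m$non_pbr), 0)
    expect_setequal(c(m$pbr, m$non_pbr), 1:53)
  }
  expect_error(build_site_mask(53, c(10, 54)), "54")
  f <- system.file("extdata", "pbr_brown_synthetic.tsv", package = "mhcclone")
  mk <- read_site_mask(f, 53)
  expect_s3_class(mk, "site_mask")
  expect_true(all(mk$pbr >= 1 & mk$pbr <= 53))
})

test_that("NG86 gives dN = dS = 0 for identical sequences and the fourfold-site value", {
  s <- strrep("GGTATC", 5)
  r0 <- nei_gojobori(setNames(c(s, s), c("a", "b")), bootstrap_reps = 10)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  # 30 glycine codons; one synonymous third-position change. Each GGN
  # codon has exactly 1 synonymous site, so S = 30 and pS = 1/30.
  s1 <- strrep("GGT", 30)
  s2 <- paste0(strrep("GGT", 29), "GGC")
  r <- nei_gojobori(c(a = s1, b = s2), bootstrap_reps = 50, seed = 1)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, -0.75 * log(1 - (4 / 3) * (1 / 30)))
})

test_that("NG86 pathway counting matches brute-force enumeration", {
  set.seed(77)
  for (i in 1:200) {
    a <- random_sense_codon()
    b <- random_sense_codon()
    got <- mhcclone:::codon_path_diffs(a, b)
    want <- oracle_codon_diffs(a, b)
    expect_equal(unname(got), unname(want),
                 info = paste(a, b))
    expect_equal(mhcclone:::syn_sites(a), oracle_syn_sites(a))
  }
})

test_that("NG86 site counts are additive over PBR/non-PBR partitions", {
  ds <- simulate_dataset(sim_config(seed = 12))
  v <- validate_clones(ds$clones)
  fun <- v$alleles$sequence[v$alleles$functional_flag == "functional"]
  fun <- fun[nchar(fun) == 159]
  seqs <- setNames(fun, paste0("a", seq_along(fun)))
  arr <- mhcclone:::ng86_arrays(seqs)
  mask <- build_site_mask(53, c(2, 7, 9, 13, 25, 30, 44), "test")
  S_all <- rowSums(arr$S)
  expect_equal(rowSums(arr$S[, mask$pbr]) + rowSums(arr$S[, mask$non_pbr]), S_all)
  expect_equal(rowSums(arr$N[, mask$pbr]) + rowSums(arr$N[, mask$non_pbr]),
               rowSums(arr$N))
  # and dN, dS are invariant to sequence order
  r1 <- nei_gojobori(seqs, bootstrap_reps = 10, seed = 4)
  r2 <- nei_gojobori(rev(seqs), bootstrap_reps = 10, seed = 4)
  expect_equal(r1$dN, r2$dN)
  expect_equal(r1$dS, r2$dS)
})

test_that("dN and dS grow monotonically under added substitutions", {
  # start from identity and add third-position synonymous changes, then
  # first-position nonsynonymous ones
  base <- strrep("GGTATCCTG", 4)  # 12 codons
  syn1 <- paste0(substr(base, 1, 2), "C", substr(base, 4, nchar(base)))
  r0 <- nei_gojobori(c(a = base, b = base), bootstrap_reps = 5)
  r1 <- nei_gojobori(c(a = base, b = syn1), bootstrap_reps = 5)
  expect_gt(r1$dS, r0$dS)
  non1 <- paste0("T", substr(syn1, 2, nchar(syn1)))
  r2 <- nei_gojobori(c(a = base, b = non1), bootstrap_reps = 5)
  expect_gt(r2$dN, r1$dN)
  expect_true(all(c(r1$dN, r1$dS, r2$dN, r2$dS) >= 0))
})

test_that("codon bootstrap is seed-deterministic and the z-test follows the normal", {
  ds <- simulate_dataset(sim_config(seed = 19, individuals_per_population = 2))
  v <- validate_clones(ds$clones)
  fun <- v$alleles$sequence[v$alleles$functional_flag == "functional"]
  fun <- fun[nchar(fun) == 159]
  seqs <- setNames(fun, paste0("a", seq_along(fun)))
  ra <- nei_gojobori(seqs, bootstrap_reps = 100, seed = 7)
  rb <- nei_gojobori(seqs, bootstrap_reps = 100, seed = 7)
  expect_equal(ra$se_dN, rb$se_dN)
  expect_equal(ra$z, rb$z)
  # z-test quantiles
  zt <- codon_z_test(0.3, 0.1, 0.005, 0.005, tail = "one")
  expect_equal(zt$z, 2)
  expect_equal(zt$p, pnorm(2, lower.tail = FALSE), tolerance = 1e-12)
  zt2 <- codon_z_test(0.2, 0.2, 0, 0)
  expect_equal(zt2$z, 0)
  expect_equal(zt2$p, 1)
})

test_that("selection_table reports one row per scheme and partition", {
  ds <- simulate_dataset(sim_config(seed = 23, individuals_per_population = 2))
  v <- validate_clones(ds$clones)
  fun <- v$alleles$sequence[v$alleles$functional_flag == "functional"]
  fun <- fun[nchar(fun) == 159]
  seqs <- setNames(fun, paste0("a", seq_along(fun)))
  m1 <- build_site_mask(53, c(7, 9, 12, 25, 31, 46), "schemeA")
  m2 <- build_site_mask(53, c(3, 9, 14, 28, 40), "schemeB")
  tab <- selection_table(seqs, list(m1, m2), bootstrap_reps = 30, seed = 2)
  expect_equal(nrow(tab), 5)  # 2 schemes x 2 partitions + all
  expect_setequal(unique(tab$partition), c("PBR", "non-PBR", "all"))
  expect_true(all(tab$dN >= 0 & tab$dS >= 0, na.rm = TRUE))
})
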