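test_that("the three-locus worked trio reproduces its hand-computed scores", {
  sc <- compute_haplotypic_pgs(toy_trio(), toy_weights())
  f <- sc$families
  expect_equal(f$pgs_t_p, 0.7)
  expect_equal(f$pgs_nt_p, 0.2)
  expect_equal(f$pgs_t_m, -0.1)
  expect_equal(f$pgs_nt_m, -0.3)
  expect_equal(f$pgs_t_p + f$pgs_t_m, 0.6)      # child full PGS
  expect_identical(sc$qc$n_loci_used, 3L)
  expect_identical(sc$qc$n_dropped_mendelian, 0L)
})

test_that("homozygous-reference samples score zero everywhere", {
  tt <- toy_trio()
  for (who in c("father", "mother", "child"))
    tt[[who]] <- list(H1 = matrix(0L, 1, 3), H2 = matrix(0L, 1, 3))
  f <- compute_haplotypic_pgs(tt, toy_weights())$families
  expect_true(all(unlist(f[, -1]) == 0))
})

test_that("simulated genotypes round-trip through VCF and reproduce stored scores", {
  sim <- quick_sim(n = 300, gens = 3, seed = 51, n_loci = 120)
  vcf <- tempfile(fileext = ".vcf")
  wtf <- tempfile(fileext = ".tsv")
  write_trio_vcf(sim$genotypes, vcf)
  write_weight_table(sim$weights, wtf)
  trios <- read_trio_vcf(vcf)
  sc <- compute_haplotypic_pgs(trios, read_weight_table(wtf))
  ord <- match(sim$families$family_id, sc$families$family_id)
  for (col in c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m"))
    expect_equal(sc$families[[col]][ord], sim$families[[col]],
                 tolerance = 1e-12)
  expect_true(all(sc$qc$n_dropped_mendelian == 0))
})

test_that("transmitted/nontransmitted sums reproduce full PGSs exactly", {
  sim <- quick_sim(n = 400, gens = 2, seed = 52, n_loci = 150)
  g <- sim$genotypes
  sc <- compute_haplotypic_pgs(g, sim$weights)
  f <- sc$families
  beta <- sim$weights$beta
  child_full <- as.numeric((g$child$H1 + g$child$H2) %*% beta)
  father_full <- as.numeric((g$father$H1 + g$father$H2) %*% beta)
  mother_full <- as.numeric((g$mother$H1 + g$mother$H2) %*% beta)
  expect_equal(f$pgs_t_p + f$pgs_t_m, child_full, tolerance = 1e-12)
  expect_equal(f$pgs_t_p + f$pgs_nt_p, father_full, tolerance = 1e-12)
  expect_equal(f$pgs_t_m + f$pgs_nt_m, mother_full, tolerance = 1e-12)
})

test_that("scoring is invariant to weight-table row order", {
  sim <- quick_sim(n = 100, gens = 2, seed = 53, n_loci = 60)
  w <- sim$weights
  f1 <- compute_haplotypic_pgs(sim$genotypes, w)$families
  f2 <- compute_haplotypic_pgs(sim$genotypes,
                               w[sample(nrow(w)), ])$families
  expect_equal(f1, f2)
})

test_that("swapping effect/other alleles with a sign flip shifts scores by the known constant", {
  sim <- quick_sim(n = 100, gens = 2, seed = 54, n_loci = 60)
  w <- sim$weights
  swap <- seq(1, nrow(w), by = 2)
  w2 <- w
  w2$effect_allele[swap] <- w$other_allele[swap]
  w2$other_allele[swap] <- w$effect_allele[swap]
  w2$beta[swap] <- -w$beta[swap]
  f1 <- compute_haplotypic_pgs(sim$genotypes, w)$families
  f2 <- compute_haplotypic_pgs(sim$genotypes, w2)$families
  shift <- -sum(w$beta[swap])   # each haplotypic score moves by this
  for (col in c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m")) {
    expect_equal(f2[[col]], f1[[col]] + shift, tolerance = 1e-12)
    expect_equal(stats::var(f2[[col]]), stats::var(f1[[col]]),
                 tolerance = 1e-12)
  }
  # the transmitted-minus-nontransmitted contrast is exactly invariant
  expect_equal(f2$pgs_t_p - f2$pgs_nt_p, f1$pgs_t_p - f1$pgs_nt_p,
               tolerance = 1e-12)
})

test_that("Mendelian-inconsistent loci are dropped and counted; bad trios are dropped", {
  sim <- quick_sim(n = 50, gens = 2, seed = 55, n_loci = 100)
  g <- sim$genotypes
  # corrupt one locus of trio 1: child paternal allele carried by neither
  # father haplotype
  l <- which(g$father$H1[1, ] == 0 & g$father$H2[1, ] == 0)[1]
  g$child$H1[1, l] <- 1L
  sc <- compute_haplotypic_pgs(g, sim$weights)
  expect_identical(sc$qc$n_dropped_mendelian[1], 1L)
  expect_identical(sum(sc$qc$n_dropped_mendelian[-1]), 0L)
  # corrupting > 1% of loci drops the trio with a warning
  bad <- which(g$father$H1[2, ] == 0 & g$father$H2[2, ] == 0)[1:3]
  g$child$H1[2, bad] <- 1L
  expect_warning(sc2 <- compute_haplotypic_pgs(g, sim$weights),
                 "dropped")
  expect_false(g$family_id[2] %in% sc2$families$family_id)
})

test_that("allele mismatches against the weight table are dropped and counted", {
  tt <- toy_trio()
  w <- toy_weights()
  w$effect_allele[2] <- "T"   # neither ref nor alt
  sc <- compute_haplotypic_pgs(tt, w)
  expect_identical(sc$qc$n_dropped_allele_mismatch, 1L)
  expect_equal(sc$families$pgs_t_p, 0.5)   # rs2 excluded
})

test_that("unphased genotypes are a hard error", {
  sim <- quick_sim(n = 5, gens = 2, seed = 56, n_loci = 10)
  vcf <- tempfile(fileext = ".vcf")
  write_trio_vcf(sim$genotypes, vcf)
  lines <- readLines(vcf)
  lines[length(lines)] <- gsub("|", "/", lines[length(lines)], fixed = TRUE)
  writeLines(lines, vcf)
  expect_error(read_trio_vcf(vcf), "unphased|phased")
})
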