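mc_se_cov <- function(x, y) stats::sd(x * y) / sqrt(length(x))

test_that("nontransmitted scores are unrelated to the offspring absent transmission and assortment", {
  sim <- quick_sim(n = 30000, f = 0, r_mate = 0, gens = 6, seed = 11)
  f <- sim$families
  cv <- stats::cov(f$pgs_nt_p, f$y_o)
  expect_lt(abs(cv), 3 * mc_se_cov(f$pgs_nt_p - mean(f$pgs_nt_p),
                                   f$y_o - mean(f$y_o)))
})

test_that("vertical transmission produces the equilibrium nurture covariance", {
  sim <- quick_sim(n = 60000, f = 0.2, r_mate = 0, gens = 15, seed = 12)
  fam <- sim$families
  eq <- truth_for(sim$config)
  cv <- stats::cov(fam$pgs_nt_p, fam$y_o)
  # model: cov(PGS_NT, Y_o) = f * theta = f * (delta * V_h + w)
  expect_equal(cv, eq$f * eq$theta,
               tolerance = 4 * mc_se_cov(fam$pgs_nt_p, fam$y_o) /
                 abs(eq$f * eq$theta))
})

test_that("assortative mating builds spousal and cross-haplotype covariance", {
  sim <- quick_sim(n = 30000, f = 0.15, r_mate = 0.3, gens = 10, seed = 13)
  fam <- sim$families
  expect_lt(abs(stats::cor(fam$y_p, fam$y_m) - 0.3), 0.02)
  expect_gt(stats::cov(fam$pgs_t_p, fam$pgs_nt_p),
            3 * mc_se_cov(fam$pgs_t_p, fam$pgs_nt_p))
})

test_that("mate pairing hits its target correlation", {
  set.seed(21)
  x <- rnorm(10000); y <- rnorm(10000)
  i0 <- assort_mates(x, y, 0)
  expect_lt(abs(stats::cor(x, y[i0])), 0.05)
  i99 <- assort_mates(x, y, 0.99)
  expect_equal(stats::cor(x, y[i99]), 0.99, tolerance = 0.02)
  im <- assort_mates(x, y, -0.5)
  expect_equal(stats::cor(x, y[im]), -0.5, tolerance = 0.04)
  expect_error(assort_mates(x, y[1:10], 0.3), "equal size")
  expect_error(assort_mates(rep(1, 100), rnorm(100), 0.3), "degenerate")
})

test_that("social-basis assortment attenuates the phenotypic spousal correlation", {
  sim <- quick_sim(n = 30000, f = 0.2, r_mate = 0.4, gens = 10, seed = 14,
                   mating_basis = "social")
  fam <- sim$families
  r_ph <- stats::cor(fam$y_p, fam$y_m)
  expect_gt(r_ph, 0.03)
  expect_lt(r_ph, 0.4 - 0.05)
})

test_that("Mendelian transmission has the right per-locus and variance behaviour", {
  set.seed(31)
  # homozygous parent: transmitted equals nontransmitted
  tr <- transmit(h1 = c(1L, 0L, 1L), h2 = c(1L, 0L, 1L))
  expect_identical(tr$transmitted, tr$nontransmitted)
  # heterozygous single locus: effect allele transmitted half the time
  picks <- replicate(10000, transmit(1L, 0L)$transmitted)
  expect_equal(mean(picks), 0.5, tolerance = 0.02)
  # many loci: segregation variance of the haplotypic PGS given the parent
  # equals sum(beta^2 * het) / 4
  L <- 300
  beta <- rnorm(L, 0, 0.1)
  h1 <- rbinom(L, 1, 0.4); h2 <- rbinom(L, 1, 0.4)
  scores <- replicate(4000, sum(beta * transmit(h1, h2)$transmitted))
  expect_equal(stats::var(scores), sum(beta^2 * (h1 != h2)) / 4,
               tolerance = 0.12)
  expect_error(transmit(matrix(0L, 2, 3), matrix(0L, 2, 4)), "ragged")
})

test_that("Gaussian-score and allele-level modes agree on second moments", {
  base <- list(n = 25000, delta = 0.3, f = 0.15, r_mate = 0.3,
               pgs_r2 = 0.3, gens = 8)
  s_g <- quick_sim(n = base$n, delta = base$delta, f = base$f,
                   r_mate = base$r_mate, pgs_r2 = base$pgs_r2,
                   gens = base$gens, seed = 41)
  s_a <- quick_sim(n = base$n, delta = base$delta, f = base$f,
                   r_mate = base$r_mate, pgs_r2 = base$pgs_r2,
                   gens = base$gens, seed = 42, n_loci = 400)
  fg <- s_g$families; fa <- s_a$families
  moments <- function(f) c(v = stats::var(f$pgs_t_p),
                           g = stats::cov(f$pgs_t_p, f$pgs_nt_p),
                           cty = stats::cov(f$pgs_t_p, f$y_o),
                           vy = stats::var(f$y_o))
  mg <- moments(fg); ma <- moments(fa)
  se <- sqrt(c(v = 2 * mg["v"]^2, g = mg["v"]^2 + mg["g"]^2,
               cty = mg["v"] * mg["vy"] + mg["cty"]^2,
               vy = 2 * mg["vy"]^2) * 2 / base$n)
  expect_true(all(abs(mg - ma) < 4 * se))
})

test_that("simulation output is reproducible under a fixed seed", {
  a <- quick_sim(n = 500, gens = 4, seed = 99)$families
  b <- quick_sim(n = 500, gens = 4, seed = 99)$families
  expect_identical(a, b)
})

test_that("infeasible configurations are rejected", {
  expect_error(sempgs_sim_config(n_families = 100, delta = 0.3,
                                 pgs_r2 = 0.5, h2 = 0.3), "pgs_r2")
  expect_error(sempgs_sim_config(n_families = 100, delta = 0.3,
                                 pgs_r2 = 0.3, r_mate = 1), "r_mate")
  expect_error(sempgs_sim_config(n_families = 0, delta = 0.3, pgs_r2 = 0.3),
               "n_families")
})
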