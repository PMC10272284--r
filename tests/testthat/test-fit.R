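moment_matched_families <- function(n, params, variant, seed = 1) {
  set.seed(seed)
  S <- unclass(expected_covariance(params, variant))
  X <- MASS::mvrnorm(n, mu = rep(0, ncol(S)), Sigma = S, empirical = TRUE)
  colnames(X) <- colnames(S)
  as.data.frame(X)
}

test_that("moment-matched data recover the generating parameters exactly", {
  vt <- sempgs_variant("equilibrium_constrained")
  truth <- c(delta = 0.3, f = 0.15, mu = 0.18, V_eps = 0.7)
  eq <- derive_equilibrium(delta = truth[["delta"]], f = truth[["f"]],
                           mu = truth[["mu"]], V_h = 0.5,
                           V_eps = truth[["V_eps"]])
  p <- sempgs_params(delta = truth[["delta"]], f = truth[["f"]], g = eq$g,
                     w = eq$w, mu = truth[["mu"]], V_eps = truth[["V_eps"]],
                     V_h = 0.5)
  fam <- moment_matched_families(4000, p, sempgs_variant("equilibrium_free"),
                                 seed = 61)
  fit <- fit_sempgs(fam, vt)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[names(truth)]), unname(truth),
               tolerance = 2e-3)
  expect_equal(unname(fit$derived[["V_F"]]), eq$V_F, tolerance = 1e-2)
  # the free variant needs the 7-variable system to identify g and w
  vt7 <- sempgs_variant("equilibrium_free", parental_phenotypes = TRUE)
  fam7 <- moment_matched_families(4000, p, vt7, seed = 61)
  fit_free <- fit_sempgs(fam7, vt7)
  expect_equal(unname(fit_free$estimates[["g"]]), eq$g, tolerance = 5e-3)
  expect_equal(unname(fit_free$estimates[["w"]]), eq$w, tolerance = 5e-3)
})

test_that("the likelihood is locally optimal at the truth on moment-matched data", {
  vt <- sempgs_variant("equilibrium_free")
  eq <- derive_equilibrium(delta = 0.3, f = 0.15, mu = 0.18, V_h = 0.5,
                           V_eps = 0.7)
  p <- sempgs_params(delta = 0.3, f = 0.15, g = eq$g, w = eq$w, mu = 0.18,
                     V_eps = 0.7, V_h = 0.5)
  fam <- moment_matched_families(2000, p, vt, seed = 62)
  fd <- sempgs:::prepare_fiml_data(fam, vt)
  n2ll <- function(free) sempgs:::fiml_neg2ll(
    sempgs:::sigma_from_free(free, vt, fd$s2hap), fd$patterns)
  truth <- list(delta = 0.3, f = 0.15, mu = 0.18, g = eq$g, w = eq$w,
                V_eps = 0.7)
  base <- n2ll(truth)
  set.seed(63)
  for (i in 1:20) {
    pert <- truth
    j <- sample(names(truth), 1)
    pert[[j]] <- pert[[j]] + runif(1, -0.05, 0.05)
    v <- tryCatch(n2ll(pert), error = function(e) Inf)
    expect_gte(v + 1e-6, base)
  }
})

test_that("estimates are invariant under paternal/maternal column swap", {
  sim <- quick_sim(n = 8000, gens = 12, seed = 64)
  fam <- sim$families
  swapped <- fam
  swapped[, c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m", "y_p", "y_m")] <-
    fam[, c("pgs_t_m", "pgs_nt_m", "pgs_t_p", "pgs_nt_p", "y_m", "y_p")]
  vt <- sempgs_variant("equilibrium_constrained", parental_phenotypes = TRUE)
  f1 <- fit_sempgs(fam, vt, se = FALSE)
  f2 <- fit_sempgs(swapped, vt, se = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-3)
})

test_that("pattern-wise likelihood uses incomplete families", {
  sim <- quick_sim(n = 12000, gens = 12, seed = 65)
  fam <- sim$families[, c(variable_order(FALSE))]
  set.seed(66)
  drop <- runif(nrow(fam)) < 0.5
  fam_miss <- fam
  fam_miss$pgs_t_p[drop] <- NA
  fam_miss$pgs_nt_p[drop] <- NA
  vt <- sempgs_variant("equilibrium_constrained")
  f_full <- fit_sempgs(fam, vt)
  f_miss <- fit_sempgs(fam_miss, vt)
  expect_true(f_miss$converged)
  expect_identical(nrow(f_miss$patterns), 2L)
  expect_lt(abs(f_miss$estimates["f"] - f_full$estimates["f"]),
            3 * f_miss$se["f"])
  # precision must not improve by deleting data
  expect_gte(f_miss$se["f"] * 1.02, f_full$se["f"])
})

test_that("degenerate inputs are rejected with clear errors", {
  sim <- quick_sim(n = 200, gens = 3, seed = 67)
  fam <- sim$families
  fam$pgs_t_p <- NA_real_
  expect_error(fit_sempgs(fam, sempgs_variant("equilibrium_constrained")),
               "all-missing")
  expect_error(fit_sempgs(sim$families[1:10, ],
                          sempgs_variant("equilibrium_constrained")),
               "too few")
  expect_error(fit_sempgs(sim$families[, c("pgs_t_p", "y_o")],
                          sempgs_variant("equilibrium_constrained")),
               "lacks column")
})

test_that("non-convergence is reported, not silent", {
  sim <- quick_sim(n = 2000, gens = 5, seed = 68)
  fit <- fit_sempgs(sim$families, sempgs_variant("equilibrium_constrained"),
                    start = c(delta = 2.5, f = -0.4, mu = 0.6, V_eps = 5),
                    se = FALSE, control = list(maxit = 3))
  expect_false(fit$converged)
  expect_output(print(fit), "NOT CONVERGED")
  s <- summary(fit)
  expect_output(print(s), "NOT CONVERGED")
})

test_that("likelihood-ratio tests behave on nested and identical fits", {
  sim <- quick_sim(n = 6000, gens = 10, seed = 69)
  vt <- sempgs_variant("equilibrium_constrained")
  full <- fit_sempgs(sim$families, vt, se = FALSE)
  null_f <- fit_sempgs(sim$families, vt, fixed = c(f = 0), se = FALSE)
  out <- lrt(null_f, full)
  expect_gte(out$statistic, 0)
  expect_identical(out$df, 1L)
  same <- lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt(full, fit_sempgs(sim$families,
                                    sempgs_variant("random_mating"),
                                    se = FALSE)),
               "not nested")
})

test_that("the free variant never fits worse than the constrained one", {
  sim <- quick_sim(n = 8000, gens = 12, seed = 71)
  fam <- sim$families
  f_con <- fit_sempgs(fam, sempgs_variant("equilibrium_constrained"),
                      se = FALSE)
  f_free <- fit_sempgs(fam, sempgs_variant("equilibrium_free"), se = FALSE)
  expect_lte(f_free$minus2ll, f_con$minus2ll + 1e-4)
})

test_that("identifiability diagnostics match the model structure", {
  probe <- c(delta = 0.3, f = 0.15, mu = 0.18, g = 0.05, w = 0.04,
             V_eps = 0.7, k = 0.3)
  # with the haplotypic scale profiled from the sample, the 5-variable
  # system supplies 5 independent moment values for 6 free parameters:
  # one flat direction (f, mu, w, V_eps are entangled)
  free5 <- identifiability_check(sempgs_variant("equilibrium_free"), probe)
  expect_identical(free5$rank, 5L)
  expect_false(free5$identified)
  expect_true(all(abs(free5$null_directions[c("delta", "g"), ]) < 1e-4))
  # observing parental phenotypes restores full rank and cannot reduce
  # information
  obs7 <- identifiability_check(
    sempgs_variant("equilibrium_free", parental_phenotypes = TRUE), probe)
  expect_identical(obs7$rank, 6L)
  expect_true(obs7$identified)
  expect_gte(obs7$rank, free5$rank)
  # the equilibrium-constrained variants are identified
  con <- identifiability_check(sempgs_variant("equilibrium_constrained"),
                               probe)
  expect_true(con$identified)
  lat <- identifiability_check(
    sempgs_variant("equilibrium_constrained", parental_phenotypes = TRUE,
                   latent_extension = TRUE), probe)
  expect_true(lat$identified)
  # severing the PGS-phenotype link (delta = 0 with no residual nurture
  # covariance, which would otherwise still carry f through theta = w)
  # collapses the rank in the 5-variable system: reported, not an error
  probe0 <- probe; probe0["delta"] <- 0; probe0["w"] <- 0
  degen <- identifiability_check(sempgs_variant("equilibrium_free"), probe0)
  expect_lt(degen$rank, free5$rank)
  expect_false(degen$identified)
})

test_that("summaries carry every free parameter exactly once and the variance share", {
  sim <- quick_sim(n = 5000, gens = 10, seed = 72)
  fit <- fit_sempgs(sim$families, sempgs_variant("equilibrium_constrained"))
  s <- summary(fit)
  expect_identical(sort(s$parameters$parameter),
                   sort(c("delta", "f", "mu", "V_eps")))
  expect_identical(anyDuplicated(s$parameters$parameter), 0L)
  expect_true("V_F_share" %in% s$derived$quantity)
  # report files
  paths <- write_fit_report(fit, file.path(tempdir(), "fit_test"))
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1])
  expect_identical(sum(tab$type == "parameter"), 4L)
})
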