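#' Simulation configuration
#'
#' Defines the generative conditions for the forward-time family simulator:
#' vertical transmission (`f`), assortative mating (`mating_basis`,
#' `r_mate`), the predictive ability of the measured PGS (`pgs_r2`) relative
#' to the total narrow-sense heritability (`h2`; the gap is carried by a
#' latent additive-genetic component), and the mode of genetic transmission
#' (Gaussian haplotypic scores, or explicit alleles when `n_loci > 0`).
#'
#' The phenotype is built as
#' `Y = delta * (h_p + h_m) + k * (l_p + l_m) + F + eps` with
#' `F = f * (Y_father + Y_mother)`.  The base haplotypic variance is set to
#' `V_h0 = pgs_r2 / (2 delta^2)` and the latent path to
#' `k = sqrt((h2 - pgs_r2) / (2 V_h0))`, so that on the unit phenotypic
#' scale of a random-mating, no-transmission population the measured PGS
#' explains `pgs_r2` of the variance and all additive effects together
#' explain `h2`.  `V_eps` defaults to `1 - h2` on that scale.
#'
#' @param n_families number of output families (and of couples per
#'   generation).
#' @param delta direct effect of one haplotypic PGS on the phenotype.
#' @param f vertical-transmission path.
#' @param pgs_r2 fraction of baseline phenotypic variance explained by the
#'   measured PGS (> 0).
#' @param h2 total narrow-sense heritability, `pgs_r2 <= h2 < 1`.
#' @param n_generations number of matings simulated (burn-in towards
#'   equilibrium); 20 is ample for the default parameter ranges.
#' @param mating_basis `"phenotypic"`, `"social"`, `"genetic"`, or
#'   `"random"`.
#' @param r_mate target spousal correlation on the mating basis.
#' @param disequilibrium if `TRUE`, mates pair randomly during burn-in and
#'   assort only in the final (parental) generation: one generation of
#'   assortative mating.
#' @param V_eps residual phenotypic variance; default `1 - h2`.
#' @param n_loci number of loci for allele-level transmission; 0 selects the
#'   Gaussian-score mode.
#' @param seed RNG seed (integer) or `NULL`.
#' @return An object of class `sempgs_sim_config`.
#' @export
sempgs_sim_config <- function(n_families, delta, f = 0, pgs_r2, h2 = pgs_r2,
                              n_generations = 20L,
                              mating_basis = c("phenotypic", "social",
                                               "genetic", "random"),
                              r_mate = 0, disequilibrium = FALSE,
                              V_eps = NULL, n_loci = 0L, seed = NULL) {
  mating_basis <- match.arg(mating_basis)
  if (n_families < 1) stop("n_families must be >= 1")
  if (pgs_r2 <= 0 || pgs_r2 > h2 || h2 >= 1)
    stop("need 0 < pgs_r2 <= h2 < 1 (infeasible variance split)")
  if (abs(r_mate) >= 1) stop("|r_mate| must be < 1 (unachievable)")
  if (delta <= 0) stop("delta must be > 0 to define the PGS scale")
  if (is.null(V_eps)) V_eps <- 1 - h2
  if (V_eps <= 0) stop("V_eps must be > 0")
  V_h0 <- pgs_r2 / (2 * delta^2)
  k <- if (h2 > pgs_r2) sqrt((h2 - pgs_r2) / (2 * V_h0)) else 0
  structure(list(n_families = as.integer(n_families), delta = delta, f = f,
                 pgs_r2 = pgs_r2, h2 = h2,
                 n_generations = as.integer(n_generations),
                 mating_basis = mating_basis, r_mate = r_mate,
                 disequilibrium = isTRUE(disequilibrium),
                 V_eps = V_eps, V_h0 = V_h0, V_l0 = V_h0, k = k,
                 n_loci = as.integer(n_loci), seed = seed),
            class = "sempgs_sim_config")
}

#' Pair two mate pools at a target correlation
#'
#' Gaussian-coupling construction: the male pool is ranked on its values and
#' matched, rank for rank, against a noisy copy of the female values whose
#' signal share is solved from the target correlation.  The sample
#' correlation of the paired values converges to `r_mate` as the pool grows.
#'
#' @param x,y numeric vectors of equal length: the mating-basis values of
#'   the two pools.
#' @param r_mate target correlation of paired values, `|r_mate| < 1`.
#' @return Integer vector `idx`: element `i` of `x` is paired with element
#'   `idx[i]` of `y`.
#' @export
assort_mates <- function(x, y, r_mate) {
  n <- length(x)
  if (length(y) != n) stop("mate pools must have equal size")
  if (abs(r_mate) >= 1) stop("|r_mate| must be < 1")
  if (r_mate == 0) return(sample.int(n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) mating values with r_mate != 0")
  key <- r_mate * as.numeric(scale(y)) + sqrt(1 - r_mate^2) * stats::rnorm(n)
  idx <- integer(n)
  idx[order(x)] <- order(key)
  idx
}

#' Mendelian transmission of phased haplotypes
#'
#' Per locus, the child receives the allele from haplotype 1 or 2 with
#' probability 1/2 independently (free recombination); the complementary
#' alleles form the nontransmitted set.
#'
#' @param h1,h2 the parent's two phased haplotypes: vectors or matrices
#'   (individuals x loci) of allele codes.
#' @return `list(transmitted, nontransmitted)` of the same shape.
#' @export
transmit <- function(h1, h2) {
  if (is.null(dim(h1))) { h1 <- rbind(h1); h2 <- rbind(h2); drop_out <- TRUE }
  else drop_out <- FALSE
  if (!identical(dim(h1), dim(h2))) stop("ragged haplotypes")
  pick <- matrix(stats::runif(length(h1)) < 0.5, nrow(h1), ncol(h1))
  tr <- ifelse(pick, h1, h2)
  nt <- ifelse(pick, h2, h1)
  if (drop_out) list(transmitted = tr[1, ], nontransmitted = nt[1, ])
  else list(transmitted = tr, nontransmitted = nt)
}

# gaussian-score meiosis: gamete = mid-haplotype + segregation deviate
transmit_gaussian <- function(h1, h2, V_base) {
  n <- length(h1)
  tr <- (h1 + h2) / 2 + stats::rnorm(n, 0, sqrt(V_base / 2))
  list(transmitted = tr, nontransmitted = h1 + h2 - tr)
}

mating_key <- function(pool, cfg) {
  switch(cfg$mating_basis,
         phenotypic = pool$Y,
         social = pool$F,
         genetic = cfg$delta * (pool$h1 + pool$h2) +
           cfg$k * (pool$l1 + pool$l2),
         random = stats::rnorm(length(pool$Y)))
}

#' Forward-time family simulator
#'
#' Simulates `n_generations` of mating, vertical transmission, and genetic
#' transmission, and returns the final generation as parent-offspring trios:
#' the four haplotypic PGSs of the parents (transmitted and nontransmitted
#' with respect to the output child), the offspring phenotype, and the
#' parental phenotypes.  This is the canonical oracle for
#' [expected_covariance()]: the empirical covariance of its output converges
#' to the model-implied matrix at the [derive_equilibrium()] state.
#'
#' In allele-level mode (`n_loci > 0`) each haplotype is an explicit
#' 0/1 allele vector; allele frequencies are drawn Uniform(0.05, 0.5) and
#' effect sizes Normal, rescaled to hit the configured `pgs_r2`.  The stored
#' haplotypic PGSs are then plain weighted allele counts, so they round-trip
#' exactly through [compute_haplotypic_pgs()].  In Gaussian-score mode
#' haplotypic PGSs are continuous with segregation variance matched to the
#' allele-level process.
#'
#' @param config a [sempgs_sim_config()] object.
#' @param keep_genotypes if `TRUE` (allele mode only) also return the phased
#'   trio genotypes and the SNP weight table.
#' @return A list of class `sempgs_sim` with elements `families` (data frame
#'   in [variable_order()] plus `family_id`), `diagnostics` (per-generation
#'   realized moments), `config`, and in allele mode `genotypes` and
#'   `weights`.
#' @export
simulate_population <- function(config, keep_genotypes = config$n_loci > 0) {
  cfg <- config
  stopifnot(inherits(cfg, "sempgs_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_families
  allele_mode <- cfg$n_loci > 0

  loci <- NULL
  if (allele_mode) {
    p <- stats::runif(cfg$n_loci, 0.05, 0.5)
    beta <- stats::rnorm(cfg$n_loci)
    genic <- sum(beta^2 * p * (1 - p))
    beta <- beta * sqrt(cfg$V_h0 / genic)     # per-haplotype genic variance V_h0
    loci <- data.frame(snp_id = sprintf("rs%05d", seq_len(cfg$n_loci)),
                       chrom = "1", pos = seq_len(cfg$n_loci) * 1000L,
                       ref = "A", alt = "G", freq = p, beta = beta,
                       stringsAsFactors = FALSE)
  }

  founder_pool <- function(n) {
    if (allele_mode) {
      H1 <- matrix(stats::rbinom(n * cfg$n_loci, 1L, rep(loci$freq, each = n)),
                   n, cfg$n_loci)
      H2 <- matrix(stats::rbinom(n * cfg$n_loci, 1L, rep(loci$freq, each = n)),
                   n, cfg$n_loci)
      ctr <- sum(loci$beta * loci$freq)
      pool <- list(H1 = H1, H2 = H2,
                   h1 = as.numeric(H1 %*% loci$beta) - ctr,
                   h2 = as.numeric(H2 %*% loci$beta) - ctr)
    } else {
      pool <- list(h1 = stats::rnorm(n, 0, sqrt(cfg$V_h0)),
                   h2 = stats::rnorm(n, 0, sqrt(cfg$V_h0)))
    }
    pool$l1 <- stats::rnorm(n, 0, sqrt(cfg$V_l0))
    pool$l2 <- stats::rnorm(n, 0, sqrt(cfg$V_l0))
    V_F0 <- if (cfg$f != 0) {
      VY0 <- (cfg$h2 + cfg$V_eps) / max(1e-8, 1 - 2 * cfg$f^2)
      2 * cfg$f^2 * VY0
    } else 0
    pool$F <- if (V_F0 > 0) stats::rnorm(n, 0, sqrt(V_F0)) else numeric(n)
    pool$Y <- cfg$delta * (pool$h1 + pool$h2) + cfg$k * (pool$l1 + pool$l2) +
      pool$F + stats::rnorm(n, 0, sqrt(cfg$V_eps))
    pool
  }

  males <- founder_pool(n)
  females <- founder_pool(n)
  diag_rows <- vector("list", cfg$n_generations)
  fam <- NULL; geno <- NULL

  for (t in seq_len(cfg$n_generations)) {
    final <- t == cfg$n_generations
    assort_now <- cfg$mating_basis != "random" && cfg$r_mate != 0 &&
      (!cfg$disequilibrium || final)
    idx <- if (assort_now)
      assort_mates(mating_key(males, cfg), mating_key(females, cfg), cfg$r_mate)
    else sample.int(n)
    mo <- lapply(females, function(z) if (is.matrix(z)) z[idx, , drop = FALSE] else z[idx])
    fa <- males

    make_child <- function() {
      if (allele_mode) {
        tf <- transmit(fa$H1, fa$H2); tm <- transmit(mo$H1, mo$H2)
        ctr <- sum(loci$beta * loci$freq)
        ch <- list(H1 = tf$transmitted, H2 = tm$transmitted,
                   h1 = as.numeric(tf$transmitted %*% loci$beta) - ctr,
                   h2 = as.numeric(tm$transmitted %*% loci$beta) - ctr)
        ch$nt_p <- as.numeric(tf$nontransmitted %*% loci$beta) - ctr
        ch$nt_m <- as.numeric(tm$nontransmitted %*% loci$beta) - ctr
        ch$NT_p <- tf$nontransmitted; ch$NT_m <- tm$nontransmitted
      } else {
        tf <- transmit_gaussian(fa$h1, fa$h2, cfg$V_h0)
        tm <- transmit_gaussian(mo$h1, mo$h2, cfg$V_h0)
        ch <- list(h1 = tf$transmitted, h2 = tm$transmitted,
                   nt_p = tf$nontransmitted, nt_m = tm$nontransmitted)
      }
      lf <- transmit_gaussian(fa$l1, fa$l2, cfg$V_l0)
      lm_ <- transmit_gaussian(mo$l1, mo$l2, cfg$V_l0)
      ch$l1 <- lf$transmitted; ch$l2 <- lm_$transmitted
      ch$F <- cfg$f * (fa$Y + mo$Y)
      ch$Y <- cfg$delta * (ch$h1 + ch$h2) + cfg$k * (ch$l1 + ch$l2) +
        ch$F + stats::rnorm(n, 0, sqrt(cfg$V_eps))
      ch
    }
    boys <- make_child()
    girls <- make_child()

    diag_rows[[t]] <- data.frame(
      generation = t,
      v_hat = (stats::var(boys$h1) + stats::var(boys$h2)) / 2,
      g_hat = stats::cov(boys$h1, boys$h2),
      w_hat = (stats::cov(boys$h1, boys$F) + stats::cov(boys$h2, boys$F)) / 2,
      V_Y_hat = stats::var(boys$Y),
      r_mate_hat = if (assort_now)
        stats::cor(mating_key(fa, cfg), mating_key(mo, cfg)) else 0)

    if (final) {
      off <- boys
      fam <- data.frame(
        family_id = sprintf("fam%06d", seq_len(n)),
        pgs_t_p = off$h1, pgs_nt_p = off$nt_p,
        pgs_t_m = off$h2, pgs_nt_m = off$nt_m,
        y_o = off$Y, y_p = fa$Y, y_m = mo$Y,
        stringsAsFactors = FALSE)
      if (allele_mode) {
        ctr <- sum(loci$beta * loci$freq)
        # store uncentered weighted allele counts so the scorer round-trips
        fam$pgs_t_p <- fam$pgs_t_p + ctr; fam$pgs_nt_p <- fam$pgs_nt_p + ctr
        fam$pgs_t_m <- fam$pgs_t_m + ctr; fam$pgs_nt_m <- fam$pgs_nt_m + ctr
        if (keep_genotypes)
          geno <- list(loci = loci,
                       father = list(H1 = fa$H1, H2 = fa$H2),
                       mother = list(H1 = mo$H1, H2 = mo$H2),
                       child = list(H1 = off$H1, H2 = off$H2),
                       family_id = fam$family_id)
      }
    }
    males <- boys[setdiff(names(boys), c("nt_p", "nt_m", "NT_p", "NT_m"))]
    females <- girls[setdiff(names(girls), c("nt_p", "nt_m", "NT_p", "NT_m"))]
  }

  out <- list(families = fam, diagnostics = do.call(rbind, diag_rows),
              config = cfg)
  if (!is.null(geno)) {
    out$genotypes <- geno
    out$weights <- data.frame(snp_id = loci$snp_id,
                              effect_allele = loci$alt,
                              other_allele = loci$ref,
                              beta = loci$beta, stringsAsFactors = FALSE)
  }
  class(out) <- "sempgs_sim"
  out
}

#' @export
print.sempgs_sim <- function(x, ...) {
  cat("Simulated", nrow(x$families), "families,",
      x$config$n_generations, "generations,",
      "basis", x$config$mating_basis,
      "r_mate", x$config$r_mate, "\n")
  invisible(x)
}
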