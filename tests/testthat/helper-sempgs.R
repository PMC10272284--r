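# Shared fixtures, built in code.

# small equilibrium simulation used by several files
quick_sim <- function(n = 20000, delta = 0.3, f = 0.15, r_mate = 0.3,
                      pgs_r2 = 0.3, h2 = pgs_r2, gens = 15, seed = 1,
                      ...) {
  simulate_population(sempgs_sim_config(
    n_families = n, delta = delta, f = f, pgs_r2 = pgs_r2, h2 = h2,
    r_mate = r_mate, n_generations = gens, seed = seed, ...))
}

# matched solver state for a simulation config
truth_for <- function(cfg) {
  derive_equilibrium(delta = cfg$delta, f = cfg$f,
                     r_mate = if (cfg$mating_basis == "random") 0 else cfg$r_mate,
                     V_h = cfg$V_h0, V_eps = cfg$V_eps, k = cfg$k,
                     mating_basis = if (cfg$mating_basis == "random")
                       "phenotypic" else cfg$mating_basis)
}

# random valid parameter draw (moderate regime, away from explosive bounds)
draw_params <- function(free_gw = FALSE) {
  delta <- runif(1, 0.1, 0.5); f <- runif(1, 0, 0.25)
  mu <- runif(1, -0.1, 0.4)
  sempgs_params(delta = delta, f = f,
                g = if (free_gw) runif(1, 0, 0.1) else 0,
                w = if (free_gw) runif(1, 0, 0.1) else 0,
                mu = mu, V_eps = runif(1, 0.4, 1.2),
                V_h = runif(1, 0.3, 2))
}

# hand-built 3-locus toy trio (father 1|0 1|1 0|0, mother 0|0 1|0 1|1,
# child 1|0 1|1 0|1 with haplotype 1 paternal)
toy_trio <- function() {
  loci <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                     snp_id = c("rs1", "rs2", "rs3"),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  structure(list(
    loci = loci,
    father = list(H1 = matrix(c(1L, 1L, 0L), 1), H2 = matrix(c(0L, 1L, 0L), 1)),
    mother = list(H1 = matrix(c(0L, 1L, 1L), 1), H2 = matrix(c(0L, 0L, 1L), 1)),
    child = list(H1 = matrix(c(1L, 1L, 0L), 1), H2 = matrix(c(0L, 1L, 1L), 1)),
    family_id = "toy1"), class = "sempgs_trios")
}

toy_weights <- function() {
  data.frame(snp_id = c("rs1", "rs2", "rs3"), effect_allele = "G",
             other_allele = "A", beta = c(0.5, 0.2, -0.3),
             stringsAsFactors = FALSE)
}
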