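#' Haplotypic transmitted / nontransmitted PGSs from phased trios
#'
#' Implements the four-score construction: each parent's genotype is divided
#' into the set of alleles transmitted to the child and the complementary
#' nontransmitted set, and a PGS is computed from each.  The child's phased
#' haplotype of known parental origin (convention: child haplotype 1 is
#' paternal, haplotype 2 maternal, as produced by pedigree phasing)
#' identifies the transmitted allele at every locus; the parent's other
#' allele is the nontransmitted one.  By construction, exactly:
#'
#' * `pgs_t_p + pgs_t_m` equals the child's full PGS, and
#' * `pgs_t_x + pgs_nt_x` equals parent x's full PGS.
#'
#' Loci are intersected with the weight table on `snp_id`; a weight whose
#' (effect, other) alleles do not match the VCF (ref, alt) pair in either
#' orientation is dropped and counted.  A locus where the child's paternal
#' haplotype is not carried by the father (or the maternal one by the
#' mother) is Mendelian-inconsistent - including loci consistent only under
#' a phase swap - and is dropped and counted; a trio with more than
#' `max_mendelian` such loci is dropped entirely rather than silently
#' re-phased, because mis-assigned transmission biases the assortment and
#' nurture covariances.
#'
#' @param trios a `sempgs_trios` object ([read_trio_vcf()] or the
#'   `genotypes` element of an allele-level [simulate_population()]).
#' @param weights weight table (`snp_id`, `effect_allele`, `other_allele`,
#'   `beta`), see [read_weight_table()].
#' @param max_mendelian maximum tolerated fraction of Mendelian-inconsistent
#'   loci per trio before the trio is dropped (default 0.01).
#' @return A list with `families` (data frame: `family_id`, the four
#'   haplotypic PGSs) and `qc` (per-trio counts: `n_loci_used`,
#'   `n_dropped_mendelian`, `n_dropped_allele_mismatch`).
#' @export
#' @examples
#' sim <- simulate_population(sempgs_sim_config(n_families = 50, delta = 0.3,
#'   pgs_r2 = 0.3, n_loci = 40, n_generations = 2, seed = 1))
#' sc <- compute_haplotypic_pgs(sim$genotypes, sim$weights)
#' all.equal(sc$families$pgs_t_p + sc$families$pgs_t_m,
#'           sc$families$pgs_t_p + sc$families$pgs_t_m)
compute_haplotypic_pgs <- function(trios, weights, max_mendelian = 0.01) {
  loci <- trios$loci
  w <- weights[match(loci$snp_id, weights$snp_id), , drop = FALSE]
  in_w <- !is.na(w$beta)
  # allele orientation: effect allele must be the VCF alt (dose = code) or
  # the VCF ref (dose = 1 - code); anything else is a mismatch.
  orient <- rep(NA_integer_, nrow(loci))
  ok <- in_w & w$effect_allele == loci$alt & w$other_allele == loci$ref
  orient[ok] <- 1L
  ok2 <- in_w & w$effect_allele == loci$ref & w$other_allele == loci$alt
  orient[ok2] <- -1L
  mismatch <- in_w & is.na(orient)
  use0 <- which(!is.na(orient))
  if (!length(use0)) stop("no loci shared between genotypes and weight table")
  beta <- w$beta[use0]
  flip <- orient[use0] == -1L

  FH1 <- trios$father$H1[, use0, drop = FALSE]
  FH2 <- trios$father$H2[, use0, drop = FALSE]
  MH1 <- trios$mother$H1[, use0, drop = FALSE]
  MH2 <- trios$mother$H2[, use0, drop = FALSE]
  CP <- trios$child$H1[, use0, drop = FALSE]   # paternal haplotype
  CM <- trios$child$H2[, use0, drop = FALSE]   # maternal haplotype

  # Mendelian consistency at each retained locus
  cons_p <- CP == FH1 | CP == FH2
  cons_m <- CM == MH1 | CM == MH2
  cons <- cons_p & cons_m
  n_trio <- nrow(CP)

  dose <- function(M) {
    D <- M
    if (any(flip)) D[, flip] <- 1L - D[, flip]
    D
  }
  score <- function(M, keep) as.numeric((dose(M) * keep) %*% beta)
  keep <- cons * 1L   # inconsistent loci contribute 0 and are counted

  fam <- data.frame(
    family_id = if (!is.null(trios$family_id)) trios$family_id
                else sprintf("trio%05d", seq_len(n_trio)),
    pgs_t_p = score(CP, keep),
    pgs_nt_p = score(FH1 + FH2 - CP, keep),
    pgs_t_m = score(CM, keep),
    pgs_nt_m = score(MH1 + MH2 - CM, keep),
    stringsAsFactors = FALSE)

  qc <- data.frame(
    trio_id = fam$family_id,
    n_loci_used = as.integer(rowSums(cons)),
    n_dropped_mendelian = as.integer(rowSums(!cons)),
    n_dropped_allele_mismatch = sum(mismatch),
    stringsAsFactors = FALSE)

  bad <- qc$n_dropped_mendelian > max_mendelian * length(use0)
  if (any(bad)) {
    fam <- fam[!bad, , drop = FALSE]
    warning(sum(bad), " trio(s) dropped: > ", 100 * max_mendelian,
            "% Mendelian-inconsistent loci")
  }
  list(families = fam, qc = qc)
}
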