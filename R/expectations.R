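#' Model-implied covariance matrix of the observed variables
#'
#' Assembles the expected covariance matrix of the observed system in the
#' fixed [variable_order()]: the four haplotypic PGSs of the parents, the
#' offspring phenotype, and (for the 7-variable system) the parental
#' phenotypes.  Every element is a polynomial in the structural parameters;
#' the key elements, writing `v = V_h + g` for the haplotypic variance,
#' `theta = delta * (v + g) + w` for the haplotype-phenotype covariance and
#' `psi` for the covariance of a variable with the mating-basis variable,
#' are (phenotypic basis, no latent component):
#'
#' * `var(PGS) = v`, `cov(PGS_T, PGS_NT | same parent) = g`
#' * `cov(father hap, mother hap) = mu * theta^2` (copath chain)
#' * `cov(PGS_T, y_o) = delta * (v + mu * theta^2) + f * theta * (1 + mu * V_Y)`
#' * `cov(PGS_NT, y_o) = delta * (g + mu * theta^2) + f * theta * (1 + mu * V_Y)`
#'
#' so the transmitted minus nontransmitted contrast is `delta * (v - g)`:
#' only transmitted scores carry the direct genetic effect, while both carry
#' the genetic-nurture and assortment terms.  The offspring variance is
#' computed by advancing the parental state one generation (at equilibrium it
#' equals the parental `V_Y`; at disequilibrium it is inflated by the new
#' assortment).
#'
#' @param params a [sempgs_params()] object.
#' @param variant a [sempgs_variant()] object; governs dimension (5 or 7),
#'   the mating basis, and how `g`, `w`, `V_Y` are obtained.
#' @param haplotype_variance optional observed haplotypic-PGS variance fixing
#'   the PGS scale (used at fit time); defaults to the value implied by
#'   `V_h` and `g`.
#' @return A symmetric positive-semidefinite matrix of class
#'   `sempgs_expected_cov` with dimnames in [variable_order()].
#' @seealso [enumerate_paths()] for the independent path-enumeration
#'   assembly, [derive_equilibrium()] for the constrained state.
#' @export
#' @examples
#' p <- sempgs_params(delta = 0.3, f = 0, V_eps = 0.7, V_h = 0.5)
#' expected_covariance(p, sempgs_variant("random_mating"))
expected_covariance <- function(params, variant = sempgs_variant("equilibrium_constrained"),
                                haplotype_variance = NULL) {
  stopifnot(inherits(params, "sempgs_params"), inherits(variant, "sempgs_variant"))
  st <- implied_state(params, variant, s2hap = haplotype_variance)
  sigma_from_state(st, params, variant)
}

# Assemble sigma from a parental-generation state (shared by the fit, which
# profiles the haplotypic variance from the sample).
sigma_from_state <- function(st, params, variant) {
  d <- params$delta; k <- params$k; f <- params$f; mu <- params$mu
  vars <- variable_order(variant$parental_phenotypes)
  nv <- length(vars)
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  v <- st$v; g <- st$g
  th_o <- st$theta_o; th_l <- st$theta_l
  ps_o <- st$psi_o; ps_l <- st$psi_l; ps_Y <- st$psi_Y
  cbar <- (st$c_s + st$c_x) / 2
  hapF <- c("pgs_t_p", "pgs_nt_p"); hapM <- c("pgs_t_m", "pgs_nt_m")

  S[hapF, hapF] <- g; S[hapM, hapM] <- g
  diag(S)[1:4] <- v
  S[hapF, hapM] <- mu * ps_o^2
  S[hapM, hapF] <- mu * ps_o^2

  # offspring phenotype row: y_o = delta (T_p + T_m) + k (L_p + L_m)
  #                                + f (Y_p + Y_m) + eps
  nurture <- f * (th_o + mu * ps_o * ps_Y)   # = child w on the hap scale
  latent_t <- k * (cbar + mu * ps_o * ps_l)  # via transmitted latent gametes
  cT <- d * (v + mu * ps_o^2) + latent_t + nurture
  cN <- d * (g + mu * ps_o^2) + latent_t + nurture
  S["pgs_t_p", "y_o"] <- S["y_o", "pgs_t_p"] <- cT
  S["pgs_t_m", "y_o"] <- S["y_o", "pgs_t_m"] <- cT
  S["pgs_nt_p", "y_o"] <- S["y_o", "pgs_nt_p"] <- cN
  S["pgs_nt_m", "y_o"] <- S["y_o", "pgs_nt_m"] <- cN
  # offspring variance from the parental state, with the haplotypic
  # variances stationary (the diagram gives parent and offspring haplotypic
  # nodes the same self-variance); the assortment-induced pieces use the
  # child-generation values.
  ch <- st$child
  S["y_o", "y_o"] <- 2 * d^2 * (v + ch$g) + 2 * k^2 * (st$v_l + ch$g_l) +
    4 * d * k * (cbar + ch$c_x) + 4 * d * ch$w + 4 * k * ch$w_l +
    ch$V_F + params$V_eps

  if (variant$parental_phenotypes) {
    S["y_p", "y_p"] <- S["y_m", "y_m"] <- st$V_Y
    S["y_p", "y_m"] <- S["y_m", "y_p"] <- mu * ps_Y^2
    for (h in hapF) { S[h, "y_p"] <- S["y_p", h] <- th_o }
    for (h in hapM) { S[h, "y_m"] <- S["y_m", h] <- th_o }
    for (h in hapF) { S[h, "y_m"] <- S["y_m", h] <- ps_o * mu * ps_Y }
    for (h in hapM) { S[h, "y_p"] <- S["y_p", h] <- ps_o * mu * ps_Y }
    cYpYo <- d * (th_o + ps_Y * mu * ps_o) + k * (th_l + ps_Y * mu * ps_l) +
      f * (st$V_Y + mu * ps_Y^2)
    S["y_p", "y_o"] <- S["y_o", "y_p"] <- cYpYo
    S["y_m", "y_o"] <- S["y_o", "y_m"] <- cYpYo
  }
  class(S) <- c("sempgs_expected_cov", class(S))
  S
}

#' @export
print.sempgs_expected_cov <- function(x, digits = 5, ...) {
  y <- x; class(y) <- "matrix"
  print(round(y, digits), ...)
  invisible(x)
}
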