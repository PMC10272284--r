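# Generation-recurrence machinery.
#
# The model is propagated on second moments of the parental generation:
#   v    variance of one measured haplotypic PGS
#   g    covariance between the two measured haplotypic PGSs of one person
#   v_l, g_l   the same for the latent (non-PGS) haplotypic component
#   c_s, c_x   within-person covariance between a measured and a latent
#              haplotypic score (same / opposite parental origin)
#   w, w_l     covariance between a haplotypic score and the owner's
#              familial environment (genetic nurture)
#   V_F, V_Y   familial-environment and total phenotypic variance
#
# One generation forward (free recombination, gamete = mid-haplotype plus a
# segregation deviate of variance V_h0 / 2):
#   v'   = (v + g)/2 + V_h0/2
#   g'   = mu * psi_o^2
#   c_s' = (c_s + c_x)/2 ;  c_x' = mu * psi_o * psi_l
#   w'   = f * (theta_o + mu * psi_o * psi_Y)
#   V_F' = f^2 * (2 V_Y + 2 mu * psi_Y^2)
# where theta_o = cov(haplotypic PGS, own phenotype), and psi_x = cov(x, K)
# with K the mating-basis variable; cross-mate covariances follow the copath
# rule cov(x_father, z_mother) = psi_x * mu * psi_z.

basis_moments <- function(st, par) {
  d <- par$delta; k <- par$k
  cc <- st$c_s + st$c_x
  theta_o <- d * (st$v + st$g) + k * cc + st$w
  theta_l <- k * (st$v_l + st$g_l) + d * cc + st$w_l
  switch(par$mating_basis,
    phenotypic = list(theta_o = theta_o, theta_l = theta_l,
                      psi_o = theta_o, psi_l = theta_l,
                      psi_Y = st$V_Y, V_K = st$V_Y),
    genetic = {
      V_K <- 2 * d^2 * (st$v + st$g) + 2 * k^2 * (st$v_l + st$g_l) +
        4 * d * k * cc
      list(theta_o = theta_o, theta_l = theta_l,
           psi_o = theta_o - st$w, psi_l = theta_l - st$w_l,
           psi_Y = V_K + 2 * d * st$w + 2 * k * st$w_l, V_K = V_K)
    },
    social = list(theta_o = theta_o, theta_l = theta_l,
                  psi_o = st$w, psi_l = st$w_l,
                  psi_Y = st$V_F + 2 * d * st$w + 2 * k * st$w_l,
                  V_K = st$V_F)
  )
}

advance_generation <- function(st, par, mu) {
  bm <- basis_moments(st, par)
  d <- par$delta; k <- par$k; f <- par$f
  ch <- list(
    v   = (st$v + st$g) / 2 + st$V_h0 / 2,
    g   = mu * bm$psi_o^2,
    v_l = (st$v_l + st$g_l) / 2 + st$V_l0 / 2,
    g_l = mu * bm$psi_l^2,
    c_s = (st$c_s + st$c_x) / 2,
    c_x = mu * bm$psi_o * bm$psi_l,
    w   = f * (bm$theta_o + mu * bm$psi_o * bm$psi_Y),
    w_l = f * (bm$theta_l + mu * bm$psi_l * bm$psi_Y),
    V_F = f^2 * (2 * st$V_Y + 2 * mu * bm$psi_Y^2),
    V_h0 = st$V_h0, V_l0 = st$V_l0
  )
  ch$V_Y <- 2 * d^2 * (ch$v + ch$g) + 2 * k^2 * (ch$v_l + ch$g_l) +
    4 * d * k * (ch$c_s + ch$c_x) + 4 * d * ch$w + 4 * k * ch$w_l +
    ch$V_F + par$V_eps
  ch
}

state_vec <- function(st)
  c(st$v, st$g, st$v_l, st$g_l, st$c_s, st$c_x, st$w, st$w_l, st$V_F, st$V_Y)

#' Equilibrium of the assortment / vertical-transmission recurrences
#'
#' Iterates the generation recurrences linking the structural parameters to
#' the assortment-induced covariances until a fixed point: `g`, the
#' within-person covariance between the two haplotypic PGSs; `w`, the
#' genetic-nurture covariance; and the familial and total phenotypic
#' variances `V_F`, `V_Y`.  Under `mu = 0` and `f = 0` the fixed point has
#' `g = w = 0`; under `mu = 0` only, `w = f * delta * V_h / (1 - f)`.
#'
#' Either `mu` (the copath coefficient) or `r_mate` (the target spousal
#' correlation on the mating basis, in which case `mu` is solved as
#' `r_mate / V_K` at the fixed point) must be given.
#'
#' @param delta,f,V_h,V_eps,k structural parameters, see [sempgs_params()].
#' @param mu copath coefficient; mutually exclusive with `r_mate`.
#' @param r_mate target spousal correlation on the mating basis.
#' @param V_l base variance of the latent haplotypic component.
#' @param mating_basis `"phenotypic"`, `"social"` or `"genetic"`.
#' @param fix_hap_variance optional: hold the equilibrium haplotypic-PGS
#'   variance at this value and solve the base `V_h` implicitly (used when
#'   fitting, where the observed haplotypic variance fixes the PGS scale).
#' @param tol convergence tolerance on the max-norm change of the state
#'   (default 1e-10).
#' @param max_iter maximum number of generations iterated (default 1000);
#'   exceeding it signals an explosive parameter regime.
#'
#' @return An object of class `sempgs_equilibrium`: a list with the fixed
#'   point (`g`, `w`, `V_Y`, `V_F`, plus latent analogues and haplotypic
#'   variance `v`), the implied `mu`, the spousal correlations on the mating
#'   basis and on the phenotype, and convergence bookkeeping.
#' @export
#' @examples
#' derive_equilibrium(delta = 0.3, f = 0.2, mu = 0, V_h = 0.5, V_eps = 0.7)$w
#' # f * delta * V_h / (1 - f) = 0.0375
derive_equilibrium <- function(delta, f, mu = NULL, V_h, V_eps,
                               k = 0, V_l = V_h, r_mate = NULL,
                               mating_basis = c("phenotypic", "social", "genetic"),
                               fix_hap_variance = NULL,
                               tol = 1e-10, max_iter = 1000L) {
  mating_basis <- match.arg(mating_basis)
  if (is.null(mu) && is.null(r_mate))
    stop("one of 'mu' or 'r_mate' must be given")
  if (!is.null(mu) && !is.null(r_mate))
    stop("'mu' and 'r_mate' are mutually exclusive")
  if (V_h <= 0 || V_eps <= 0) stop("V_h and V_eps must be > 0")
  if (!is.null(r_mate) && abs(r_mate) >= 1)
    stop("|r_mate| must be < 1")
  par <- list(delta = delta, f = f, k = k, V_eps = V_eps,
              mating_basis = mating_basis)
  st <- list(v = V_h, g = 0, v_l = V_l, g_l = 0, c_s = 0, c_x = 0,
             w = 0, w_l = 0, V_F = 0, V_h0 = V_h, V_l0 = V_l)
  if (!is.null(fix_hap_variance)) st$v <- fix_hap_variance
  st$V_Y <- 2 * delta^2 * st$v + 2 * k^2 * st$v_l + V_eps
  mu_t <- if (is.null(mu)) 0 else mu
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    bm <- basis_moments(st, par)
    if (!is.null(r_mate)) {
      mu_t <- if (bm$V_K > 0) r_mate / bm$V_K else 0
    }
    ch <- advance_generation(st, par, mu_t)
    if (!is.null(fix_hap_variance)) {
      # hold the realized haplotypic variance; the base V_h0 is implied
      ch$V_h0 <- fix_hap_variance - ch$g
      ch$V_l0 <- ch$V_h0
      ch$v <- fix_hap_variance
      ch$v_l <- ch$V_l0 + ch$g_l
      if (ch$V_h0 <= 0)
        stop("infeasible parameter set: implied base haplotypic variance <= 0")
    }
    if (!all(is.finite(state_vec(ch))) || ch$V_Y > 1e8 || ch$V_Y <= 0)
      stop("equilibrium iteration diverged: explosive parameter regime ",
           "(e.g. |f| too large or |mu| * V_Y >= 1)")
    delta_max <- max(abs(state_vec(ch) - state_vec(st)))
    st <- ch
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("equilibrium not reached after ", max_iter,
         " iterations (explosive parameter regime)")
  bm <- basis_moments(st, par)
  if (abs(mu_t) * bm$V_K >= 1)
    stop("infeasible parameter set: implied spousal correlation >= 1")
  if (st$V_F < -1e-10 || st$v <= 0)
    stop("infeasible parameter set: negative implied variance")
  out <- c(st, list(mu = mu_t, n_iter = iter, converged = converged,
                    mating_basis = mating_basis,
                    theta = bm$theta_o, psi_Y = bm$psi_Y, V_K = bm$V_K,
                    r_basis = mu_t * bm$V_K,
                    r_phenotypic = mu_t * bm$psi_Y^2 / st$V_Y,
                    delta = delta, f = f, k = k, V_eps = V_eps))
  class(out) <- "sempgs_equilibrium"
  out
}

#' @export
print.sempgs_equilibrium <- function(x, ...) {
  cat("Equilibrium state (", x$n_iter, " generations to |change| < tol):\n",
      sep = "")
  print(round(unlist(x[c("g", "w", "V_Y", "V_F", "v", "mu")]), 6))
  cat("spousal correlation on mating basis:", round(x$r_basis, 4),
      "| on phenotype:", round(x$r_phenotypic, 4), "\n")
  invisible(x)
}

# Parental-generation second-moment state implied by a parameter set under a
# model variant.  For the free / disequilibrium / random-mating variants the
# phenotypic variance solves the self-consistency equation
#   V_F = f^2 (2 V_Y + 2 mu psi_Y^2),  V_Y = genetic + 4 delta w + V_F + V_eps
# by fixed-point iteration (general across mating bases).
implied_state <- function(params, variant, s2hap = NULL) {
  p <- params
  basis <- variant$mating_basis
  par <- list(delta = p$delta, f = p$f, k = p$k, V_eps = p$V_eps,
              mating_basis = basis)
  if (variant$name == "equilibrium_constrained") {
    eq <- derive_equilibrium(p$delta, p$f, mu = p$mu, V_h = p$V_h,
                             V_eps = p$V_eps, k = p$k, V_l = p$V_l,
                             mating_basis = basis,
                             fix_hap_variance = s2hap)
    st <- eq[c("v", "g", "v_l", "g_l", "c_s", "c_x", "w", "w_l",
               "V_F", "V_Y", "V_h0", "V_l0")]
  } else {
    v <- if (is.null(s2hap)) p$V_h + p$g else s2hap
    V_h0 <- v - p$g
    if (V_h0 <= 0) stop("infeasible parameter set: V_h + g inconsistency")
    st <- list(v = v, g = p$g, v_l = p$V_l + p$g_l, g_l = p$g_l,
               c_s = p$c_ol, c_x = p$c_ol, w = p$w, w_l = p$w_l,
               V_F = 0, V_Y = NA_real_, V_h0 = V_h0, V_l0 = p$V_l)
    mu_par <- if (variant$name == "equilibrium_free") p$mu else 0
    # parental generation: for disequilibrium_am / random_mating the parents
    # themselves are products of random mating, so mu does not enter their
    # own variance.
    gen <- 2 * p$delta^2 * (st$v + st$g) + 2 * p$k^2 * (st$v_l + st$g_l) +
      4 * p$delta * p$k * (st$c_s + st$c_x) +
      4 * p$delta * st$w + 4 * p$k * st$w_l
    V_Y <- gen + p$V_eps
    for (i in 1:200) {
      st$V_Y <- V_Y
      bm <- basis_moments(st, par)
      V_F <- p$f^2 * (2 * V_Y + 2 * mu_par * bm$psi_Y^2)
      V_Y_new <- gen + V_F + p$V_eps
      st$V_F <- V_F
      if (!is.finite(V_Y_new) || V_Y_new <= 0 || V_Y_new > 1e8)
        stop("infeasible parameter set: phenotypic variance diverged")
      if (abs(V_Y_new - V_Y) < 1e-12) { V_Y <- V_Y_new; break }
      V_Y <- V_Y_new
    }
    st$V_Y <- V_Y
  }
  bm <- basis_moments(st, par)
  st$theta_o <- bm$theta_o; st$theta_l <- bm$theta_l
  st$psi_o <- bm$psi_o; st$psi_l <- bm$psi_l
  st$psi_Y <- bm$psi_Y; st$V_K <- bm$V_K
  st$child <- advance_generation(st, par, p$mu)
  st
}
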