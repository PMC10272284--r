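#' Model parameters for the haplotypic-PGS family model
#'
#' Bundles the structural parameters of the parental-effects model: the direct
#' effect of one haplotypic PGS on its owner's phenotype (`delta`), the
#' vertical-transmission path from a parental phenotype to the offspring
#' familial environment (`f`), the assortative-mating-induced covariance
#' between the two haplotypic PGSs of one person (`g`), the genetic-nurture
#' covariance between a haplotypic PGS and its owner's familial environment
#' (`w`), the copath coefficient between mate selection variables (`mu`), the
#' residual phenotypic variance (`V_eps`), and the base variance of one
#' haplotypic PGS under random mating (`V_h`, fixed by standardization rather
#' than estimated).  When the measured PGS captures only part of the
#' heritability, a latent additive-genetic component enters with path
#' coefficient `k` and its own nurture/assortment analogues (`g_l`, `w_l`,
#' `c_ol` the within-person covariance between a measured and a latent
#' haplotypic score).
#'
#' The total phenotypic variance `V_Y` and the familial-environment variance
#' `V_F` are derived quantities: at equilibrium
#' `V_F = 2 f^2 V_Y (1 + mu V_Y)` and `V_Y` solves the implicit
#' variance-decomposition equation (see [expected_covariance()]).
#'
#' @param delta direct effect of one haplotypic PGS on the phenotype
#'   (phenotype SD per PGS unit).
#' @param f vertical-transmission path from one parental phenotype to the
#'   offspring familial environment.
#' @param g within-person covariance between the two haplotypic PGSs induced
#'   by prior-generation assortative mating.
#' @param w covariance between a haplotypic PGS and the same person's
#'   familial environment (genetic nurture).
#' @param mu copath coefficient between the mates' selection variables;
#'   the spousal covariance on the mating basis is `mu * V_K^2` where `V_K`
#'   is the basis variance, so the spousal correlation is `mu * V_K`.
#' @param V_eps residual phenotypic variance (> 0).
#' @param V_h base variance of one haplotypic PGS under random mating (> 0).
#' @param k path coefficient of one latent (non-PGS) haplotypic genetic
#'   component on the phenotype; 0 disables the latent extension.
#' @param g_l,w_l,c_ol latent-component analogues of `g`, `w`, and the
#'   within-person measured-latent haplotypic covariance; ignored when
#'   `k == 0`.  In the equilibrium-constrained model these are functions of
#'   the structural parameters (see [derive_equilibrium()]).
#' @param V_l base variance of one latent haplotypic component; defaults to
#'   `V_h` (the latent scale is absorbed by `k`).
#'
#' @return An object of class `sempgs_params` (a named list).
#' @seealso [validate_parameters()], [derive_equilibrium()],
#'   [expected_covariance()]
#' @export
#' @examples
#' p <- sempgs_params(delta = 0.3, f = 0.15, mu = 0.2, V_eps = 0.7, V_h = 0.5)
#' p
sempgs_params <- function(delta, f = 0, g = 0, w = 0, mu = 0,
                          V_eps, V_h, k = 0, g_l = 0, w_l = 0, c_ol = 0,
                          V_l = V_h) {
  p <- list(delta = delta, f = f, g = g, w = w, mu = mu,
            V_eps = V_eps, V_h = V_h, k = k,
            g_l = g_l, w_l = w_l, c_ol = c_ol, V_l = V_l)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  }
  structure(p, class = "sempgs_params")
}

#' @export
print.sempgs_params <- function(x, ...) {
  cat("Haplotypic-PGS model parameters:\n")
  core <- c("delta", "f", "g", "w", "mu", "V_eps", "V_h")
  vals <- unlist(x[core])
  print(round(vals, 6))
  if (x$k != 0) {
    cat("latent genetic extension:\n")
    print(round(unlist(x[c("k", "g_l", "w_l", "c_ol", "V_l")]), 6))
  }
  invisible(x)
}

#' Model variants
#'
#' Describes which structural regime is assumed and which variables are
#' observed.  Variants differ in how the assortment-induced covariances are
#' treated:
#'
#' * `random_mating`: no copath (`mu = 0`), `g = 0`; free parameters
#'   `delta, f, w, V_eps`.
#' * `disequilibrium_am`: assortment began in the parental generation, so a
#'   between-mate PGS covariance exists through the copath but the
#'   within-person cross-haplotype covariance has not yet built up (`g = 0`);
#'   free parameters `delta, f, mu, w, V_eps`.
#' * `equilibrium_free`: assortment and transmission of unspecified history;
#'   `g` and `w` are free parameters; free set
#'   `delta, f, mu, g, w, V_eps` (6 parameters).
#' * `equilibrium_constrained`: assortment and vertical transmission at their
#'   multi-generation fixed point, so `g` and `w` are deterministic functions
#'   of `delta, f, mu` through [derive_equilibrium()]; free set
#'   `delta, f, mu, V_eps` (4 parameters).
#'
#' @param name one of `"random_mating"`, `"disequilibrium_am"`,
#'   `"equilibrium_free"`, `"equilibrium_constrained"`.
#' @param mating_basis which variable the copath joins between mates:
#'   `"phenotypic"` (own phenotype), `"social"` (own familial environment),
#'   or `"genetic"` (full additive genetic value).  The non-phenotypic bases
#'   are extensions validated against the simulator.
#' @param parental_phenotypes logical; if `TRUE` the parental phenotypes are
#'   observed and the model works with the 7-variable system, otherwise the
#'   5-variable system (parental phenotypes latent).
#' @param latent_extension logical; adds the latent non-PGS additive genetic
#'   component with path `k`, so the measured PGS captures only part of the
#'   heritability.  Only fittable under `equilibrium_constrained`
#'   (identifiability).
#'
#' @return An object of class `sempgs_variant`.
#' @export
sempgs_variant <- function(name = c("equilibrium_constrained",
                                    "equilibrium_free",
                                    "disequilibrium_am",
                                    "random_mating"),
                           mating_basis = c("phenotypic", "social", "genetic"),
                           parental_phenotypes = FALSE,
                           latent_extension = FALSE) {
  name <- match.arg(name)
  mating_basis <- match.arg(mating_basis)
  if (latent_extension && name != "equilibrium_constrained")
    stop("the latent genetic extension is only fittable in the ",
         "'equilibrium_constrained' variant (rank-deficient otherwise)")
  structure(list(name = name, mating_basis = mating_basis,
                 parental_phenotypes = isTRUE(parental_phenotypes),
                 latent_extension = isTRUE(latent_extension)),
            class = "sempgs_variant")
}

#' @export
print.sempgs_variant <- function(x, ...) {
  cat("Model variant:", x$name,
      "| mating basis:", x$mating_basis,
      "| parental phenotypes:", if (x$parental_phenotypes) "observed" else "latent",
      "| latent genetic extension:", x$latent_extension, "\n")
  invisible(x)
}

#' Fixed variable order of the observed system
#'
#' The order is fixed and identical across the expectations, the simulator
#' output, and the fit input: paternal transmitted, paternal nontransmitted,
#' maternal transmitted, maternal nontransmitted haplotypic PGS, offspring
#' phenotype, and (when observed) the paternal and maternal phenotypes.
#'
#' @param parental_phenotypes logical; append the parental phenotype labels.
#' @return Character vector of variable labels.
#' @export
variable_order <- function(parental_phenotypes = FALSE) {
  v <- c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m", "y_o")
  if (parental_phenotypes) v <- c(v, "y_p", "y_m")
  v
}

#' Validate a parameter set against a model variant
#'
#' Checks the parameter-set invariants (positive variances, implied spousal
#' correlation strictly inside (-1, 1), the familial-variance identity) and
#' the variant-specific constraints (e.g. `g` must be 0 under
#' `disequilibrium_am`; `mu` must be 0 under `random_mating`).  Derived
#' quantities `V_Y` and `V_F` are attached.
#'
#' @param params a [sempgs_params()] object.
#' @param variant a [sempgs_variant()] object.
#' @return The checked parameter set with elements `V_Y` and `V_F` populated.
#' @export
validate_parameters <- function(params, variant = sempgs_variant("equilibrium_free")) {
  stopifnot(inherits(params, "sempgs_params"), inherits(variant, "sempgs_variant"))
  if (params$V_eps <= 0) stop("invalid parameter V_eps: must be > 0")
  if (params$V_h <= 0) stop("invalid parameter V_h: must be > 0")
  if (variant$name == "random_mating" && params$mu != 0)
    stop("invalid parameter mu: must be 0 under the random_mating variant")
  if (variant$name %in% c("random_mating", "disequilibrium_am") && params$g != 0)
    stop("invalid parameter g: must be 0 under the ", variant$name,
         " variant (no prior-generation assortment)")
  if (!variant$latent_extension && params$k != 0)
    stop("invalid parameter k: latent extension not enabled in this variant")
  st <- implied_state(params, variant)
  if (st$V_Y < params$V_eps - 1e-12)
    stop("invalid parameter set: implied V_Y < V_eps")
  if (st$V_F < -1e-10)
    stop("invalid parameter set: implied V_F < 0")
  if (abs(params$mu) * st$V_K >= 1)
    stop("invalid parameter mu: implied spousal correlation >= 1 ",
         "(|mu| * V_basis = ", format(abs(params$mu) * st$V_K), ")")
  params$V_Y <- st$V_Y
  params$V_F <- st$V_F
  params
}
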