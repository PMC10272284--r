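# Full-information maximum likelihood for the haplotypic-PGS family model.
#
# Families are independent; each contributes the multivariate-normal
# likelihood of its observed subset of variables (pattern-wise FIML), so
# relative pairs (parent-offspring, spouse) and incomplete trios are used
# without imputation and estimates are unbiased under data missing at
# random.  Column means are profiled (available-case means; the model is a
# pure covariance structure).  The haplotypic-PGS scale is fixed from the
# sample: the observed haplotypic variance satisfies v = V_h + g, so V_h is
# profiled as s2_hap - g at every evaluation and g remains free (or
# equilibrium-determined).

free_par_names <- function(variant) {
  switch(variant$name,
    random_mating = c("delta", "f", "w", "V_eps"),
    disequilibrium_am = c("delta", "f", "mu", "w", "V_eps"),
    equilibrium_free = c("delta", "f", "mu", "g", "w", "V_eps"),
    equilibrium_constrained =
      c("delta", "f", "mu", if (variant$latent_extension) "k", "V_eps"))
}

to_transformed <- function(x) {
  x["V_eps"] <- log(x["V_eps"])
  names(x)[names(x) == "V_eps"] <- "log_V_eps"
  x
}
to_natural <- function(x) {
  x["log_V_eps"] <- exp(x["log_V_eps"])
  names(x)[names(x) == "log_V_eps"] <- "V_eps"
  x
}

params_from_free <- function(free, variant, s2hap) {
  a <- function(nm, default = 0) if (nm %in% names(free)) free[[nm]] else default
  sempgs_params(delta = a("delta"), f = a("f"), g = a("g"), w = a("w"),
                mu = a("mu"), V_eps = a("V_eps", 1), V_h = s2hap,
                k = a("k"))
}

sigma_from_free <- function(free, variant, s2hap) {
  p <- params_from_free(free, variant, s2hap)
  st <- implied_state(p, variant, s2hap = s2hap)
  sigma_from_state(st, p, variant)
}

prepare_fiml_data <- function(families, variant) {
  vars <- variable_order(variant$parental_phenotypes)
  missing_cols <- setdiff(vars, names(families))
  if (length(missing_cols))
    stop("family table lacks column(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(families[, vars, drop = FALSE])
  storage.mode(X) <- "double"
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na))
    stop("all-missing column(s): ", paste(vars[all_na], collapse = ", "))
  mns <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, mns)
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]
  hap <- intersect(c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m"), vars)
  s2hap <- mean(apply(X[, hap, drop = FALSE], 2, stats::var, na.rm = TRUE))
  pat_key <- apply(!is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  patterns <- lapply(split(seq_len(nrow(X)), pat_key), function(idx) {
    obs <- which(!is.na(X[idx[1], ]))
    Xi <- X[idx, obs, drop = FALSE]
    list(obs = obs, n = length(idx), W = crossprod(Xi),
         vars = vars[obs])
  })
  list(X = X, vars = vars, s2hap = s2hap, patterns = patterns,
       means = mns, n = nrow(X))
}

fiml_neg2ll <- function(S_full, patterns) {
  tot <- 0
  for (pt in patterns) {
    Sk <- S_full[pt$obs, pt$obs, drop = FALSE]
    R <- tryCatch(chol(Sk), error = function(e) NULL)
    if (is.null(R)) return(NA_real_)
    logdet <- 2 * sum(log(diag(R)))
    tr <- sum(chol2inv(R) * pt$W)
    tot <- tot + pt$n * (length(pt$obs) * log(2 * pi) + logdet) + tr
  }
  tot
}

moment_starts <- function(fd, variant) {
  pc <- suppressWarnings(stats::cov(fd$X, use = "pairwise.complete.obs"))
  dimnames(pc) <- list(fd$vars, fd$vars)
  gv <- function(a, b) { x <- pc[a, b]; if (is.finite(x)) x else 0 }
  s2 <- fd$s2hap
  cT <- mean(c(gv("pgs_t_p", "y_o"), gv("pgs_t_m", "y_o")))
  cN <- mean(c(gv("pgs_nt_p", "y_o"), gv("pgs_nt_m", "y_o")))
  g0 <- mean(c(gv("pgs_t_p", "pgs_nt_p"), gv("pgs_t_m", "pgs_nt_m")))
  btw <- mean(c(gv("pgs_t_p", "pgs_t_m"), gv("pgs_t_p", "pgs_nt_m"),
                gv("pgs_nt_p", "pgs_t_m"), gv("pgs_nt_p", "pgs_nt_m")))
  VY <- max(gv("y_o", "y_o"), 1e-3)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  delta0 <- clamp((cT - cN) / max(s2 - g0, 0.1 * s2), 0.02, 3)
  theta0 <- max(delta0 * (s2 + g0), 1e-3)
  mu0 <- if (variant$parental_phenotypes && is.finite(pc["y_p", "y_m"]))
    pc["y_p", "y_m"] / max(pc["y_p", "y_p"], 1e-3)^2
  else btw / theta0^2
  mu0 <- clamp(mu0, -0.5 / VY, 0.9 / VY)
  f0 <- clamp((cN - delta0 * g0 - delta0 * max(btw, 0)) /
                (theta0 * (1 + mu0 * VY)), -0.45, 0.45)
  w0 <- clamp(f0 * theta0, -1, 1)
  Veps0 <- clamp(VY - 2 * delta0^2 * (s2 + g0) - 4 * delta0 * w0,
                 0.1 * VY, VY)
  full <- c(delta = delta0, f = f0, mu = mu0, g = max(g0, 0), w = w0,
            k = 0.3, V_eps = Veps0)
  full[free_par_names(variant)]
}

derived_from_free <- function(free, variant, s2hap) {
  p <- params_from_free(free, variant, s2hap)
  st <- implied_state(p, variant, s2hap = s2hap)
  c(V_F = st$V_F, V_Y = st$V_Y, g = st$g, w = st$w,
    V_F_share = st$V_F / st$V_Y,
    r_spousal = p$mu * st$psi_Y^2 / st$V_Y)
}

num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x),
              dimnames = list(names(f0), names(x)))
  for (j in seq_along(x)) {
    h <- eps * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Fit the family model by full-information maximum likelihood
#'
#' Minimizes the multivariate-normal -2 log-likelihood summed over
#' missingness patterns (each family contributes the sub-matrix of the
#' model-implied covariance corresponding to its observed variables).
#' Start values come from method-of-moments (the transmitted minus
#' nontransmitted covariance contrast for `delta`, the nontransmitted
#' covariance for `f`, the spousal correlation or between-mate PGS
#' covariance for `mu`); optimization is Nelder-Mead followed by a BFGS
#' polish on a transformed scale (log for `V_eps`).  Standard errors come
#' from the numeric observed information; `V_F`, `V_Y` and (in constrained
#' variants) `g`, `w` get delta-method standard errors.
#'
#' @param families family table (data frame; see [read_family_table()]).
#'   Missing entries must be `NA`.
#' @param variant a [sempgs_variant()]; `parental_phenotypes = TRUE`
#'   requires `y_p`, `y_m` columns.
#' @param fixed optional named numeric vector holding a subset of the free
#'   parameters at fixed values (e.g. `c(f = 0)` for a null fit).
#' @param start optional named start vector overriding the moment starts.
#' @param se compute standard errors (numeric Hessian); disable for speed
#'   in replicate studies where only estimates are needed.
#' @param control list: `reltol` (default 1e-10), `maxit` (default 2000),
#'   `verbose` (log the running `-2 logL` every 50 evaluations).
#' @return Object of class `sempgs_fit`: estimates, standard errors,
#'   `derived` quantities with delta-method SEs, `minus2ll`, convergence
#'   flag and gradient norm, missingness-pattern table, and bookkeeping.
#' @seealso [lrt()], [identifiability_check()], [summary.sempgs_fit()]
#' @export
fit_sempgs <- function(families, variant = sempgs_variant("equilibrium_constrained"),
                       fixed = NULL, start = NULL, se = TRUE,
                       control = list()) {
  stopifnot(inherits(variant, "sempgs_variant"))
  reltol <- control$reltol %||% 1e-10
  maxit <- control$maxit %||% 2000L
  fd <- prepare_fiml_data(families, variant)
  free_names <- free_par_names(variant)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% free_names))
      stop("'fixed' names must be free parameters of the variant")
    free_names <- setdiff(free_names, names(fixed))
  }
  informative <- sum(vapply(fd$patterns, function(p)
    if (length(p$obs) >= 2) p$n else 0L, numeric(1)))
  if (informative < 5 * length(free_names))
    stop("too few informative families (", informative,
         ") for ", length(free_names), " free parameters")

  st0 <- moment_starts(fd, variant)
  if (!is.null(start)) st0[names(start)] <- start
  if (!is.null(fixed)) st0 <- st0[setdiff(names(st0), names(fixed))]

  assemble <- function(free_nat) {
    if (!is.null(fixed)) c(free_nat, fixed) else free_nat
  }
  neg2ll_nat <- function(free_nat) {
    S <- tryCatch(sigma_from_free(as.list(assemble(free_nat)), variant, fd$s2hap),
                  error = function(e) NULL)
    if (is.null(S)) return(NA_real_)
    fiml_neg2ll(S, fd$patterns)
  }
  verbose <- isTRUE(control$verbose)
  n_eval <- 0L
  obj <- function(theta_t) {
    nat <- to_natural(stats::setNames(theta_t, tnames))
    v <- neg2ll_nat(nat)
    v <- if (!is.finite(v)) 1e10 + sum(theta_t^2) else v
    n_eval <<- n_eval + 1L
    if (verbose && n_eval %% 50L == 1L)
      message("[fit_sempgs] eval ", n_eval, ": -2logL = ",
              format(v, digits = 12))
    v
  }
  t0 <- to_transformed(st0)
  tnames <- names(t0)

  o1 <- stats::optim(t0, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = reltol))
  o2 <- tryCatch(stats::optim(o1$par, obj, method = "BFGS",
                              control = list(maxit = min(200L, maxit),
                                             reltol = reltol)),
                 error = function(e) o1)
  best <- if (o2$value <= o1$value) o2 else o1
  theta_t <- best$par
  # the latent path enters the covariance structure only through even
  # powers, so its sign is not identified; report the positive root
  if ("k" %in% tnames) theta_t[tnames == "k"] <- abs(theta_t[tnames == "k"])
  est <- to_natural(stats::setNames(theta_t, tnames))

  grad <- vapply(seq_along(theta_t), function(j) {
    h <- 1e-5 * (1 + abs(theta_t[j]))
    xp <- theta_t; xp[j] <- xp[j] + h
    xm <- theta_t; xm[j] <- xm[j] - h
    (obj(xp) - obj(xm)) / (2 * h)
  }, numeric(1))
  grad_norm <- max(abs(grad)) / max(1, abs(best$value))
  converged <- is.finite(best$value) && best$value < 1e9 &&
    grad_norm < 1e-4

  se_vec <- stats::setNames(rep(NA_real_, length(est)), names(est))
  vcov_nat <- NULL; hess_pd <- NA
  if (se) {
    H <- tryCatch(stats::optimHess(theta_t, obj), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      hess_pd <- all(ev > 0)
      Vt <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(Vt)) {
        # chain rule back to the natural scale
        J <- diag(length(est))
        iv <- which(names(est) == "V_eps")
        if (length(iv)) J[iv, iv] <- est[["V_eps"]]
        vcov_nat <- J %*% Vt %*% t(J)
        dimnames(vcov_nat) <- list(names(est), names(est))
        dg <- diag(vcov_nat)
        se_vec[dg > 0] <- sqrt(dg[dg > 0])
      }
    }
  }

  der_fn <- function(nat_vec)
    derived_from_free(as.list(assemble(nat_vec)), variant, fd$s2hap)
  derived_est <- der_fn(est)
  derived_se <- stats::setNames(rep(NA_real_, length(derived_est)),
                                names(derived_est))
  if (!is.null(vcov_nat)) {
    Jd <- tryCatch(num_jacobian(der_fn, est), error = function(e) NULL)
    if (!is.null(Jd)) {
      Vd <- Jd %*% vcov_nat %*% t(Jd)
      dg <- diag(Vd)
      derived_se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }

  pat_tab <- data.frame(
    pattern = vapply(fd$patterns, function(p) paste(p$vars, collapse = ","),
                     character(1)),
    n = vapply(fd$patterns, `[[`, numeric(1), "n"),
    n_vars = vapply(fd$patterns, function(p) length(p$obs), numeric(1)),
    row.names = NULL)
  pat_tab$covariance_informative <- pat_tab$n_vars >= 2

  structure(list(estimates = est, se = se_vec, vcov = vcov_nat,
                 derived = derived_est, derived_se = derived_se,
                 minus2ll = best$value, converged = converged,
                 grad_norm = grad_norm, hessian_pd = hess_pd,
                 n_families = fd$n, patterns = pat_tab,
                 s2hap = fd$s2hap, variant = variant, fixed = fixed,
                 free_names = names(est), start = st0,
                 means = fd$means),
            class = "sempgs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sempgs_fit <- function(x, ...) {
  cat("Haplotypic-PGS family model fit (", x$variant$name, ", ",
      if (x$variant$parental_phenotypes) "7" else "5",
      "-variable system)\n", sep = "")
  if (!x$converged) cat("*** NOT CONVERGED (gradient norm ",
                        format(x$grad_norm), ") ***\n", sep = "")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 5))
  cat("derived:\n")
  print(round(data.frame(estimate = x$derived, se = x$derived_se), 5))
  cat("-2 logL =", format(x$minus2ll, digits = 10),
      "| families =", x$n_families, "\n")
  if (!is.null(x$fixed))
    cat("fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object a `sempgs_fit`.
#' @param ... unused.
#' @return A list of class `sempgs_fit_summary` with an `parameters` table
#'   (every free parameter exactly once), derived quantities including the
#'   vertical-transmission variance share `V_F / V_Y`, the
#'   missingness-pattern table, and convergence diagnostics.
#' @export
summary.sempgs_fit <- function(object, ...) {
  x <- object
  out <- list(
    parameters = data.frame(parameter = names(x$estimates),
                            estimate = unname(x$estimates),
                            se = unname(x$se),
                            z = unname(x$estimates / x$se)),
    derived = data.frame(quantity = names(x$derived),
                         estimate = unname(x$derived),
                         se = unname(x$derived_se)),
    minus2ll = x$minus2ll, converged = x$converged,
    grad_norm = x$grad_norm, hessian_pd = x$hessian_pd,
    patterns = x$patterns, n_families = x$n_families,
    variant = x$variant$name, fixed = x$fixed)
  class(out) <- "sempgs_fit_summary"
  out
}

#' @export
print.sempgs_fit_summary <- function(x, ...) {
  if (!x$converged) cat("*** NOT CONVERGED ***\n")
  cat("Variant:", x$variant, "| families:", x$n_families,
      "| -2 logL:", format(x$minus2ll, digits = 10), "\n")
  print(x$parameters, digits = 5, row.names = FALSE)
  cat("Derived quantities:\n")
  print(x$derived, digits = 5, row.names = FALSE)
  cat("Missingness patterns:\n")
  print(x$patterns, row.names = FALSE)
  invisible(x)
}

#' Write fit reports (TSV and JSON-lines)
#'
#' @param fit a `sempgs_fit`.
#' @param prefix output path prefix; writes `<prefix>_parameters.tsv` and
#'   `<prefix>_report.jsonl`.
#' @return Invisibly, the two paths.
#' @export
write_fit_report <- function(fit, prefix) {
  s <- summary(fit)
  tab <- rbind(
    data.frame(name = s$parameters$parameter, type = "parameter",
               estimate = s$parameters$estimate, se = s$parameters$se),
    data.frame(name = s$derived$quantity, type = "derived",
               estimate = s$derived$estimate, se = s$derived$se))
  tsv <- paste0(prefix, "_parameters.tsv")
  atomic_write(c("name\ttype\testimate\tse",
                 sprintf("%s\t%s\t%s\t%s", tab$name, tab$type,
                         format(tab$estimate, digits = 10),
                         format(tab$se, digits = 10))), tsv)
  jl <- paste0(prefix, "_report.jsonl")
  recs <- c(
    jsonlite::toJSON(list(record = "meta", variant = s$variant,
                          n_families = s$n_families,
                          minus2ll = s$minus2ll, converged = s$converged),
                     auto_unbox = TRUE),
    vapply(seq_len(nrow(tab)), function(i)
      as.character(jsonlite::toJSON(as.list(tab[i, ]), auto_unbox = TRUE,
                                    na = "null")),
      character(1)))
  atomic_write(recs, jl)
  invisible(c(tsv, jl))
}

#' Likelihood-ratio test of nested fits
#'
#' @param null,alt `sempgs_fit` objects on the same data; the null's free
#'   parameters must be a subset of the alternative's.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "sempgs_fit"), inherits(alt, "sempgs_fit"))
  if (null$n_families != alt$n_families)
    stop("fits are not on the same data (different family counts)")
  if (!all(null$free_names %in% alt$free_names))
    stop("models are not nested: null free parameters not a subset of alt's")
  df <- length(alt$free_names) - length(null$free_names)
  if (df == 0 && !identical(sort(null$free_names), sort(alt$free_names)))
    stop("models are not nested")
  stat <- null$minus2ll - alt$minus2ll
  # tolerate optimizer round-off (relative to the deviance scale), but a
  # materially negative statistic signals a failed alternative fit
  if (stat < -max(1e-6, 1e-8 * abs(null$minus2ll)))
    stop("negative likelihood-ratio statistic (", format(stat),
         "): optimizer failure in one of the fits")
  stat <- max(stat, 0)
  p <- if (df == 0) as.numeric(stat <= 0) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Numeric identifiability diagnostics
#'
#' Computes the Jacobian of the unique elements of the model-implied
#' covariance matrix with respect to the free parameters at a probe point
#' and reports its numerical rank: the covariance structure identifies the
#' free parameters iff the Jacobian has full column rank.  The
#' seven-quantity claim of the 5-variable system - and structural
#' degeneracies such as `f` being unidentified at `delta = 0` - can be
#' checked directly.
#'
#' @param variant a [sempgs_variant()].
#' @param probe named vector of free-parameter values (natural scale).
#' @param s2hap haplotypic variance fixing the PGS scale (default 1).
#' @param tol singular values below `tol * max(sv)` count as null
#'   directions (default 1e-8).
#' @return List: `rank`, `n_free`, `identified`, `singular_values`,
#'   `null_directions` (matrix of near-null parameter combinations).
#' @export
identifiability_check <- function(variant, probe, s2hap = 1, tol = 1e-8) {
  free_names <- free_par_names(variant)
  if (!all(free_names %in% names(probe)))
    stop("probe must provide: ", paste(free_names, collapse = ", "))
  probe <- probe[free_names]
  vech_fn <- function(nat) {
    S <- sigma_from_free(as.list(nat), variant, s2hap)
    S[upper.tri(S, diag = TRUE)]
  }
  J <- num_jacobian(vech_fn, probe)
  sv <- svd(J)
  rank <- sum(sv$d > tol * max(sv$d))
  nullspace <- if (rank < length(probe))
    structure(sv$v[, (rank + 1):length(probe), drop = FALSE],
              dimnames = list(free_names, NULL))
  else NULL
  list(rank = rank, n_free = length(probe),
       identified = rank == length(probe),
       singular_values = sv$d, null_directions = nullspace,
       free_names = free_names)
}
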