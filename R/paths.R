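# Path diagram and chain enumeration.
#
# The diagram is the standard family path model: each parent's transmitted
# and nontransmitted haplotypic PGSs (plus latent haplotypic analogues when
# the PGS is partially predictive) load on the parent's phenotype with
# coefficient delta (k for latent); the two transmitted scores load directly
# on the offspring phenotype; each parental phenotype feeds the offspring
# familial environment with coefficient f; double-headed edges carry the
# haplotypic variances, the within-person assortment covariance g, and the
# genetic-nurture covariance w; a single copath mu joins the mates'
# mating-basis variables.  Prior-generation infinite regress is absorbed
# into the exogenous g and w edges, which is what makes the diagram finite.

PATH_LABELS <- c(pgs_t_p = "PGS_T,p", pgs_nt_p = "PGS_NT,p",
                 pgs_t_m = "PGS_T,m", pgs_nt_m = "PGS_NT,m",
                 lat_t_p = "LAT_T,p", lat_nt_p = "LAT_NT,p",
                 lat_t_m = "LAT_T,m", lat_nt_m = "LAT_NT,m",
                 F_p = "F_p", F_m = "F_m", F_o = "F_o",
                 y_p = "Y_p", y_m = "Y_m", y_o = "Y_o")

#' Build the family path diagram for a parameter set
#'
#' Constructs the directed-edge coefficient matrix, the symmetric
#' double-headed edge matrix, and the copath specification used by
#' [enumerate_paths()].  Edge values are taken from the parental-generation
#' state implied by the parameter set under the variant (so the diagram and
#' the closed-form expectations describe the same population).
#'
#' @inheritParams expected_covariance
#' @return A list of class `sempgs_diagram` with elements `nodes`, `A`
#'   (directed coefficients, `A[child, parent]`), `S` (double-headed
#'   values), `copath` (`mu` plus basis loading vectors for the two mates),
#'   and `observed`.
#' @export
path_diagram <- function(params, variant = sempgs_variant("equilibrium_constrained"),
                         haplotype_variance = NULL) {
  st <- implied_state(params, variant, s2hap = haplotype_variance)
  latent <- params$k != 0
  nodes <- c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m",
             if (latent) c("lat_t_p", "lat_nt_p", "lat_t_m", "lat_nt_m"),
             "F_p", "F_m", "y_p", "y_m", "F_o", "y_o")
  nn <- length(nodes)
  A <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  S <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  d <- params$delta; k <- params$k; f <- params$f
  A["y_p", c("pgs_t_p", "pgs_nt_p")] <- d
  A["y_m", c("pgs_t_m", "pgs_nt_m")] <- d
  A["y_p", "F_p"] <- 1; A["y_m", "F_m"] <- 1
  A["y_o", c("pgs_t_p", "pgs_t_m")] <- d
  A["F_o", c("y_p", "y_m")] <- f
  A["y_o", "F_o"] <- 1
  if (latent) {
    A["y_p", c("lat_t_p", "lat_nt_p")] <- k
    A["y_m", c("lat_t_m", "lat_nt_m")] <- k
    A["y_o", c("lat_t_p", "lat_t_m")] <- k
  }
  cbar <- (st$c_s + st$c_x) / 2
  fill_side <- function(S, hap, lat, Fv) {
    S[hap, hap] <- st$g; diag(S[hap, hap]) <- st$v
    S[hap, Fv] <- S[Fv, hap] <- st$w
    if (latent) {
      S[lat, lat] <- st$g_l; diag(S[lat, lat]) <- st$v_l
      S[lat, Fv] <- S[Fv, lat] <- st$w_l
      S[hap, lat] <- S[lat, hap] <- cbar
    }
    S[Fv, Fv] <- st$V_F
    S
  }
  S <- fill_side(S, c("pgs_t_p", "pgs_nt_p"), c("lat_t_p", "lat_nt_p"), "F_p")
  S <- fill_side(S, c("pgs_t_m", "pgs_nt_m"), c("lat_t_m", "lat_nt_m"), "F_m")
  S["y_p", "y_p"] <- S["y_m", "y_m"] <- S["y_o", "y_o"] <- params$V_eps
  lamF <- stats::setNames(numeric(nn), nodes)
  lamM <- lamF
  switch(variant$mating_basis,
    phenotypic = { lamF["y_p"] <- 1; lamM["y_m"] <- 1 },
    social = { lamF["F_p"] <- 1; lamM["F_m"] <- 1 },
    genetic = {
      lamF[c("pgs_t_p", "pgs_nt_p")] <- d; lamM[c("pgs_t_m", "pgs_nt_m")] <- d
      if (latent) {
        lamF[c("lat_t_p", "lat_nt_p")] <- k
        lamM[c("lat_t_m", "lat_nt_m")] <- k
      }
    })
  structure(list(nodes = nodes, A = A, S = S,
                 copath = list(mu = params$mu, father = lamF, mother = lamM),
                 observed = variable_order(variant$parental_phenotypes),
                 state = st),
            class = "sempgs_diagram")
}

# all directed paths ending at `node`, as list(nodes = chr vector from source
# to node, coeff = product of edge coefficients); includes the trivial path.
directed_paths_to <- function(diagram, node, memo = new.env(parent = emptyenv())) {
  if (!is.null(memo[[node]])) return(memo[[node]])
  A <- diagram$A
  out <- list(list(nodes = node, coeff = 1))
  parents <- colnames(A)[A[node, ] != 0]
  for (pa in parents) {
    for (sub in directed_paths_to(diagram, pa, memo)) {
      out[[length(out) + 1L]] <- list(nodes = c(sub$nodes, node),
                                      coeff = sub$coeff * A[node, pa])
    }
  }
  memo[[node]] <- out
  out
}

chain_string <- function(back, Suv, fwd, copath_lab = NULL) {
  lab <- function(x) unname(PATH_LABELS[x])
  left <- paste(rev(lab(back$nodes)), collapse = " <- ")
  right <- paste(lab(fwd$nodes), collapse = " -> ")
  mid <- if (back$nodes[1] == fwd$nodes[1] && length(Suv) == 1)
    paste0(" =", format(Suv, digits = 4), "= ") else
    paste0(" ~", format(Suv, digits = 4), "~ ")
  s <- paste0(left, mid, right)
  if (!is.null(copath_lab)) s else s
}

# all copath-free chains from a to b: (directed path u -> a, S[u, v],
# directed path v -> b), RAM semantics (the two legs may share nodes).
chains_nocopath <- function(diagram, a, b, memo) {
  Pa <- directed_paths_to(diagram, a, memo)
  Pb <- directed_paths_to(diagram, b, memo)
  S <- diagram$S
  out <- list()
  for (p1 in Pa) {
    u <- p1$nodes[1]
    vs <- colnames(S)[S[u, ] != 0]
    if (!length(vs)) next
    for (p2 in Pb) {
      v <- p2$nodes[1]
      if (!(v %in% vs)) next
      out[[length(out) + 1L]] <- list(back = p1, fwd = p2, Suv = S[u, v],
                                      contribution = p1$coeff * S[u, v] * p2$coeff)
    }
  }
  out
}

#' Enumerate legitimate covariance chains between two variables
#'
#' Lists every legitimate chain connecting `var_a` and `var_b` on the
#' diagram, with its numeric contribution; the contributions sum to the
#' model-implied covariance.  A chain runs backward along directed edges
#' from `var_a` to a source, crosses exactly one double-headed edge (a
#' variance when the two sources coincide), and runs forward to `var_b`;
#' the two legs may legitimately share pass-through nodes (needed for
#' variance chains through the offspring familial environment).  A chain may
#' additionally cross the copath once: it is then the splice of a chain from
#' `var_a` to one mate's mating-basis variable, the copath coefficient `mu`,
#' and a chain from the other mate's basis variable to `var_b` - so the
#' classic assortment chain from a nontransmitted score to the offspring
#' phenotype, `PGS_NT,p -> Y_p ~mu~ Y_m ... PGS_T,m -> Y_o`, appears with
#' contribution `theta * mu * theta_T` terms.
#'
#' @param diagram a [path_diagram()].
#' @param var_a,var_b node labels (see `diagram$nodes`).
#' @return A data frame with columns `path` (display string) and
#'   `contribution`; attribute `"total"` holds the summed covariance.
#' @export
enumerate_paths <- function(diagram, var_a, var_b) {
  stopifnot(inherits(diagram, "sempgs_diagram"))
  for (v in c(var_a, var_b))
    if (!v %in% diagram$nodes) stop("unknown node: ", v)
  memo <- new.env(parent = emptyenv())
  rows <- list()
  add <- function(str, contr)
    rows[[length(rows) + 1L]] <<- data.frame(path = str, contribution = contr,
                                             stringsAsFactors = FALSE)
  for (ch in chains_nocopath(diagram, var_a, var_b, memo))
    add(chain_string(ch$back, ch$Suv, ch$fwd), ch$contribution)
  mu <- diagram$copath$mu
  if (mu != 0) {
    lam <- list(diagram$copath$father, diagram$copath$mother)
    for (ord in list(c(1, 2), c(2, 1))) {
      lamL <- lam[[ord[1]]]; lamR <- lam[[ord[2]]]
      for (kf in names(lamL)[lamL != 0]) for (km in names(lamR)[lamR != 0]) {
        chL <- chains_nocopath(diagram, var_a, kf, memo)
        chR <- chains_nocopath(diagram, km, var_b, memo)
        for (cl in chL) for (cr in chR) {
          contr <- cl$contribution * lamL[[kf]] * mu * lamR[[km]] *
            cr$contribution
          str <- paste0(chain_string(cl$back, cl$Suv, cl$fwd),
                        " [", PATH_LABELS[kf], "] ~mu~ [", PATH_LABELS[km], "] ",
                        chain_string(cr$back, cr$Suv, cr$fwd))
          add(str, contr)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(path = character(), contribution = numeric())
  attr(out, "total") <- sum(out$contribution)
  out
}

#' Model-implied covariance by exhaustive path enumeration
#'
#' Independent assembly of the observed covariance matrix: every element is
#' the sum of [enumerate_paths()] contributions.  Used as a cross-check of
#' the closed-form [expected_covariance()]; the two agree to numerical
#' round-off for any valid parameter set.
#'
#' @inheritParams expected_covariance
#' @return Symmetric matrix over [variable_order()].
#' @export
expected_covariance_paths <- function(params,
                                      variant = sempgs_variant("equilibrium_constrained"),
                                      haplotype_variance = NULL) {
  dg <- path_diagram(params, variant, haplotype_variance)
  vars <- variable_order(variant$parental_phenotypes)
  nv <- length(vars)
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  for (i in seq_len(nv)) for (j in i:nv) {
    S[i, j] <- S[j, i] <- attr(enumerate_paths(dg, vars[i], vars[j]), "total")
  }
  S
}

#' Write the enumerated chains for one covariance as plain text
#'
#' Debug/teaching dump: one chain per line with its contribution, plus the
#' total.  Reproduces, for example, the genetic-nurture chain
#' `PGS_NT,p -> Y_p -> F_o -> Y_o` and the assortment chain through the
#' copath for the nontransmitted-offspring covariance.
#'
#' @param diagram a [path_diagram()].
#' @param var_a,var_b node labels.
#' @param file connection or path passed to [base::writeLines()]; default
#'   stdout.
#' @return Invisibly, the data frame from [enumerate_paths()].
#' @export
dump_paths <- function(diagram, var_a, var_b, file = stdout()) {
  pp <- enumerate_paths(diagram, var_a, var_b)
  lines <- c(sprintf("cov(%s, %s): %d chain(s), total %.6g",
                     PATH_LABELS[var_a], PATH_LABELS[var_b],
                     nrow(pp), attr(pp, "total")),
             sprintf("% .6g   %s", pp$contribution, pp$path))
  writeLines(lines, con = file)
  invisible(pp)
}
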