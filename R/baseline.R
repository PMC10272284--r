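#' Transmitted / nontransmitted PGS regression (baseline estimator)
#'
#' Ordinary least squares of the offspring phenotype on the summed
#' transmitted PGS (`pgs_t_p + pgs_t_m`) and the summed nontransmitted PGS
#' (`pgs_nt_p + pgs_nt_m`), with intercept.  The nontransmitted coefficient
#' is the genetic-nurture association - nontransmitted alleles are
#' genetically unrelated to the offspring, so absent assortment and
#' stratification their association with the offspring trait runs through
#' the parental phenotype and the rearing environment.  `beta_T - beta_NT`
#' estimates the direct-effect component under the no-assortment
#' assumption; under unmodeled assortative mating `beta_NT` is biased away
#' from zero by the transmitted-nontransmitted correlation, which is the
#' contrast the structural model resolves.
#'
#' @param families family table; only complete trios (all four PGSs and
#'   `y_o` present) are used, and the number dropped is reported.
#' @param separate_parents if `TRUE`, fit the four-regressor version with
#'   paternal and maternal scores entered separately (distinguishing
#'   paternal versus maternal nurture associations).
#' @return An object of class `kong_result`: coefficient table
#'   (`beta_T`, `beta_NT`, or the four parent-specific versions), their
#'   standard errors, `n` used and `n_dropped`.
#' @export
kong_regression <- function(families, separate_parents = FALSE) {
  need <- c("pgs_t_p", "pgs_nt_p", "pgs_t_m", "pgs_nt_m", "y_o")
  if (!all(need %in% names(families)))
    stop("family table lacks column(s): ",
         paste(setdiff(need, names(families)), collapse = ", "))
  cc <- stats::complete.cases(families[, need])
  d <- families[cc, need, drop = FALSE]
  if (nrow(d) < 4) stop("fewer complete trios than regression parameters")
  if (separate_parents) {
    for (v in need[1:4]) if (stats::sd(d[[v]]) == 0)
      stop("zero-variance regressor: ", v)
    fit <- stats::lm(y_o ~ pgs_t_p + pgs_t_m + pgs_nt_p + pgs_nt_m, data = d)
  } else {
    d$T_sum <- d$pgs_t_p + d$pgs_t_m
    d$NT_sum <- d$pgs_nt_p + d$pgs_nt_m
    if (stats::sd(d$T_sum) == 0 || stats::sd(d$NT_sum) == 0)
      stop("zero-variance regressor")
    fit <- stats::lm(y_o ~ T_sum + NT_sum, data = d)
  }
  co <- summary(fit)$coefficients
  co <- co[setdiff(rownames(co), "(Intercept)"), , drop = FALSE]
  out <- list(coefficients = data.frame(
                term = rownames(co), estimate = co[, 1], se = co[, 2],
                z = co[, 1] / co[, 2], row.names = NULL),
              beta_T = if (!separate_parents) co["T_sum", 1] else NA_real_,
              beta_NT = if (!separate_parents) co["NT_sum", 1] else NA_real_,
              se_T = if (!separate_parents) co["T_sum", 2] else NA_real_,
              se_NT = if (!separate_parents) co["NT_sum", 2] else NA_real_,
              n = nrow(d), n_dropped = sum(!cc), lm = fit)
  class(out) <- "kong_result"
  out
}

#' @export
print.kong_result <- function(x, ...) {
  cat("Transmitted/nontransmitted PGS regression (n =", x$n,
      "complete trios,", x$n_dropped, "dropped)\n")
  print(x$coefficients, digits = 5, row.names = FALSE)
  if (!is.na(x$beta_T))
    cat("direct-effect contrast beta_T - beta_NT =",
        format(x$beta_T - x$beta_NT, digits = 5), "\n")
  invisible(x)
}

#' Write a baseline-regression report
#' @param result a `kong_result`.
#' @param prefix output path prefix; writes `<prefix>_kong.tsv` and
#'   `<prefix>_kong.jsonl`.
#' @export
write_kong_report <- function(result, prefix) {
  co <- result$coefficients
  tsv <- paste0(prefix, "_kong.tsv")
  atomic_write(c("term\testimate\tse\tz",
                 sprintf("%s\t%s\t%s\t%s", co$term,
                         format(co$estimate, digits = 10),
                         format(co$se, digits = 10),
                         format(co$z, digits = 6))), tsv)
  jl <- paste0(prefix, "_kong.jsonl")
  recs <- c(jsonlite::toJSON(list(record = "meta", n = result$n,
                                  n_dropped = result$n_dropped),
                             auto_unbox = TRUE),
            vapply(seq_len(nrow(co)), function(i)
              as.character(jsonlite::toJSON(as.list(co[i, ]),
                                            auto_unbox = TRUE)),
              character(1)))
  atomic_write(recs, jl)
  invisible(c(tsv, jl))
}
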