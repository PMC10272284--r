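# File formats: family table TSV, SNP weight TSV, QC TSV, minimal VCF 4.2
# writer.  All writes are atomic (temp file in the target directory, then
# rename).  Missing values are empty strings; "." is rejected on read to
# avoid silent VCF-style missingness leaking into the table.

FAMILY_COLUMNS <- c("family_id", "pgs_t_p", "pgs_nt_p", "pgs_t_m",
                    "pgs_nt_m", "y_o", "y_p", "y_m")

atomic_write <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Write / read a family table
#'
#' Tab-separated, UTF-8, header row; empty string encodes a missing value.
#' Columns: `family_id`, the four haplotypic PGSs
#' (`pgs_t_p`, `pgs_nt_p`, `pgs_t_m`, `pgs_nt_m`), offspring phenotype
#' `y_o`, and optional parental phenotypes `y_p`, `y_m`.
#'
#' @param families data frame with (a subset of) the family columns.
#' @param path file path.
#' @return `write_family_table` returns the path invisibly;
#'   `read_family_table` returns the data frame with numeric columns and
#'   `NA` for missing entries.
#' @export
write_family_table <- function(families, path) {
  cols <- intersect(FAMILY_COLUMNS, names(families))
  if (!length(cols)) stop("no recognised family-table columns")
  df <- families[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  body <- vapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(seq_along(cols), function(j) {
      x <- df[i, j]
      if (is.na(x)) "" else if (num[j]) format(x, digits = 15) else as.character(x)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  atomic_write(c(paste(cols, collapse = "\t"), body), path)
}

#' @rdname write_family_table
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  unknown <- setdiff(names(df), FAMILY_COLUMNS)
  if (length(unknown))
    stop("unknown family-table column(s): ", paste(unknown, collapse = ", "))
  for (nm in setdiff(names(df), "family_id")) {
    x <- df[[nm]]
    if (any(x == ".", na.rm = TRUE))
      stop("'.' is not a valid missing-value code in column ", nm,
           " (use an empty field)")
    x[x == ""] <- NA_character_
    df[[nm]] <- as.numeric(x)
  }
  df
}

#' Write / read a SNP weight table
#'
#' Columns `snp_id`, `effect_allele`, `other_allele`, `beta` (per-allele
#' effect weight).
#'
#' @param weights data frame with the four columns.
#' @param path file path.
#' @export
write_weight_table <- function(weights, path) {
  need <- c("snp_id", "effect_allele", "other_allele", "beta")
  if (!all(need %in% names(weights))) stop("weight table needs columns: ",
                                           paste(need, collapse = ", "))
  if (anyDuplicated(weights$snp_id)) stop("duplicate snp_id in weight table")
  body <- sprintf("%s\t%s\t%s\t%s", weights$snp_id, weights$effect_allele,
                  weights$other_allele, format(weights$beta, digits = 15))
  atomic_write(c(paste(need, collapse = "\t"), body), path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "beta")
  if (!all(need %in% names(df))) stop("weight table needs columns: ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in weight table")
  if (any(df$effect_allele == df$other_allele))
    stop("effect_allele must differ from other_allele")
  df$beta <- as.numeric(df$beta)
  df
}

#' Write simulated phased trio genotypes as VCF 4.2
#'
#' Minimal VCF with pipe-phased GT fields and three sample columns per trio
#' (`<fam>_F`, `<fam>_M`, `<fam>_C`); child haplotype 1 is paternal and
#' haplotype 2 maternal (pedigree-phase convention expected by
#' [compute_haplotypic_pgs()]).
#'
#' @param genotypes the `genotypes` element of an allele-level
#'   [simulate_population()] run.
#' @param path file path.
#' @return The implied pedigree data frame (columns `family_id`, `father`,
#'   `mother`, `child`), invisibly usable with [read_trio_vcf()].
#' @export
write_trio_vcf <- function(genotypes, path) {
  g <- genotypes
  fam <- g$family_id
  samples <- as.vector(rbind(paste0(fam, "_F"), paste0(fam, "_M"),
                             paste0(fam, "_C")))
  header <- c("##fileformat=VCFv4.2",
              "##source=sempgs",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- function(H1, H2, l) paste0(H1[, l], "|", H2[, l])
  n_loci <- nrow(g$loci)
  body <- vapply(seq_len(n_loci), function(l) {
    cells <- as.vector(rbind(gt(g$father$H1, g$father$H2, l),
                             gt(g$mother$H1, g$mother$H2, l),
                             gt(g$child$H1, g$child$H2, l)))
    paste(c(g$loci$chrom[l], g$loci$pos[l], g$loci$snp_id[l], g$loci$ref[l],
            g$loci$alt[l], ".", "PASS", ".", "GT", cells), collapse = "\t")
  }, character(1))
  atomic_write(c(header, body), path)
  invisible(data.frame(family_id = fam,
                       father = paste0(fam, "_F"),
                       mother = paste0(fam, "_M"),
                       child = paste0(fam, "_C"),
                       stringsAsFactors = FALSE))
}

#' Read phased trio genotypes from a VCF
#'
#' Thin wrapper over [vcfR::read.vcfR()] extracting phased GT fields for the
#' trios named in `pedigree`.  Unphased genotypes are a hard error: the
#' scorer's transmission assignment requires pedigree phase.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param pedigree data frame with columns `family_id`, `father`, `mother`,
#'   `child` naming VCF sample columns.  If `NULL`, samples following the
#'   `<fam>_F`/`_M`/`_C` convention are auto-grouped.
#' @return A `sempgs_trios` list: `loci` (chrom, pos, snp_id, ref, alt) and
#'   per-trio phased allele matrices.
#' @export
read_trio_vcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (is.null(pedigree)) {
    ch <- grep("_C$", samples, value = TRUE)
    fam <- sub("_C$", "", ch)
    pedigree <- data.frame(family_id = fam, father = paste0(fam, "_F"),
                           mother = paste0(fam, "_M"), child = ch,
                           stringsAsFactors = FALSE)
  }
  need <- c(pedigree$father, pedigree$mother, pedigree$child)
  missing <- setdiff(need, samples)
  if (length(missing)) stop("samples not in VCF: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (any(grepl("/", gt[, need], fixed = TRUE)))
    stop("unphased genotype(s) found; the haplotypic scorer requires ",
         "pedigree-phased data (GT with '|')")
  hap_mats <- function(cols) {
    H1 <- t(vapply(cols, function(cl) as.integer(
      vapply(strsplit(gt[, cl], "|", fixed = TRUE), `[`, character(1), 1L)),
      integer(nrow(gt))))
    H2 <- t(vapply(cols, function(cl) as.integer(
      vapply(strsplit(gt[, cl], "|", fixed = TRUE), `[`, character(1), 2L)),
      integer(nrow(gt))))
    list(H1 = unname(H1), H2 = unname(H2))
  }
  out <- list(loci = data.frame(chrom = fix[, "CHROM"],
                                pos = as.integer(fix[, "POS"]),
                                snp_id = fix[, "ID"], ref = fix[, "REF"],
                                alt = fix[, "ALT"], stringsAsFactors = FALSE),
              father = hap_mats(pedigree$father),
              mother = hap_mats(pedigree$mother),
              child = hap_mats(pedigree$child),
              family_id = pedigree$family_id)
  class(out) <- "sempgs_trios"
  out
}

#' Write a QC report
#'
#' One row per trio: loci used and dropped by reason.
#' @param qc data frame from [compute_haplotypic_pgs()].
#' @param path file path.
#' @export
write_qc_table <- function(qc, path) {
  body <- sprintf("%s\t%d\t%d\t%d", qc$trio_id, qc$n_loci_used,
                  qc$n_dropped_mendelian, qc$n_dropped_allele_mismatch)
  atomic_write(c("trio_id\tn_loci_used\tn_dropped_mendelian\tn_dropped_allele_mismatch",
                 body), path)
}
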