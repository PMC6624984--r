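#' Genotype matrix container
#'
#' Biallelic-first genotype container: a `sites` tibble (one row per variant
#' record, 0-based positions) plus an integer matrix of alt-allele dosages
#' (sites x accessions; 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing).
#' Multiallelic records are retained but flagged so that filtering can decide
#' their fate; their dosages refer to the first ALT allele.
#'
#' @param sites Tibble with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `dp` (per-site total read depth) and `multiallelic` (logical).
#' @param gt Integer matrix, `nrow(sites)` rows, one named column per
#'   accession, values in `{0, 1, 2, NA}`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, gt) {
  stopifnot(is.data.frame(sites), is.matrix(gt), nrow(sites) == nrow(gt))
  need <- c("chrom", "pos", "ref", "alt", "dp", "multiallelic")
  miss <- setdiff(need, names(sites))
  if (length(miss)) abort(paste0("sites is missing columns: ", toString(miss)))
  if (is.null(colnames(gt))) abort("gt must have accession column names")
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad)) abort("genotype codes must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  split_pos <- split(sites$pos, sites$chrom)
  if (any(vapply(split_pos, function(p) any(diff(p) <= 0), logical(1)))) {
    abort("site positions must be strictly increasing within each chromosome")
  }
  structure(list(sites = as_tibble(sites), gt = gt), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d sites x %d accessions on %d chromosome(s)\n",
    nrow(x$sites), ncol(x$gt), length(unique(x$sites$chrom))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$sites), ncol(x$gt))

#' Accession names of a genotype matrix
#' @param x A `geno_matrix`.
#' @return Character vector of accession ids.
#' @export
accessions <- function(x) colnames(x$gt)

# subset sites by logical/integer index, keeping the container valid
geno_subset <- function(x, idx) {
  structure(list(sites = x$sites[idx, , drop = FALSE],
                 gt = x$gt[idx, , drop = FALSE]),
            class = "geno_matrix")
}

# per-site called-allele count and alt-allele frequency over a set of columns
allele_stats <- function(gt, cols) {
  sub <- gt[, cols, drop = FALSE]
  called <- 2L * rowSums(!is.na(sub))
  alt <- rowSums(sub, na.rm = TRUE)
  p <- ifelse(called > 0, alt / called, NA_real_)
  list(n = called, p = p)
}

#' Build or validate a population panel
#'
#' A panel maps every accession to exactly one population label.
#'
#' @param accession Character vector of accession ids.
#' @param population Character vector of population labels, same length.
#' @param allowed Optional character vector of permitted labels.
#' @return Tibble with columns `accession`, `population`.
#' @export
population_panel <- function(accession, population, allowed = NULL) {
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    abort(paste0("accession(s) labelled more than once: ", toString(dup)))
  }
  if (length(accession) != length(population)) {
    abort("accession and population must have equal length")
  }
  if (!is.null(allowed)) {
    bad <- setdiff(unique(population), allowed)
    if (length(bad)) {
      abort(paste0("unknown population label(s): ", toString(bad),
                   "; allowed: ", toString(allowed)))
    }
  }
  tibble(accession = as.character(accession), population = as.character(population))
}

panel_members <- function(panel, pops) {
  panel$accession[panel$population %in% pops]
}
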