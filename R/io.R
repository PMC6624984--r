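# Readers and writers. One coordinate convention everywhere: 0-based
# half-open. VCF is the single 1-based surface; the conversion happens here
# and nowhere else. gzip is handled transparently by readr / vcfR.

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into alt-allele dosages. 1-based VCF positions become
#' 0-based internal positions. Multiallelic records are kept and flagged;
#' genotypes involving an allele other than REF or the first ALT are stored
#' as missing (site filtering normally removes such records). Per-site total
#' depth is taken from INFO/DP when present.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) abort("VCF contains no records")
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|]", "/", gt_raw)
  code <- matrix(NA_integer_, nrow = n, ncol = ncol(gt_raw),
                 dimnames = list(NULL, colnames(gt_raw)))
  code[alleles == "0/0"] <- 0L
  code[alleles == "0/1" | alleles == "1/0"] <- 1L
  code[alleles == "1/1"] <- 2L
  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.double(fix$POS) - 1,   # 1-based VCF -> 0-based internal
    ref = fix$REF, alt = fix$ALT,
    dp = ifelse(is.na(dp), NA_integer_, dp),
    multiallelic = grepl(",", fix$ALT)
  )
  geno_matrix(sites, code)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Internal 0-based positions are written as 1-based POS; INFO carries DP and
#' FORMAT is GT. `read_vcf(write_vcf(x, f))` reproduces all retained fields.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @param extra_header Optional character vector of extra `##` header lines
#'   (e.g. a config echo).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, extra_header = character()) {
  s <- geno$sites
  gt_txt <- matrix(c("0/0", "0/1", "1/1")[geno$gt + 1L], nrow = nrow(s))
  gt_txt[is.na(geno$gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    extra_header,
    sprintf("##contig=<ID=%s>", unique(s$chrom)),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions(geno)), collapse = "\t")
  )
  body <- paste(s$chrom, format(s$pos + 1, scientific = FALSE, trim = TRUE),
                ".", s$ref, s$alt, ".", ".",
                ifelse(is.na(s$dp), ".", paste0("DP=", s$dp)), "GT",
                apply(gt_txt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a window read-depth track
#'
#' Expects columns `accession`, `chrom`, `window_start`, `raw_depth`
#' (and passes through `norm_depth` if present). Window starts must be
#' ascending within each accession/chromosome.
#'
#' @param path TSV path (optionally gzipped; `#` lines are comments).
#' @return Depth-track tibble.
#' @export
read_depth_track <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("accession", "chrom", "window_start", "raw_depth")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("depth track missing column(s): ", toString(miss)))
  bad <- x |>
    group_by(.data$accession, .data$chrom) |>
    summarise(mono = all(diff(.data$window_start) > 0) || n() == 1, .groups = "drop")
  if (!all(bad$mono)) abort("window_start must be strictly increasing within accession/chromosome")
  x
}

#' Read a divergent-site track
#'
#' Expects columns `accession`, `chrom`, `window_start`, `divergent_count`,
#' `covered_bp` on a non-overlapping window grid.
#'
#' @param path TSV path.
#' @return Divergence-track tibble.
#' @export
read_divergence_track <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("accession", "chrom", "window_start", "divergent_count", "covered_bp")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("divergence track missing column(s): ", toString(miss)))
  x
}

#' Read an accession-to-population panel
#'
#' Two-column TSV (`accession`, `population`). Duplicate accessions are an
#' error; when `allowed` is given, unknown labels error and the message lists
#' the permitted set.
#'
#' @param path TSV path.
#' @param allowed Optional character vector of permitted population labels.
#' @return Panel tibble.
#' @export
read_panel <- function(path, allowed = NULL) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  miss <- setdiff(c("accession", "population"), names(x))
  if (length(miss)) abort(paste0("panel missing column(s): ", toString(miss)))
  population_panel(x$accession, x$population, allowed = allowed)
}

#' Write / read BED intervals
#'
#' BED3+ with optional extra columns; coordinates are written as-is
#' (internal convention is already BED-native 0-based half-open).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional extras.
#' @param path File path.
#' @param header Optional `#` comment lines to prepend.
#' @return `path` invisibly; `read_bed` returns a tibble.
#' @export
write_bed <- function(intervals, path, header = character()) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss)) abort(paste0("intervals missing column(s): ", toString(miss)))
  intervals <- intervals[, c(need, setdiff(names(intervals), need)), drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("#", header), con)
  lines <- do.call(paste, c(lapply(intervals, function(col) {
    if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE) else as.character(col)
  }), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names Column names to assign (`read_bed`); defaults to
#'   chrom/start/end plus `V4`, `V5`, ... for extras.
#' @export
read_bed <- function(path, col_names = NULL) {
  x <- readr::read_tsv(path, comment = "#", col_names = FALSE, show_col_types = FALSE)
  if (nrow(x) == 0) return(genomic_intervals())
  nm <- c("chrom", "start", "end")
  if (is.null(col_names)) {
    col_names <- c(nm, paste0("V", seq_len(max(0, ncol(x) - 3)) + 3))
  }
  names(x) <- col_names[seq_len(ncol(x))]
  x$start <- as.double(x$start); x$end <- as.double(x$end)
  x
}

#' Read QTL intervals
#'
#' TSV with columns `chrom`, `start`, `end`, `trait`. A row carrying only a
#' point position (`end` missing or equal to `start`) is stored as a
#' zero-length anchor (`end == start`) for later symmetric extension by
#' [qtl_colocalize()].
#'
#' @param path TSV path.
#' @return Tibble: `chrom`, `start`, `end`, `trait`, `is_point`.
#' @export
read_qtl <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  miss <- setdiff(c("chrom", "start", "trait"), names(x))
  if (length(miss)) abort(paste0("QTL table missing column(s): ", toString(miss)))
  end <- if ("end" %in% names(x)) as.double(x$end) else NA_real_
  end[is.na(end)] <- as.double(x$start)[is.na(end)]
  tibble(chrom = as.character(x$chrom), start = as.double(x$start), end = end,
         trait = as.character(x$trait), is_point = end == as.double(x$start))
}

# standard "# key: value" provenance header used by the CLI and run_demo()
output_header <- function(config_hash, seed) {
  c(sprintf(" introsweep %s", as.character(utils::packageVersion("introsweep"))),
    sprintf(" config_hash: %s", config_hash),
    sprintf(" seed: %d", seed))
}
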