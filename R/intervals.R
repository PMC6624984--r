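# Interval helpers. Every coordinate in this package is 0-based, half-open
# [start, end); VCF POS is the only 1-based surface (see read_vcf/write_vcf).

#' Build a tibble of genomic intervals
#'
#' Light constructor used internally and by the simulator; validates the
#' 0-based half-open convention (`0 <= start < end`).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like vectors, 0-based half-open.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(), end = integer()) {
  start <- as.double(start)
  end <- as.double(end)
  if (any(start < 0) || any(start >= end)) {
    abort("intervals must satisfy 0 <= start < end (0-based, half-open)")
  }
  tibble(chrom = as.character(chrom), start = start, end = end)
}

# length of the intersection of [s1,e1) and [s2,e2); 0 when disjoint
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# TRUE when the shared length strictly exceeds `frac` of BOTH interval lengths
reciprocal_overlap <- function(s1, e1, s2, e2, frac = 0.5, strict = TRUE) {
  ov <- overlap_len(s1, e1, s2, e2)
  if (strict) ov > frac * (e1 - s1) & ov > frac * (e2 - s2)
  else ov >= frac * (e1 - s1) & ov >= frac * (e2 - s2)
}

# union of possibly-overlapping intervals on one chromosome -> disjoint set
reduce_intervals <- function(start, end) {
  if (length(start) == 0) return(tibble(start = double(), end = double()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  k <- 1L
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1L
      out_s[k] <- start[i]; out_e[k] <- end[i]
    }
  }
  tibble(start = out_s, end = out_e)
}

# union-find for single-linkage components
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}
uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

# subgenome letter from wheat-style chromosome names ("1A", "chr3B"), else
# the chromosome name itself
subgenome_of <- function(chrom) {
  out <- chrom
  hit <- grepl("[0-9][A-Z]$", chrom)
  out[hit] <- sub("^.*[0-9]([A-Z])$", "\\1", chrom[hit])
  out
}
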