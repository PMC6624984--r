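# Windowed diversity statistics. Per site with n called alleles and alt
# frequency p the unbiased heterozygosity is (n/(n-1)) * 2p(1-p); window pi
# divides the per-site sum by the physical window length, so adding
# monomorphic records never changes pi. Fst is Hudson's ratio-of-sums
# 1 - sum(Hw)/sum(Hb) with Hb = pa(1-pb) + pb(1-pa).

#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp (default 100 kb).
#' @return Tibble: `chrom`, `start`, `end` (last window truncated at the
#'   chromosome end).
#' @export
make_windows <- function(chrom_lengths, size = 100000L) {
  bind_rows(lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    s <- seq(0, L - 1, by = size)
    tibble(chrom = ch, start = s, end = pmin(s + size, L))
  }))
}

# window index (row of `windows`) for each site; NA when outside all windows
assign_windows <- function(chrom, pos, windows) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    w <- which(windows$chrom == ch)
    if (length(w) == 0) next
    sel <- which(chrom == ch)
    o <- order(windows$start[w])
    w <- w[o]
    k <- findInterval(pos[sel], windows$start[w])
    ok <- k >= 1 & pos[sel] < windows$end[w][pmax(k, 1)]
    out[sel[ok]] <- w[k[ok]]
  }
  out
}

site_pi <- function(gt, cols) {
  st <- allele_stats(gt, cols)
  ifelse(st$n >= 2, (st$n / (st$n - 1)) * 2 * st$p * (1 - st$p), NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Per-bp pi per window for one population: the sum of per-site unbiased
#' heterozygosities divided by the physical window length. A window whose
#' every site has fewer than two called alleles in the population is
#' reported missing; a window without sites is 0 (monomorphic).
#'
#' @param geno A [geno_matrix()].
#' @param panel Population panel.
#' @param pop Population label(s) defining the sample.
#' @param windows Non-overlapping window tibble (see [make_windows()]).
#' @return `windows` with `n_snps` and `pi` columns.
#' @export
pi_window <- function(geno, panel, pop, windows) {
  cols <- panel_members(panel, pop)
  if (length(cols) == 0) abort(paste0("no accessions in population(s): ", toString(pop)))
  ps <- site_pi(geno$gt, cols)
  wi <- assign_windows(geno$sites$chrom, geno$sites$pos, windows)
  n_snps <- tabulate(wi, nbins = nrow(windows))
  informative <- tabulate(wi[!is.na(ps)], nbins = nrow(windows))
  sums <- rep(0, nrow(windows))
  keep <- !is.na(wi) & !is.na(ps)
  if (any(keep)) {
    agg <- rowsum(ps[keep], wi[keep])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  windows |>
    mutate(n_snps = n_snps,
           pi = ifelse(n_snps > 0 & informative == 0, NA_real_,
                       sums / (.data$end - .data$start)))
}

#' Windowed Hudson Fst
#'
#' Ratio-of-sums Hudson estimator per window between two populations,
#' using only sites where both populations have at least two called
#' alleles. Windows with fewer than `min_snps` usable SNPs are reported
#' missing (the estimator's variance blows up on sparse windows). Negative
#' values are reported as-is, not clipped.
#'
#' @param geno A [geno_matrix()].
#' @param panel Population panel.
#' @param pop_a,pop_b Population label(s) of the two samples.
#' @param windows Non-overlapping window tibble.
#' @param min_snps Minimum usable SNPs per window (default 20).
#' @return `windows` with `n_snps` and `fst` columns.
#' @export
fst_window <- function(geno, panel, pop_a, pop_b, windows, min_snps = 20L) {
  ca <- panel_members(panel, pop_a); cb <- panel_members(panel, pop_b)
  if (length(ca) == 0 || length(cb) == 0) {
    abort("both populations must contain at least one accession")
  }
  sa <- allele_stats(geno$gt, ca); sb <- allele_stats(geno$gt, cb)
  used <- sa$n >= 2 & sb$n >= 2
  hw <- ((sa$n / (sa$n - 1)) * 2 * sa$p * (1 - sa$p) +
         (sb$n / (sb$n - 1)) * 2 * sb$p * (1 - sb$p)) / 2
  hb <- sa$p * (1 - sb$p) + sb$p * (1 - sa$p)
  wi <- assign_windows(geno$sites$chrom, geno$sites$pos, windows)
  keep <- used & !is.na(wi)
  n_used <- tabulate(wi[keep], nbins = nrow(windows))
  sum_w <- sum_b <- rep(0, nrow(windows))
  if (any(keep)) {
    aw <- rowsum(hw[keep], wi[keep]); ab <- rowsum(hb[keep], wi[keep])
    sum_w[as.integer(rownames(aw))] <- aw[, 1]
    sum_b[as.integer(rownames(ab))] <- ab[, 1]
  }
  windows |>
    mutate(n_snps = n_used,
           fst = ifelse(n_used >= min_snps & sum_b > 0, 1 - sum_w / sum_b, NA_real_))
}

#' Windowed dxy between two accessions
#'
#' Expected per-bp difference between one haplotype drawn from each
#' accession: per co-called site `px(1-py) + py(1-px)` with `p = dosage/2`,
#' summed and divided by the physical window length. Sites missing in either
#' accession are excluded from the numerator only.
#'
#' @param geno A [geno_matrix()].
#' @param accession_x,accession_y Accession ids.
#' @param windows Non-overlapping window tibble.
#' @return `windows` with a `dxy` column.
#' @export
dxy_pair <- function(geno, accession_x, accession_y, windows) {
  px <- geno$gt[, accession_x] / 2
  py <- geno$gt[, accession_y] / 2
  d <- px * (1 - py) + py * (1 - px)
  wi <- assign_windows(geno$sites$chrom, geno$sites$pos, windows)
  keep <- !is.na(d) & !is.na(wi)
  sums <- rep(0, nrow(windows))
  if (any(keep)) {
    agg <- rowsum(d[keep], wi[keep])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  mutate(windows, dxy = sums / (.data$end - .data$start))
}

# mean per-bp dxy over a region, averaged over all x-y accession pairs
mean_dxy_region <- function(geno, xs, ys, chrom, start, end) {
  sel <- geno$sites$chrom == chrom & geno$sites$pos >= start & geno$sites$pos < end
  gx <- geno$gt[sel, xs, drop = FALSE] / 2
  gy <- geno$gt[sel, ys, drop = FALSE] / 2
  len <- end - start
  vals <- outer(seq_along(xs), seq_along(ys), Vectorize(function(i, j) {
    d <- gx[, i] * (1 - gy[, j]) + gy[, j] * (1 - gx[, i])
    sum(d, na.rm = TRUE) / len
  }))
  mean(vals)
}

#' Combined per-window statistics table
#'
#' Convenience wrapper: one window table carrying `pi_<pop>` for every
#' requested population and `fst_<a>_<b>` for every requested pair.
#'
#' @param geno A [geno_matrix()].
#' @param panel Population panel.
#' @param windows Non-overlapping window tibble.
#' @param pops Character vector of populations to compute pi for.
#' @param fst_pairs Optional list of 2-element character vectors.
#' @param min_snps Minimum SNPs for Fst windows.
#' @return Window tibble with `n_snps`, `pi_*` and `fst_*` columns.
#' @export
window_stats <- function(geno, panel, windows, pops, fst_pairs = NULL, min_snps = 20L) {
  out <- windows
  first <- TRUE
  for (pop in pops) {
    w <- pi_window(geno, panel, pop, windows)
    if (first) { out$n_snps <- w$n_snps; first <- FALSE }
    out[[paste0("pi_", pop)]] <- w$pi
  }
  for (pair in fst_pairs %||% list()) {
    w <- fst_window(geno, panel, pair[[1]], pair[[2]], windows, min_snps = min_snps)
    out[[paste0("fst_", pair[[1]], "_", pair[[2]])]] <- w$fst
  }
  out
}

# integers d in [lo, hi) intersected with 1..M (one ramp of distances)
ramp_count <- function(M, lo, hi) {
  pmax(0, pmin(hi - 1, M) - pmax(lo, 1) + 1)
}

#' Diversity as a function of distance to the nearest gene
#'
#' Each site gets its distance in bp to the nearest gene base (0 inside a
#' gene, including the start/end boundary bases); per-site diversity is
#' aggregated per distance bin and divided by the total number of genomic
#' bases falling in that bin, so the profile is a per-bp pi comparable
#' across bins.
#'
#' @param geno A [geno_matrix()].
#' @param panel Population panel.
#' @param pop Population label(s).
#' @param genes Gene interval tibble (`chrom`, `start`, `end`); overlapping
#'   genes are merged.
#' @param chrom_lengths Named chromosome lengths (needed for the per-bin
#'   base totals).
#' @param breaks Ascending distance-bin edges starting at 0; bins are
#'   `[breaks[i], breaks[i+1])` with the first bin (distance 0) genic.
#' @return Tibble: `bin_lo`, `bin_hi`, `n_sites`, `bp`, `pi`.
#' @export
pi_by_gene_distance <- function(geno, panel, pop, genes, chrom_lengths,
                                breaks = c(0, 1, 5e3, 2e4, 1e5, Inf)) {
  if (nrow(genes) == 0) abort("gene annotation is empty")
  if (breaks[1] != 0 || is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be strictly increasing and start at 0")
  }
  cols <- panel_members(panel, pop)
  ps <- site_pi(geno$gt, cols)
  nb <- length(breaks) - 1
  bin_sites <- integer(nb); bin_pi <- numeric(nb); bin_bp <- numeric(nb)

  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    merged <- reduce_intervals(g$start, g$end)
    gs <- merged$start; ge <- pmin(merged$end, L)
    # per-bin genomic base totals
    bin_bp[1] <- bin_bp[1] + sum(ge - gs)               # genic bases, distance 0
    gaps <- if (length(gs) == 0) tibble(a = 0, b = L, left = FALSE, right = FALSE) else
      tibble(a = c(0, ge), b = c(gs, L),
             left = c(FALSE, rep(TRUE, length(ge))),    # gene on the left edge?
             right = c(rep(TRUE, length(gs)), FALSE))
    for (i in seq_len(nrow(gaps))) {
      G <- gaps$b[i] - gaps$a[i]
      if (G <= 0) next
      for (k in seq_len(nb)) {
        lo <- breaks[k]; hi <- breaks[k + 1]
        if (gaps$left[i] && gaps$right[i]) {
          half <- G %/% 2
          cnt <- 2 * ramp_count(half, lo, hi)
          if (G %% 2 == 1) cnt <- cnt + (lo <= (G + 1) / 2 && (G + 1) / 2 < hi)
        } else if (gaps$left[i] || gaps$right[i]) {
          cnt <- ramp_count(G, lo, hi)
        } else {
          cnt <- 0   # chromosome with no gene: no defined distance
        }
        bin_bp[k] <- bin_bp[k] + cnt
      }
    }
    # per-site distances
    sel <- which(geno$sites$chrom == ch)
    if (length(sel) == 0 || length(gs) == 0) next
    x <- geno$sites$pos[sel]
    k <- findInterval(x, gs)
    inside <- k >= 1 & x < ge[pmax(k, 1)]
    d_left <- ifelse(k >= 1, x - (ge[pmax(k, 1)] - 1), Inf)
    d_right <- ifelse(k < length(gs), gs[pmin(k + 1, length(gs))] - x, Inf)
    dist <- ifelse(inside, 0, pmin(d_left, d_right))
    bk <- findInterval(dist, breaks)
    ok <- bk >= 1 & bk <= nb & is.finite(dist)
    for (k2 in unique(bk[ok])) {
      in_bin <- sel[ok & bk == k2]
      bin_sites[k2] <- bin_sites[k2] + length(in_bin)
      bin_pi[k2] <- bin_pi[k2] + sum(ps[in_bin], na.rm = TRUE)
    }
  }
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
         n_sites = bin_sites, bp = bin_bp,
         pi = ifelse(bin_bp > 0, bin_pi / bin_bp, NA_real_))
}
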