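# Fixture builders and independent brute-force oracles used across tests.

# small genotype matrix from an explicit dosage matrix
make_geno <- function(gt, pos = NULL, chrom = "chr1", dp = 600L,
                      multiallelic = FALSE, ref = "A", alt = "T") {
  n <- nrow(gt)
  if (is.null(colnames(gt))) colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  sites <- tibble::tibble(
    chrom = chrom,
    pos = if (is.null(pos)) seq(0, by = 100, length.out = n) else pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    dp = rep_len(as.integer(dp), n),
    multiallelic = rep_len(multiallelic, n)
  )
  geno_matrix(sites, gt)
}

make_panel <- function(...) {
  pops <- list(...)
  tibble::tibble(
    accession = unlist(pops, use.names = FALSE),
    population = rep(names(pops), lengths(pops))
  )
}

# depth track on a regular grid from a vector of raw depths
make_depth <- function(raw, accession = "acc1", chrom = "chr1", step = 500) {
  tibble::tibble(accession = accession, chrom = chrom,
                 window_start = step * (seq_along(raw) - 1),
                 raw_depth = raw)
}

# --- independent CNV oracle -------------------------------------------------
# Chains flags and merges calls by direct enumeration of the rules:
# every span of `span` consecutive windows with >= min_hits flags seeds its
# windows; maximal seeded runs trimmed to outermost flags become calls;
# adjacent calls merge (restarting from scratch after every merge) while the
# gap is under gap_frac of the combined length.
oracle_cnv <- function(hits, min_hits = 5, span = 7, window_size = 1000,
                       step = 500, gap_frac = 0.2) {
  n <- length(hits)
  seeded <- rep(FALSE, n)
  if (n >= span) {
    for (i in 1:(n - span + 1)) {
      if (sum(hits[i:(i + span - 1)]) >= min_hits) seeded[i:(i + span - 1)] <- TRUE
    }
  }
  calls <- list()
  i <- 1
  while (i <= n) {
    if (!seeded[i]) { i <- i + 1; next }
    j <- i
    while (j < n && seeded[j + 1]) j <- j + 1
    idx <- i:j
    fl <- idx[hits[idx]]
    if (length(fl) > 0) {
      a <- min(fl); b <- max(fl)
      calls[[length(calls) + 1]] <- c(step * (a - 1), step * (b - 1) + window_size)
    }
    i <- j + 1
  }
  # merge to fixed point, re-scanning from the left after every merge
  repeat {
    merged <- FALSE
    if (length(calls) >= 2) {
      for (k in 1:(length(calls) - 1)) {
        a <- calls[[k]]; b <- calls[[k + 1]]
        gap <- b[1] - a[2]
        if (gap < gap_frac * ((a[2] - a[1]) + (b[2] - b[1]))) {
          calls[[k]] <- c(a[1], max(a[2], b[2]))
          calls[[k + 1]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  if (length(calls) == 0) {
    return(tibble::tibble(start = double(), end = double()))
  }
  tibble::tibble(start = vapply(calls, `[`, double(1), 1),
                 end = vapply(calls, `[`, double(1), 2))
}

# run the package's flag -> chain -> merge path on a raw flag pattern by
# fabricating a depth track whose normalized depths trigger exactly `hits`
cnv_pipeline_from_hits <- function(hits, min_hits = 5, span = 7,
                                   window_size = 1000, step = 500,
                                   gap_frac = 0.2) {
  raw <- ifelse(hits, 0L, 30L)
  # pad with enough normal windows that the median stays 30
  pad <- rep(30L, length(hits) + 10)
  d <- make_depth(c(raw, pad), step = step)
  flagged <- flag_windows(normalize_depth(d))
  calls <- merge_calls(chain_calls(flagged, min_hits = min_hits, span = span,
                                   window_size = window_size),
                       gap_frac = gap_frac)
  calls <- calls[calls$kind == "DEL" & calls$start < step * length(hits), ]
  calls[, c("start", "end")]
}

# --- exhaustive pairwise pi oracle ------------------------------------------
# mean pairwise difference over all haplotype pairs, per site, summed and
# divided by the window length; haplotypes are enumerated from dosages
oracle_pi <- function(gt_window, window_len) {
  total <- 0
  for (s in seq_len(nrow(gt_window))) {
    g <- gt_window[s, ]
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    hap <- unlist(lapply(g, function(x) switch(as.character(x),
                                               "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))))
    if (length(hap) < 2) next
    pairs <- utils::combn(length(hap), 2)
    diffs <- sum(hap[pairs[1, ]] != hap[pairs[2, ]])
    total <- total + diffs / ncol(pairs)
  }
  total / window_len
}

# quantile-free top-k sort oracle: the ceil(0.01 * N) largest values
oracle_top_k <- function(v, q = 0.99) {
  k <- ceiling((1 - q) * length(v))
  sort(v, decreasing = TRUE)[seq_len(k)]
}
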