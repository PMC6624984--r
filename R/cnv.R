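# Read-depth CNV calling. Depth is summarised in 1000-bp windows on a 500-bp
# step; windows with normalized depth < 0.25 / > 1.75 are deletion /
# duplication evidence; evidence is chained with the five-of-seven rule,
# nearby calls are merged when their gap is under 20% of the combined
# length, and cross-accession regions use > 50% reciprocal overlap with the
# largest call as representative.

#' Normalize a read-depth track
#'
#' Divides each accession's raw window depth by that accession's median raw
#' depth over all its windows, so a diploid background sits at 1. Tracks
#' should comfortably exceed ~100 windows for the median to be a stable
#' baseline.
#'
#' @param depth Depth tibble (`accession`, `chrom`, `window_start`,
#'   `raw_depth`).
#' @return The tibble with a `norm_depth` column added.
#' @export
normalize_depth <- function(depth) {
  depth |>
    group_by(.data$accession) |>
    mutate(.med = median(.data$raw_depth)) |>
    ungroup() -> x
  if (any(x$.med == 0)) {
    bad <- unique(x$accession[x$.med == 0])
    abort(paste0("uncallable accession(s) with zero median depth: ", toString(bad)))
  }
  x |> mutate(norm_depth = .data$raw_depth / .data$.med) |> select(-".med")
}

#' Flag deletion / duplication windows
#'
#' A window is deletion evidence iff its normalized depth is strictly below
#' `del_thresh` and duplication evidence iff strictly above `dup_thresh`;
#' the flags are mutually exclusive by construction.
#'
#' @param depth Normalized depth tibble (see [normalize_depth()]).
#' @param del_thresh,dup_thresh Strict thresholds (defaults 0.25 and 1.75).
#' @return The tibble with a `flag` column (`"DEL"`, `"DUP"` or `NA`).
#' @export
flag_windows <- function(depth, del_thresh = 0.25, dup_thresh = 1.75) {
  if (!"norm_depth" %in% names(depth)) abort("depth must be normalized first")
  if (del_thresh >= dup_thresh) abort("del_thresh must be below dup_thresh")
  depth |>
    mutate(flag = dplyr::case_when(
      .data$norm_depth < del_thresh ~ "DEL",
      .data$norm_depth > dup_thresh ~ "DUP",
      TRUE ~ NA_character_
    ))
}

# rolling-any of `ok` over the trailing `span` positions, vectorized
seeded_from_spans <- function(hit, min_hits, span) {
  n <- length(hit)
  if (n < span) return(rep(FALSE, n))
  cs <- c(0, cumsum(hit))
  ok <- (cs[(span + 1):(n + 1)] - cs[1:(n - span + 1)]) >= min_hits  # span starts
  cok <- c(0, cumsum(ok))
  j <- seq_len(n)
  hi <- pmin(j, n - span + 1L)
  lo <- pmax(0L, j - span)
  valid <- hi >= 1L & hi > lo
  out <- rep(FALSE, n)
  out[valid] <- (cok[hi[valid] + 1L] - cok[lo[valid] + 1L]) > 0
  out
}

chain_one <- function(window_start, norm_depth, hit, min_hits, span, window_size) {
  seeded <- seeded_from_spans(hit, min_hits, span)
  if (!any(seeded)) return(NULL)
  r <- rle(seeded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    fl <- idx[hit[idx]]
    if (length(fl) == 0) next
    a <- min(fl); b <- max(fl)
    out[[length(out) + 1]] <- tibble(
      start = window_start[a], end = window_start[b] + window_size,
      n_windows = b - a + 1L, mean_norm_depth = mean(norm_depth[a:b])
    )
  }
  bind_rows(out)
}

#' Chain flagged windows into CNV calls
#'
#' A window is seeded iff it lies in at least one run of `span` consecutive
#' windows containing at least `min_hits` same-kind flags ("five of seven").
#' Each maximal run of seeded windows, trimmed to its outermost flagged
#' windows, becomes one call; the call interval is the genomic union of the
#' trimmed windows (each window covers `window_size` bp from its start).
#'
#' @param flagged Flagged depth tibble (see [flag_windows()]); windows must
#'   form a regular grid per accession/chromosome.
#' @param min_hits Minimum flags within a span (default 5).
#' @param span Span of consecutive windows examined (default 7).
#' @param window_size Window size in bp (default 1000).
#' @return Call tibble: `accession`, `chrom`, `start`, `end`, `kind`,
#'   `n_windows`, `mean_norm_depth`.
#' @export
chain_calls <- function(flagged, min_hits = 5L, span = 7L, window_size = 1000L) {
  if (span < min_hits) abort("span must be >= min_hits")
  if (!"flag" %in% names(flagged)) abort("run flag_windows() first")
  flagged |>
    group_by(.data$accession, .data$chrom) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(g$window_start), ]
      bind_rows(lapply(c("DEL", "DUP"), function(kind) {
        res <- chain_one(g$window_start, g$norm_depth, !is.na(g$flag) & g$flag == kind,
                         min_hits, span, window_size)
        if (is.null(res) || nrow(res) == 0) return(NULL)
        mutate(res, kind = kind)
      }))
    }) |>
    ungroup() -> out
  cols <- c("accession", "chrom", "start", "end", "kind", "n_windows", "mean_norm_depth")
  if (nrow(out) == 0) {
    return(tibble(accession = character(), chrom = character(), start = double(),
                  end = double(), kind = character(), n_windows = integer(),
                  mean_norm_depth = double()))
  }
  out |>
    select(dplyr::all_of(cols)) |>
    arrange(.data$accession, .data$chrom, .data$kind, .data$start)
}

merge_pass <- function(d, gap_frac) {
  i <- 1L
  repeat {
    if (i >= nrow(d)) return(d)
    gap <- d$start[i + 1] - d$end[i]
    if (gap < gap_frac * ((d$end[i] - d$start[i]) + (d$end[i + 1] - d$start[i + 1]))) {
      d$mean_norm_depth[i] <- stats::weighted.mean(
        c(d$mean_norm_depth[i], d$mean_norm_depth[i + 1]),
        c(d$n_windows[i], d$n_windows[i + 1]))
      d$end[i] <- max(d$end[i], d$end[i + 1])
      d$n_windows[i] <- d$n_windows[i] + d$n_windows[i + 1]
      d <- d[-(i + 1), ]
      # stay on i: the grown call may now absorb its next neighbour
    } else {
      i <- i + 1L
    }
  }
}

#' Merge nearby CNV calls
#'
#' Two adjacent same-kind calls of one accession are merged when the gap
#' between them is strictly less than `gap_frac` times their combined
#' length; merging proceeds left to right and re-evaluates after every merge
#' until a fixed point (so a merge can enable the next one).
#'
#' @param calls Call tibble from [chain_calls()].
#' @param gap_frac Gap threshold as a fraction of combined length
#'   (default 0.2).
#' @return Merged call tibble, same columns.
#' @export
merge_calls <- function(calls, gap_frac = 0.2) {
  if (nrow(calls) == 0) return(calls)
  calls |>
    group_by(.data$accession, .data$chrom, .data$kind) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(g$start), ]
      repeat {
        g2 <- merge_pass(g, gap_frac)
        if (nrow(g2) == nrow(g)) return(g2)
        g <- g2
      }
    }) |>
    ungroup() |>
    select(dplyr::all_of(names(calls))) |>
    arrange(.data$accession, .data$chrom, .data$kind, .data$start)
}

#' Build cross-accession CNV regions
#'
#' Calls overlapping any excluded interval (e.g. known introgressions) are
#' dropped. Two calls of the same kind overlap when their shared length
#' strictly exceeds `reciprocal` of BOTH lengths; single-linkage components
#' of that relation form one region, represented by its largest member call
#' (ties broken by smaller start). Per-population carrier frequencies are
#' attached when a panel is given.
#'
#' @param calls Merged call tibble.
#' @param panel Optional population panel for carrier frequencies.
#' @param reciprocal Reciprocal-overlap fraction (default 0.5, strict).
#' @param exclude Optional interval tibble (`chrom`, `start`, `end`) of
#'   regions whose calls are removed before merging.
#' @return Region tibble: `cnvr_id`, `chrom`, `start`, `end`, `kind`,
#'   `n_calls`, `carriers` (list-column), and a `freq` list-column of named
#'   per-population carrier fractions when `panel` is supplied.
#' @export
build_cnvr <- function(calls, panel = NULL, reciprocal = 0.5, exclude = NULL) {
  x <- calls
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(x) > 0) {
    drop <- vapply(seq_len(nrow(x)), function(i) {
      e <- exclude[exclude$chrom == x$chrom[i], , drop = FALSE]
      any(overlap_len(x$start[i], x$end[i], e$start, e$end) > 0)
    }, logical(1))
    x <- x[!drop, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    return(tibble(cnvr_id = character(), chrom = character(), start = double(),
                  end = double(), kind = character(), n_calls = integer(),
                  carriers = list()))
  }
  regions <- x |>
    group_by(.data$chrom, .data$kind) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(g$start, g$end), ]
      n <- nrow(g)
      parent <- uf_new(n)
      for (i in seq_len(n)) {
        j <- i + 1L
        while (j <= n && g$start[j] < g$end[i]) {
          if (reciprocal_overlap(g$start[i], g$end[i], g$start[j], g$end[j], reciprocal)) {
            parent <- uf_union(parent, i, j)
          }
          j <- j + 1L
        }
      }
      comp <- uf_components(parent)
      bind_rows(lapply(split(seq_len(n), comp), function(idx) {
        len <- g$end[idx] - g$start[idx]
        cand <- idx[len == max(len)]
        best <- cand[which.min(g$start[cand])]
        tibble(start = g$start[best], end = g$end[best],
               n_calls = length(idx),
               carriers = list(sort(unique(g$accession[idx]))))
      }))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start, .data$kind) |>
    mutate(cnvr_id = sprintf("cnvr_%04d", row_number())) |>
    select("cnvr_id", "chrom", "start", "end", "kind", "n_calls", "carriers")
  if (!is.null(panel)) {
    pops <- unique(panel$population)
    regions$freq <- lapply(regions$carriers, function(cs) {
      vapply(pops, function(p) {
        members <- panel$accession[panel$population == p]
        if (length(members) == 0) return(NA_real_)
        mean(members %in% cs)
      }, double(1))
    })
  }
  regions
}

carrier_freq <- function(carriers, panel, pops) {
  members <- panel_members(panel, pops)
  if (length(members) == 0) {
    abort(paste0("no accessions in population(s): ", toString(pops)))
  }
  mean(members %in% carriers)
}

#' Relative frequency difference (RFD) of CNV regions
#'
#' For each region, the carrier frequency is computed in two population
#' groups and the RFD is their absolute difference, `|f_a - f_b|`, giving a
#' statistic in `[0, 1]` whose extremes flag copy-number variants under
#' differential selection.
#'
#' @param cnvr Region tibble from [build_cnvr()].
#' @param panel Population panel.
#' @param pop_a,pop_b Character vectors of population labels forming the two
#'   compared groups (e.g. landraces vs varieties).
#' @return Tibble: `cnvr_id`, `chrom`, `start`, `end`, `kind`, `f_a`, `f_b`,
#'   `rfd`.
#' @export
rfd <- function(cnvr, panel, pop_a, pop_b) {
  if (nrow(cnvr) == 0) abort("no CNV regions supplied")
  f_a <- vapply(cnvr$carriers, carrier_freq, double(1), panel = panel, pops = pop_a)
  f_b <- vapply(cnvr$carriers, carrier_freq, double(1), panel = panel, pops = pop_b)
  tibble(cnvr_id = cnvr$cnvr_id, chrom = cnvr$chrom, start = cnvr$start,
         end = cnvr$end, kind = cnvr$kind,
         f_a = f_a, f_b = f_b, rfd = abs(f_a - f_b))
}

#' Threshold RFD values at an empirical top quantile
#'
#' The threshold is the empirical `q` quantile (linear interpolation) of the
#' RFD values; regions strictly above it are selected, so the highest 1%
#' (default) flag candidate selected CNVs.
#'
#' @param rfd_tbl Tibble from [rfd()].
#' @param q Quantile (default 0.99).
#' @return An `rfd_scan` object; see [tidy.rfd_scan()].
#' @export
rfd_threshold <- function(rfd_tbl, q = 0.99) {
  thr <- unname(quantile(rfd_tbl$rfd, q, na.rm = TRUE, type = 7))
  records <- mutate(rfd_tbl, selected = .data$rfd > thr)
  structure(list(records = records, threshold = thr, q = q), class = "rfd_scan")
}

#' @export
print.rfd_scan <- function(x, ...) {
  cat(sprintf("<rfd_scan> %d regions, q = %.2f, threshold = %.4f, %d selected\n",
              nrow(x$records), x$q, x$threshold, sum(x$records$selected)))
  invisible(x)
}

#' Tidy an RFD scan
#' @param x An `rfd_scan` object.
#' @param ... Unused.
#' @return Per-region tibble with the `selected` flag.
#' @method tidy rfd_scan
#' @export
tidy.rfd_scan <- function(x, ...) x$records

#' @rdname tidy.rfd_scan
#' @return `glance()`: one-row summary (n, threshold, n selected).
#' @method glance rfd_scan
#' @export
glance.rfd_scan <- function(x, ...) {
  tibble(n_regions = nrow(x$records), q = x$q, threshold = x$threshold,
         n_selected = sum(x$records$selected))
}
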