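# Alien-introgression detection. An introgressed segment fails to map to
# the reference (so it surfaces as a large deleted CNV) while the reads that
# do map carry an excess of divergent sites. Both signals are required: a
# deleted CNV of >= 500 kb is called introgressed when more than half of its
# non-overlapping 50-kb windows are one-sided Z-test outliers of the
# per-accession divergent-site ratio.

#' One-sided standard-normal critical value
#'
#' @param alpha Significance level (default 0.05, giving 1.644853627...).
#' @return The critical value `qnorm(1 - alpha)`.
#' @export
z_crit_value <- function(alpha = 0.05) qnorm(1 - alpha)

#' Per-window divergent-site ratios
#'
#' Ratio = divergent sites / covered length per non-overlapping 50-kb
#' window; windows with zero covered length get a missing ratio and are
#' excluded from the Z statistics.
#'
#' @param track Divergence tibble (`accession`, `chrom`, `window_start`,
#'   `divergent_count`, `covered_bp`).
#' @param window Window size in bp (default 50 kb); recorded for interval
#'   arithmetic downstream.
#' @return Tibble with `window_end` and `ratio` columns added.
#' @export
divergent_windows <- function(track, window = 50000L) {
  if (any(track$divergent_count < 0) || any(track$covered_bp < 0)) {
    abort("divergent_count and covered_bp must be non-negative")
  }
  if (any(track$divergent_count > track$covered_bp)) {
    abort("divergent_count cannot exceed covered_bp")
  }
  track |>
    mutate(window_end = .data$window_start + window,
           ratio = ifelse(.data$covered_bp > 0,
                          .data$divergent_count / .data$covered_bp, NA_real_))
}

#' Z-score and flag candidate introgressed windows
#'
#' For each accession, ratios are standardized against that accession's own
#' genome-wide mean and sample standard deviation (n-1) over all non-missing
#' windows; a window is a candidate when its Z score strictly exceeds
#' `z_crit` (one-sided alpha = 0.05 by default).
#'
#' @param windows Tibble from [divergent_windows()].
#' @param z_crit Critical value (default [z_crit_value()] at alpha 0.05).
#' @param min_windows Minimum non-missing windows per accession (default 100).
#' @return The tibble with `z` and `candidate` columns.
#' @export
z_flag <- function(windows, z_crit = z_crit_value(0.05), min_windows = 100L) {
  windows |>
    group_by(.data$accession) |>
    dplyr::group_modify(function(g, key) {
      ok <- !is.na(g$ratio)
      if (sum(ok) < min_windows) {
        abort(sprintf("accession %s has %d non-missing windows; need >= %d",
                      key$accession, sum(ok), min_windows))
      }
      m <- mean(g$ratio[ok]); s <- sd(g$ratio[ok])
      if (s == 0) {
        warn(paste0("accession ", key$accession,
                    ": zero variance in divergent-site ratios; no candidates"))
        g$z <- ifelse(ok, 0, NA_real_)
        g$candidate <- ifelse(ok, FALSE, NA)
        return(g)
      }
      g$z <- (g$ratio - m) / s
      g$candidate <- !is.na(g$z) & g$z > z_crit
      g
    }) |>
    ungroup()
}

#' Call introgression segments from deleted CNVs and flagged windows
#'
#' Deleted CNVs shorter than `min_len` are skipped. A 50-kb window belongs
#' to a CNV when its midpoint lies inside the CNV interval; the CNV becomes
#' an introgression segment when the fraction of its windows flagged as
#' candidates strictly exceeds `min_frac` ("more than half").
#'
#' @param del_calls Deletion call tibble (`accession`, `chrom`, `start`,
#'   `end`); duplications must not be passed.
#' @param flagged Flagged window tibble from [z_flag()].
#' @param min_len Minimum CNV length in bp (default 500 kb, i.e. >= 10
#'   windows).
#' @param min_frac Candidate-fraction threshold (default 0.5, strict `>`).
#' @return Segment tibble: `accession`, `chrom`, `start`, `end`,
#'   `n_windows`, `n_candidate`, `fraction`.
#' @export
call_introgressions <- function(del_calls, flagged, min_len = 500000L,
                                min_frac = 0.5) {
  if (any(del_calls$kind != "DEL", na.rm = TRUE)) {
    abort("only deleted CNVs seed introgression calls; filter kind == 'DEL'")
  }
  big <- del_calls[del_calls$end - del_calls$start >= min_len, , drop = FALSE]
  if (nrow(big) == 0) {
    return(tibble(accession = character(), chrom = character(), start = double(),
                  end = double(), n_windows = integer(), n_candidate = integer(),
                  fraction = double()))
  }
  out <- lapply(seq_len(nrow(big)), function(i) {
    fw <- flagged[flagged$accession == big$accession[i] &
                    flagged$chrom == big$chrom[i], , drop = FALSE]
    mid <- (fw$window_start + fw$window_end) / 2
    inside <- mid >= big$start[i] & mid < big$end[i] & !is.na(fw$candidate)
    nw <- sum(inside)
    nc <- sum(fw$candidate[inside])
    tibble(accession = big$accession[i], chrom = big$chrom[i],
           start = big$start[i], end = big$end[i],
           n_windows = nw, n_candidate = nc,
           fraction = ifelse(nw > 0, nc / nw, NA_real_))
  })
  bind_rows(out) |>
    filter(!is.na(.data$fraction) & .data$fraction > min_frac) |>
    arrange(.data$accession, .data$chrom, .data$start)
}

#' Summarise introgression content per population
#'
#' Per accession and per population, the union length (bp) of carried
#' segments; between every pair of populations, the length shared, where
#' "shared" means a pair of population-union intervals with at least
#' `reciprocal` reciprocal overlap (the shared length is their
#' intersection).
#'
#' @param segments Segment tibble from [call_introgressions()].
#' @param panel Population panel.
#' @param reciprocal Reciprocal-overlap fraction for sharing (default 0.5,
#'   `>=`).
#' @return List of tibbles: `per_accession`, `per_population` (with a
#'   subgenome breakdown inferred from wheat-style chromosome names), and
#'   `shared` (population pairs).
#' @export
population_summary <- function(segments, panel, reciprocal = 0.5) {
  per_acc <- segments |>
    group_by(.data$accession, .data$chrom) |>
    dplyr::group_modify(function(g, key) {
      u <- reduce_intervals(g$start, g$end)
      tibble(length_bp = sum(u$end - u$start), n_segments = nrow(u))
    }) |>
    ungroup() |>
    group_by(.data$accession) |>
    summarise(length_bp = sum(.data$length_bp),
              n_segments = sum(.data$n_segments), .groups = "drop") |>
    left_join(panel, by = "accession")

  pop_union <- function(pop) {
    seg <- segments[segments$accession %in% panel_members(panel, pop), , drop = FALSE]
    seg |>
      group_by(.data$chrom) |>
      dplyr::group_modify(function(g, key) reduce_intervals(g$start, g$end)) |>
      ungroup()
  }
  all_pops <- unique(panel$population)
  per_pop <- bind_rows(lapply(all_pops, function(p) {
    u <- pop_union(p)
    if (nrow(u) == 0) {
      return(tibble(population = p, subgenome = NA_character_, length_bp = 0))
    }
    u |>
      mutate(subgenome = subgenome_of(.data$chrom)) |>
      group_by(.data$subgenome) |>
      summarise(length_bp = sum(.data$end - .data$start), .groups = "drop") |>
      mutate(population = p) |>
      select("population", "subgenome", "length_bp")
  }))
  shared <- bind_rows(apply(utils::combn(all_pops, 2), 2, function(pair) {
    ua <- pop_union(pair[1]); ub <- pop_union(pair[2])
    shared_bp <- 0
    for (ch in intersect(ua$chrom, ub$chrom)) {
      a <- ua[ua$chrom == ch, ]; b <- ub[ub$chrom == ch, ]
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (reciprocal_overlap(a$start[i], a$end[i], b$start[j], b$end[j],
                               reciprocal, strict = FALSE)) {
          shared_bp <- shared_bp + overlap_len(a$start[i], a$end[i],
                                               b$start[j], b$end[j])
        }
      }
    }
    tibble(pop_a = pair[1], pop_b = pair[2], shared_bp = shared_bp)
  }, simplify = FALSE))
  list(per_accession = per_acc, per_population = per_pop, shared = shared)
}

#' Co-localize introgression segments with QTL intervals
#'
#' QTL point anchors are first expanded symmetrically by `extend` bp
#' (clamped at chromosome ends when lengths are given); every
#' positive-length intersection between a segment and a QTL interval is
#' reported with its overlap length and trait.
#'
#' @param segments Segment tibble.
#' @param qtls QTL tibble from [read_qtl()] (columns `chrom`, `start`,
#'   `end`, `trait`, optional `is_point`).
#' @param chrom_lengths Optional named chromosome lengths for clamping.
#' @param extend Extension in bp for point anchors (default 2 Mb).
#' @return Overlap tibble: segment columns, `trait`, QTL interval,
#'   `overlap_bp`.
#' @export
qtl_colocalize <- function(segments, qtls, chrom_lengths = NULL, extend = 2e6) {
  q <- qtls
  pt <- if ("is_point" %in% names(q)) q$is_point else q$end == q$start
  q$start[pt] <- pmax(0, q$start[pt] - extend)
  q$end[pt] <- q$end[pt] + extend
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[q$chrom]
    q$end <- pmin(q$end, ifelse(is.na(lim), q$end, lim))
  }
  out <- list()
  for (i in seq_len(nrow(segments))) {
    hit <- q$chrom == segments$chrom[i] &
      overlap_len(segments$start[i], segments$end[i], q$start, q$end) > 0
    if (!any(hit)) next
    h <- q[hit, , drop = FALSE]
    out[[length(out) + 1]] <- tibble(
      accession = segments$accession[i], chrom = segments$chrom[i],
      seg_start = segments$start[i], seg_end = segments$end[i],
      trait = h$trait, qtl_start = h$start, qtl_end = h$end,
      overlap_bp = overlap_len(segments$start[i], segments$end[i], h$start, h$end)
    )
  }
  if (length(out) == 0) {
    return(tibble(accession = character(), chrom = character(),
                  seg_start = double(), seg_end = double(), trait = character(),
                  qtl_start = double(), qtl_end = double(), overlap_bp = double()))
  }
  bind_rows(out)
}

#' Rank candidate donor panels by divergence and assign an origin
#'
#' Donors are ranked by ascending mean dxy of the introgressed accession to
#' each candidate donor panel over the segment; the best donor is assigned
#' only when its dxy undercuts the runner-up by a relative `margin`
#' (default 20%), otherwise the segment stays unassigned — most real
#' introgressions cannot be traced to a reliable origin.
#'
#' @param dxy_by_donor Named numeric vector (or 2-column tibble
#'   `donor`/`dxy`) of mean dxy per candidate donor panel.
#' @param margin Relative margin the best donor must win by (default 0.2).
#' @return List: `ranking` (tibble, ascending dxy) and `assignment` (donor
#'   name or `"unassigned"`).
#' @export
donor_rank <- function(dxy_by_donor, margin = 0.2) {
  if (is.data.frame(dxy_by_donor)) {
    d <- setNames(dxy_by_donor$dxy, dxy_by_donor$donor)
  } else d <- dxy_by_donor
  if (length(d) < 2) abort("need at least 2 candidate donor panels")
  o <- order(d)
  ranking <- tibble(donor = names(d)[o], dxy = unname(d[o]), rank = seq_along(d))
  best <- ranking$dxy[1]; second <- ranking$dxy[2]
  assignment <- if (best < (1 - margin) * second) ranking$donor[1] else "unassigned"
  list(ranking = ranking, assignment = assignment)
}
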