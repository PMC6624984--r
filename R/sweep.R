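# ln pi-ratio selection scan. Windows with a diversity ratio in the top 1%
# (empirical quantile, strict exceedance) are selective candidates; selected
# windows closer than 200 kb merge into sweep regions. Thresholds are always
# recomputed from the data at hand — published genome-wide values are
# realized quantiles of a particular panel, not constants.

#' Per-window ln diversity ratio
#'
#' Adds `ln_ratio = ln(pi_num / pi_den)` to a window-statistics table.
#' Windows where either pi is missing, or the denominator is 0, are set to
#' missing; the number of such exclusions is attached as attribute
#' `n_excluded`.
#'
#' @param stats Window tibble carrying `pi_<pop>` columns (see
#'   [window_stats()]).
#' @param num_pop,den_pop Population labels naming the pi columns; the scan
#'   convention is progenitor diversity over derived-population diversity,
#'   so sweeps in the derived population give large positive values.
#' @return `stats` with an `ln_ratio` column.
#' @export
ln_pi_ratio <- function(stats, num_pop, den_pop) {
  num <- stats[[paste0("pi_", num_pop)]]
  den <- stats[[paste0("pi_", den_pop)]]
  if (is.null(num) || is.null(den)) {
    abort(paste0("stats must carry columns pi_", num_pop, " and pi_", den_pop))
  }
  bad <- is.na(num) | is.na(den) | den == 0
  out <- mutate(stats, ln_ratio = ifelse(bad, NA_real_, log(num / den)))
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Select windows above an empirical top quantile
#'
#' The threshold is the empirical `q` quantile with linear interpolation
#' (type 7) over non-missing values; selected windows are those strictly
#' above it, so ties at the threshold are excluded and the selection is
#' reproducible.
#'
#' @param stats Window tibble with the value column.
#' @param value_col Column to threshold (default `"ln_ratio"`).
#' @param q Quantile (default 0.99 — the top 1%).
#' @param min_values Minimum non-missing values required (default 100).
#' @return List: `threshold` and `selected` (the selected window rows).
#' @export
select_top <- function(stats, value_col = "ln_ratio", q = 0.99, min_values = 100L) {
  v <- stats[[value_col]]
  if (is.null(v)) abort(paste0("no column '", value_col, "' in stats"))
  ok <- !is.na(v)
  if (sum(ok) < min_values) {
    abort(sprintf("need at least %d non-missing values, got %d", min_values, sum(ok)))
  }
  thr <- unname(quantile(v[ok], q, type = 7))
  list(threshold = thr, selected = stats[ok & v > thr, , drop = FALSE])
}

#' Merge selected windows into sweep regions
#'
#' Consecutive selected windows on one chromosome whose gap is strictly
#' below `max_gap` join one region spanning from the first window start to
#' the last window end.
#'
#' @param selected Selected window rows (sorted or not).
#' @param max_gap Maximum gap in bp (default 200 kb, strict `<`).
#' @return Region tibble: `chrom`, `start`, `end`, `n_windows`,
#'   `max_value`.
#' @param value_col Column the per-region maximum is taken over.
#' @export
merge_sweeps <- function(selected, max_gap = 200000L, value_col = "ln_ratio") {
  if (nrow(selected) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  n_windows = integer(), max_value = double()))
  }
  selected |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(.grp = cumsum(c(TRUE, (.data$start[-1] - .data$end[-n()]) >= max_gap))) |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = n(),
              max_value = max(.data[[value_col]]), .groups = "drop") |>
    select(-".grp") |>
    arrange(.data$chrom, .data$start)
}

#' Run a full ln pi-ratio sweep scan
#'
#' Computes `ln(pi_num/pi_den)` per window, thresholds at the empirical top
#' quantile, and merges selected windows into sweep regions.
#'
#' @inheritParams ln_pi_ratio
#' @inheritParams select_top
#' @inheritParams merge_sweeps
#' @return A `sweep_scan` object with `windows`, `threshold`, `regions` and
#'   the comparison label; see [tidy.sweep_scan()] and
#'   [autoplot.sweep_scan()].
#' @export
sweep_scan <- function(stats, num_pop, den_pop, q = 0.99, max_gap = 200000L,
                       min_values = 100L) {
  w <- ln_pi_ratio(stats, num_pop, den_pop)
  sel <- select_top(w, "ln_ratio", q = q, min_values = min_values)
  regions <- merge_sweeps(sel$selected, max_gap = max_gap)
  structure(list(windows = w, threshold = sel$threshold, regions = regions,
                 comparison = paste0(num_pop, "/", den_pop), q = q,
                 max_gap = max_gap, n_excluded = attr(w, "n_excluded")),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("<sweep_scan> %s: %d windows, q = %.2f, threshold = %.3f, %d region(s)\n",
              x$comparison, sum(!is.na(x$windows$ln_ratio)), x$q, x$threshold,
              nrow(x$regions)))
  invisible(x)
}

#' Tidy / summarise a sweep scan
#' @param x A `sweep_scan` object.
#' @param ... Unused.
#' @return `tidy()`: the merged sweep-region tibble with the comparison
#'   label; `glance()`: one-row scan summary.
#' @method tidy sweep_scan
#' @export
tidy.sweep_scan <- function(x, ...) {
  mutate(x$regions, comparison = x$comparison)
}

#' @rdname tidy.sweep_scan
#' @method glance sweep_scan
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble(comparison = x$comparison,
         n_windows = sum(!is.na(x$windows$ln_ratio)),
         n_excluded = x$n_excluded %||% NA_integer_,
         q = x$q, threshold = x$threshold,
         n_selected = sum(x$windows$ln_ratio > x$threshold, na.rm = TRUE),
         n_regions = nrow(x$regions))
}

#' Plot a sweep scan
#'
#' ln pi-ratio against window midpoint, faceted by chromosome, with the
#' empirical threshold as a horizontal line and merged sweep regions shaded.
#'
#' @param object A `sweep_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_scan
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- dplyr::filter(object$windows, !is.na(.data$ln_ratio))
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                       y = .data$ln_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = bquote("ln" ~ pi ~ "ratio (" * .(object$comparison) * ")"),
                  title = "Selective-sweep scan") +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE)
  }
  p
}
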