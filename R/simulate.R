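# Synthetic multi-population data generator.
#
# Genotypes follow the Balding-Nichols model: an ancestral allele frequency p
# is drawn per site, and each population's frequency is drawn from
# Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p(1-p) --
# i.e. populations differentiate around the ancestral frequency with
# expected Fst equal to F. Read depth is Poisson per sliding window with the
# window copy number scaling the rate; divergent-site counts are binomial on
# the covered length. Planted events perturb exactly the signal each
# downstream detector consumes: DEL/DUP change window copy number,
# INTROGRESSION collapses mapping coverage and inflates the divergent-site
# rate, SWEEP pushes one population's frequencies toward fixation so that
# expected heterozygosity shrinks by a chosen factor.

#' Describe one planted event
#'
#' @param kind One of `"DEL"`, `"DUP"`, `"INTROGRESSION"`, `"SWEEP"`.
#' @param chrom Chromosome name.
#' @param start,end Event interval in bp, 0-based half-open.
#' @param carriers Accession ids carrying the event (DEL/DUP/INTROGRESSION).
#' @param copy_number Integer copy number for DEL (0 or 1) / DUP (3 or 4).
#' @param divergence_fold Multiplier on the background divergent-site rate
#'   inside an INTROGRESSION event; must be > 1.
#' @param pi_reduction Factor by which expected heterozygosity is reduced
#'   inside a SWEEP event; must be > 1.
#' @param target_pop Population whose diversity is reduced (SWEEP only).
#' @return One-row tibble; rows from several calls can be `bind_rows()`-ed.
#' @export
planted_event <- function(kind, chrom, start, end, carriers = character(),
                          copy_number = NA_integer_, divergence_fold = NA_real_,
                          pi_reduction = NA_real_, target_pop = NA_character_) {
  kind <- match.arg(kind, c("DEL", "DUP", "INTROGRESSION", "SWEEP"))
  if (!(start < end) || start < 0) abort("event must satisfy 0 <= start < end")
  if (kind %in% c("DEL", "DUP", "INTROGRESSION") && length(carriers) == 0) {
    abort(paste0(kind, " event needs at least one carrier"))
  }
  if (kind == "DEL" && !copy_number %in% c(0L, 1L)) abort("DEL copy_number must be 0 or 1")
  if (kind == "DUP" && !copy_number %in% c(3L, 4L)) abort("DUP copy_number must be 3 or 4")
  if (kind == "INTROGRESSION" && !(is.finite(divergence_fold) && divergence_fold > 1)) {
    abort("INTROGRESSION needs divergence_fold > 1")
  }
  if (kind == "SWEEP") {
    if (!(is.finite(pi_reduction) && pi_reduction > 1)) abort("SWEEP needs pi_reduction > 1")
    if (is.na(target_pop)) abort("SWEEP needs target_pop")
  }
  tibble(kind = kind, chrom = as.character(chrom),
         start = as.double(start), end = as.double(end),
         carriers = list(as.character(carriers)),
         copy_number = as.integer(copy_number),
         divergence_fold = as.double(divergence_fold),
         pi_reduction = as.double(pi_reduction),
         target_pop = as.character(target_pop))
}

empty_events <- function() {
  planted_event("DEL", "x", 0, 1, carriers = "a", copy_number = 0L)[0, ]
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The same config
#' (including `seed`) always produces byte-identical output.
#'
#' @param seed Integer seed; all three generators derive their streams from it.
#' @param chrom_lengths Named numeric vector, chromosome -> length in bp.
#'   Lengths must be positive multiples of `depth_step`.
#' @param n_per_pop Named integer vector, population label -> diploid count.
#' @param fst Per-population differentiation F in `[0, 1)`; a scalar is
#'   recycled over populations.
#' @param snp_density Expected SNPs per bp.
#' @param depth_lambda Expected reads per depth window at copy number 2.
#' @param background_divergence Per-bp divergent-site rate outside events.
#' @param events Tibble of [planted_event()] rows.
#' @param missing_rate Per-genotype missing probability.
#' @param coverage_frac Fraction of each 50-kb window covered by reads
#'   outside introgressions.
#' @param intro_coverage_frac Covered fraction inside introgressed segments
#'   (alien sequence mostly fails to map).
#' @param intro_copy Window copy number for introgression carriers inside the
#'   event (0 = complete mapping failure).
#' @param depth_window,depth_step Depth window size and step in bp.
#' @param div_window Divergence window size in bp (non-overlapping grid).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 10e6),
                       n_per_pop = c(popA = 10L, popB = 10L),
                       fst = 0.15,
                       snp_density = 1e-4,
                       depth_lambda = 30,
                       background_divergence = 1e-3,
                       events = empty_events(),
                       missing_rate = 0.02,
                       coverage_frac = 0.8,
                       intro_coverage_frac = 0.2,
                       intro_copy = 0L,
                       depth_window = 1000L,
                       depth_step = 500L,
                       div_window = 50000L) {
  if (length(fst) == 1) fst <- setNames(rep(fst, length(n_per_pop)), names(n_per_pop))
  if (any(fst < 0 | fst >= 1)) abort("fst must lie in [0, 1)")
  if (snp_density <= 0) abort("snp_density must be > 0")
  if (depth_lambda <= 0) abort("depth_lambda must be > 0")
  if (background_divergence <= 0) abort("background_divergence must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  if (any(chrom_lengths <= 0) || any(chrom_lengths %% depth_step != 0)) {
    abort("chrom_lengths must be positive multiples of depth_step")
  }
  if (is.null(names(chrom_lengths)) || is.null(names(n_per_pop))) {
    abort("chrom_lengths and n_per_pop must be named")
  }
  if (!setequal(names(fst), names(n_per_pop))) abort("fst must be named by population")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_per_pop = n_per_pop, fst = fst[names(n_per_pop)],
                 snp_density = snp_density, depth_lambda = depth_lambda,
                 background_divergence = background_divergence,
                 events = events, missing_rate = missing_rate,
                 coverage_frac = coverage_frac,
                 intro_coverage_frac = intro_coverage_frac,
                 intro_copy = as.integer(intro_copy),
                 depth_window = as.integer(depth_window),
                 depth_step = as.integer(depth_step),
                 div_window = as.integer(div_window)),
            class = "sim_config")
}

#' Accession panel implied by a simulation config
#'
#' Accession ids are deterministic (`<pop>_<index>`), so depth and divergence
#' tracks can be generated without first generating genotypes.
#'
#' @param config A [sim_config()].
#' @return Tibble with `accession` and `population`.
#' @export
config_panel <- function(config) {
  pops <- names(config$n_per_pop)
  tibble(
    accession = unlist(lapply(pops, function(p) {
      sprintf("%s_%02d", p, seq_len(config$n_per_pop[[p]]))
    }), use.names = FALSE),
    population = rep(pops, times = config$n_per_pop)
  )
}

events_of <- function(config, kinds) {
  ev <- config$events
  ev[ev$kind %in% kinds, , drop = FALSE]
}

# shrink heterozygosity 2p(1-p) by factor k, moving p toward its nearer
# boundary; solves p'(1-p') = p(1-p)/k
sweep_shift <- function(p, k) {
  disc <- pmax(0, 1 - 4 * p * (1 - p) / k)
  lo <- (1 - sqrt(disc)) / 2
  ifelse(p <= 0.5, lo, 1 - lo)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Sites are placed uniformly at the configured density; each population's
#' allele frequency is drawn around a Uniform(0.05, 0.95) ancestral frequency
#' with the configured F, and diploid genotypes are Binomial(2, p).
#' Inside SWEEP events the target population's frequencies are pushed toward
#' fixation so expected heterozygosity drops by `pi_reduction`. Missing
#' genotypes are injected at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return List with elements `geno` (a [geno_matrix()]), `panel`, and
#'   `freqs` — the generating per-population allele-frequency matrix
#'   (sites x populations, after any sweep adjustment), kept for
#'   benchmarking estimators against the truth.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config_panel(config)
  pops <- names(config$n_per_pop)
  sweeps <- events_of(config, "SWEEP")

  sites_list <- list()
  gt_list <- list()
  freq_list <- list()
  for (chrom in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chrom]]
    n <- round(config$snp_density * L)
    if (n == 0) next
    pos <- sort(sample.int(L, n)) - 1
    p_anc <- runif(n, 0.05, 0.95)
    gt <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
                 dimnames = list(NULL, panel$accession))
    fq <- matrix(NA_real_, nrow = n, ncol = length(pops),
                 dimnames = list(NULL, pops))
    for (pop in pops) {
      Fp <- config$fst[[pop]]
      p_pop <- if (Fp > 0) {
        rbeta(n, p_anc * (1 - Fp) / Fp, (1 - p_anc) * (1 - Fp) / Fp)
      } else p_anc
      sw <- sweeps[sweeps$target_pop == pop & sweeps$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(sw))) {
        inside <- pos >= sw$start[i] & pos < sw$end[i]
        p_pop[inside] <- sweep_shift(p_pop[inside], sw$pi_reduction[i])
      }
      fq[, pop] <- p_pop
      for (acc in panel$accession[panel$population == pop]) {
        gt[, acc] <- rbinom(n, 2L, p_pop)
      }
    }
    if (config$missing_rate > 0) {
      drop <- matrix(runif(length(gt)) < config$missing_rate, nrow = n)
      gt[drop] <- NA_integer_
    }
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    dp <- rpois(n, config$depth_lambda * nrow(panel))
    sites_list[[chrom]] <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                  dp = dp, multiallelic = FALSE)
    gt_list[[chrom]] <- gt
    freq_list[[chrom]] <- fq
  }
  sites <- bind_rows(sites_list)
  gt <- do.call(rbind, gt_list)
  list(geno = geno_matrix(sites, gt), panel = panel,
       freqs = do.call(rbind, freq_list))
}

#' Simulate per-accession window read-depth tracks
#'
#' Raw depth per sliding window is Poisson(lambda * c / 2) where the copy
#' number c is 2 outside events, the planted `copy_number` inside DEL/DUP
#' events for carriers, and `intro_copy` (default 0) inside INTROGRESSION
#' events for carriers — introgressed alien sequence largely fails to map to
#' the reference, mimicking a deletion. A window belongs to an event when its
#' midpoint lies inside the event interval.
#'
#' @param config A [sim_config()].
#' @return Tibble: `accession`, `chrom`, `window_start`, `raw_depth`.
#' @export
simulate_depth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  panel <- config_panel(config)
  w <- config$depth_window; s <- config$depth_step
  ev <- events_of(config, c("DEL", "DUP", "INTROGRESSION"))
  out <- vector("list", 0)
  for (acc in panel$accession) {
    for (chrom in names(config$chrom_lengths)) {
      L <- config$chrom_lengths[[chrom]]
      if (L < w) next
      starts <- seq(0, L - w, by = s)
      cn <- rep(2L, length(starts))
      mid <- starts + w / 2
      evi <- ev[ev$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(evi))) {
        if (!acc %in% evi$carriers[[i]]) next
        inside <- mid >= evi$start[i] & mid < evi$end[i]
        cn[inside] <- if (evi$kind[i] == "INTROGRESSION") config$intro_copy else evi$copy_number[i]
      }
      out[[length(out) + 1]] <- tibble(
        accession = acc, chrom = chrom, window_start = starts,
        raw_depth = rpois(length(starts), config$depth_lambda * cn / 2)
      )
    }
  }
  bind_rows(out)
}

#' Simulate per-accession divergent-site tracks
#'
#' On a non-overlapping 50-kb grid, the covered length is
#' `div_window * coverage_frac` outside events and
#' `div_window * intro_coverage_frac` inside introgressed segments for
#' carriers; the divergent-site count is Binomial(covered, r0) outside events
#' and Binomial(covered, min(1, fold * r0)) inside, where r0 is the
#' background per-bp divergent-site rate.
#'
#' @param config A [sim_config()].
#' @return Tibble: `accession`, `chrom`, `window_start`, `divergent_count`,
#'   `covered_bp`.
#' @export
simulate_divergent_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  panel <- config_panel(config)
  w <- config$div_window
  r0 <- config$background_divergence
  ev <- events_of(config, "INTROGRESSION")
  out <- vector("list", 0)
  for (acc in panel$accession) {
    for (chrom in names(config$chrom_lengths)) {
      L <- config$chrom_lengths[[chrom]]
      nw <- floor(L / w)
      if (nw == 0) next
      starts <- w * (0:(nw - 1))
      mid <- starts + w / 2
      covered <- rep(round(w * config$coverage_frac), nw)
      rate <- rep(r0, nw)
      evi <- ev[ev$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(evi))) {
        if (!acc %in% evi$carriers[[i]]) next
        inside <- mid >= evi$start[i] & mid < evi$end[i]
        covered[inside] <- round(w * config$intro_coverage_frac)
        f <- evi$divergence_fold[i] * r0
        if (f > 1) warn("divergence_fold * r0 exceeds 1; clamped to 1")
        rate[inside] <- min(1, f)
      }
      out[[length(out) + 1]] <- tibble(
        accession = acc, chrom = chrom, window_start = starts,
        divergent_count = rbinom(nw, covered, rate), covered_bp = covered
      )
    }
  }
  bind_rows(out)
}

#' Write / read the planted-event truth table
#'
#' BED-like TSV (chrom, start, end first; 0-based half-open) with one record
#' per planted event. `read_truth(write_truth(cfg, f))` reproduces the event
#' list exactly.
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly (`write_truth`); the events tibble (`read_truth`).
#' @export
write_truth <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  ev <- config$events
  out <- tibble(
    chrom = ev$chrom, start = ev$start, end = ev$end, kind = ev$kind,
    carriers = vapply(ev$carriers, paste, character(1), collapse = ","),
    copy_number = ev$copy_number, divergence_fold = ev$divergence_fold,
    pi_reduction = ev$pi_reduction, target_pop = ev$target_pop
  )
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = "c", start = "d", end = "d", kind = "c",
                         carriers = "c", copy_number = "i",
                         divergence_fold = "d", pi_reduction = "d",
                         target_pop = "c"))
  carriers_txt <- as.character(x$carriers)
  carriers_txt[is.na(carriers_txt)] <- ""
  tibble(kind = x$kind, chrom = x$chrom, start = x$start, end = x$end,
         carriers = lapply(strsplit(carriers_txt, ","), function(v) v[nzchar(v)]),
         copy_number = x$copy_number, divergence_fold = x$divergence_fold,
         pi_reduction = x$pi_reduction, target_pop = x$target_pop)
}
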