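#' Site-filtering rules
#'
#' Defaults reproduce the resequencing-panel site filters: total read depth
#' strictly between 240 and 2200, per-population minor allele frequency of at
#' least 0.05 (0.2 for the small Aegilops tauschii panel, via
#' `maf_overrides`), missing rate strictly below 0.1, and biallelic sites
#' only.
#'
#' @param dp_min,dp_max Total-depth bounds; a site survives iff
#'   `dp_min < DP < dp_max` (both strict).
#' @param maf_default Default per-population MAF threshold (site passes a
#'   population when its MAF is `>=` the threshold).
#' @param maf_overrides Named numeric vector of population-specific MAF
#'   thresholds, e.g. `c(AET = 0.2)`.
#' @param max_missing Missing-rate bound (strict `<`).
#' @param biallelic_only Drop multiallelic records.
#' @return A list of class `site_filter_rules`.
#' @export
site_filter_rules <- function(dp_min = 240, dp_max = 2200, maf_default = 0.05,
                              maf_overrides = c(AET = 0.2), max_missing = 0.1,
                              biallelic_only = TRUE) {
  if (!is.na(maf_default) && (maf_default <= 0 || maf_default > 0.5)) {
    abort("maf_default must lie in (0, 0.5]")
  }
  if (any(maf_overrides <= 0 | maf_overrides > 0.5)) abort("MAF thresholds must lie in (0, 0.5]")
  if (!(dp_min < dp_max)) abort("dp_min must be < dp_max")
  structure(list(dp_min = dp_min, dp_max = dp_max, maf_default = maf_default,
                 maf_overrides = maf_overrides, max_missing = max_missing,
                 biallelic_only = biallelic_only),
            class = "site_filter_rules")
}

maf_threshold_for <- function(rules, pop) {
  if (pop %in% names(rules$maf_overrides)) return(rules$maf_overrides[[pop]])
  if (is.na(rules$maf_default)) {
    abort(paste0("no MAF threshold resolvable for population '", pop,
                 "': set maf_default or add an override"))
  }
  rules$maf_default
}

#' Filter SNP sites
#'
#' Applies the rules in a fixed order — biallelic, depth, missing rate,
#' per-population MAF — so the per-rule removal counts are mutually exclusive
#' and reproducible. `maf_scope` controls how per-population MAF thresholds
#' combine: `"any"` keeps a site when at least one population meets its
#' threshold (the permissive reading, which preserves fixed inter-population
#' differences for downstream Fst work), `"all"` requires every population to
#' meet its own.
#'
#' @param geno A [geno_matrix()].
#' @param panel Population panel tibble.
#' @param rules A [site_filter_rules()].
#' @param maf_scope `"any"` (default) or `"all"`.
#' @return List: `geno` (filtered matrix) and `report`, a tibble of per-rule
#'   removal counts whose sum plus surviving sites equals the input sites.
#' @export
filter_sites <- function(geno, panel, rules = site_filter_rules(),
                         maf_scope = c("any", "all")) {
  maf_scope <- match.arg(maf_scope)
  stopifnot(inherits(geno, "geno_matrix"))
  pops <- unique(panel$population)
  thresholds <- vapply(pops, function(p) maf_threshold_for(rules, p), double(1))

  n0 <- nrow(geno$sites)
  alive <- rep(TRUE, n0)
  removed <- c(multiallelic = 0L, depth = 0L, missing = 0L, maf = 0L)

  if (rules$biallelic_only) {
    hit <- alive & geno$sites$multiallelic
    removed["multiallelic"] <- sum(hit)
    alive <- alive & !hit
  }
  dp_ok <- !is.na(geno$sites$dp) &
    geno$sites$dp > rules$dp_min & geno$sites$dp < rules$dp_max
  hit <- alive & !dp_ok
  removed["depth"] <- sum(hit)
  alive <- alive & !hit

  miss_rate <- rowMeans(is.na(geno$gt))
  hit <- alive & !(miss_rate < rules$max_missing)
  removed["missing"] <- sum(hit)
  alive <- alive & !hit

  pass_pop <- matrix(FALSE, nrow = n0, ncol = length(pops),
                     dimnames = list(NULL, pops))
  for (pop in pops) {
    st <- allele_stats(geno$gt, panel$accession[panel$population == pop])
    maf <- pmin(st$p, 1 - st$p)
    pass_pop[, pop] <- !is.na(maf) & maf >= thresholds[[pop]]
  }
  maf_ok <- if (maf_scope == "any") rowSums(pass_pop) > 0 else rowSums(pass_pop) == length(pops)
  hit <- alive & !maf_ok
  removed["maf"] <- sum(hit)
  alive <- alive & !hit

  list(
    geno = geno_subset(geno, alive),
    report = tibble(rule = c(names(removed), "surviving"),
                    n_sites = c(unname(removed), sum(alive)))
  )
}
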