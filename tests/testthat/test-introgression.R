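make_div <- function(counts, covered = 40000, accession = "a1", chrom = "chr1") {
  tibble::tibble(accession = accession, chrom = chrom,
                 window_start = 50000 * (seq_along(counts) - 1),
                 divergent_count = counts, covered_bp = rep_len(covered, length(counts)))
}

test_that("the one-sided critical value reproduces the canonical alpha = 0.05 constant", {
  expect_equal(z_crit_value(0.05), 1.644853627, tolerance = 1e-9)
  expect_equal(z_crit_value(0.025), qnorm(0.975))
})

test_that("divergent-site ratios handle zero coverage and reject invalid counts", {
  d <- make_div(c(40, 0, 0), covered = c(20000, 40000, 0))
  w <- divergent_windows(d)
  expect_equal(w$ratio[1], 0.002)
  expect_true(is.na(w$ratio[3]))
  expect_true(all(w$ratio <= 1, na.rm = TRUE))
  expect_error(divergent_windows(make_div(-1)), "non-negative")
  expect_error(divergent_windows(make_div(50000, covered = 10)), "exceed")
})

test_that("Z flagging standardizes per accession with sample sd and strict exceedance", {
  set.seed(3)
  counts <- rbinom(200, 40000, 0.001)
  d <- divergent_windows(make_div(counts))
  f <- z_flag(d)
  m <- mean(d$ratio); s <- sd(d$ratio)
  expect_equal(f$z, (d$ratio - m) / s)
  expect_equal(f$candidate, f$z > 1.644853627)
  expect_false(any(f$candidate[abs(f$z) < 1e-9]))   # ratio at the mean is never a candidate
  # constant ratios: zero variance, no candidates, warning
  expect_warning(f0 <- z_flag(divergent_windows(make_div(rep(40, 150)))), "zero variance")
  expect_false(any(f0$candidate))
  expect_error(z_flag(divergent_windows(make_div(rep(40, 10)))), "non-missing windows")
})

test_that("introgression calls need >= 500 kb and strictly more than half candidate windows", {
  flag_fix <- function(cand) {
    tibble::tibble(accession = "a1", chrom = "chr1",
                   window_start = 50000 * (seq_along(cand) - 1),
                   window_end = 50000 * seq_along(cand),
                   ratio = 0.001, z = 0, candidate = cand)
  }
  del <- function(start, end) {
    tibble::tibble(accession = "a1", chrom = "chr1", start = start, end = end,
                   kind = "DEL")
  }
  # 1-Mb CNV = 20 windows, 12 candidates -> fraction 0.6 -> called
  seg <- call_introgressions(del(0, 1e6), flag_fix(c(rep(TRUE, 12), rep(FALSE, 8))))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_windows, 20L)
  expect_equal(seg$fraction, 0.6)
  # 10 of 20: boundary, strict >
  expect_equal(nrow(call_introgressions(del(0, 1e6),
                                        flag_fix(c(rep(TRUE, 10), rep(FALSE, 10))))), 0)
  # 400-kb CNV skipped regardless
  expect_equal(nrow(call_introgressions(del(0, 4e5), flag_fix(rep(TRUE, 20)))), 0)
  # duplications must not sneak in
  dup <- del(0, 1e6); dup$kind <- "DUP"
  expect_error(call_introgressions(dup, flag_fix(rep(TRUE, 20))), "DEL")
})

test_that("population summaries use union lengths and reciprocal sharing", {
  panel <- make_panel(LAW = c("l1", "l2"), VAR = c("v1"))
  seg <- function(acc, start, end, chrom = "chr1A") {
    tibble::tibble(accession = acc, chrom = chrom, start = start, end = end,
                   n_windows = 10L, n_candidate = 10L, fraction = 1)
  }
  # landrace-only segment
  s1 <- population_summary(seg("l1", 0, 1e6), panel)
  expect_equal(s1$per_population$length_bp[s1$per_population$population == "LAW"], 1e6)
  expect_equal(sum(s1$per_population$length_bp[s1$per_population$population == "VAR"]), 0)
  expect_equal(s1$shared$shared_bp, 0)
  # identical segment in both populations: fully shared
  s2 <- population_summary(dplyr::bind_rows(seg("l1", 0, 1e6), seg("v1", 0, 1e6)), panel)
  expect_equal(s2$shared$shared_bp, 1e6)
  expect_equal(unique(s2$per_population$subgenome), "A")
  # disjoint segments share nothing despite equal totals
  s3 <- population_summary(dplyr::bind_rows(seg("l1", 0, 1e6), seg("v1", 2e6, 3e6)), panel)
  expect_equal(s3$shared$shared_bp, 0)
})

test_that("QTL point anchors expand 2 Mb both ways and overlaps are reported", {
  qtls <- tibble::tibble(chrom = "chr1", start = 1e7, end = 1e7, trait = "Pm",
                         is_point = TRUE)
  seg <- tibble::tibble(accession = "a1", chrom = "chr1",
                        start = 11500000, end = 13000000)
  hits <- qtl_colocalize(seg, qtls)
  expect_equal(hits$qtl_start, 8e6)
  expect_equal(hits$qtl_end, 1.2e7)
  expect_equal(hits$overlap_bp, 5e5)
  none <- qtl_colocalize(dplyr::mutate(seg, start = 2e7, end = 2.1e7), qtls)
  expect_equal(nrow(none), 0)
  clamped <- qtl_colocalize(dplyr::mutate(seg, start = 8.5e6, end = 9e6),
                            qtls, chrom_lengths = c(chr1 = 1.15e7))
  expect_equal(clamped$qtl_end, 1.15e7)
  low <- qtl_colocalize(dplyr::mutate(seg, start = 1e5, end = 6e5),
                        dplyr::mutate(qtls, start = 1e6, end = 1e6))
  expect_equal(low$qtl_start, 0)               # clamped at the chromosome start
})

test_that("donor ranking assigns only with a clear relative margin", {
  r <- donor_rank(c(X = 0.002, Y = 0.010, Z = 0.012))
  expect_equal(r$assignment, "X")
  expect_equal(r$ranking$donor, c("X", "Y", "Z"))
  near <- donor_rank(c(X = 0.0050, Y = 0.0052))
  expect_equal(near$assignment, "unassigned")
  expect_error(donor_rank(c(X = 1)), "at least 2")
  set.seed(17)
  for (rep in 1:50) {
    d <- setNames(runif(4, 1e-4, 1e-2), c("NL", "SL1", "SL2", "AET"))
    expect_equal(donor_rank(d)$ranking$dxy, sort(unname(d)))
  }
})

test_that("null candidate rates sit near alpha and rise monotonically with divergence fold", {
  carriers <- "A_01"
  rates <- vapply(c(2, 5, 10), function(fold) {
    ev <- planted_event("INTROGRESSION", "chr1", 2e6, 4e6, carriers = carriers,
                        divergence_fold = fold)
    cfg <- sim_config(seed = 500, chrom_lengths = c(chr1 = 5e7),
                      n_per_pop = c(A = 1L), background_divergence = 1e-3,
                      events = ev)
    dv <- z_flag(divergent_windows(simulate_divergent_sites(cfg)))
    mid <- dv$window_start + 25000
    mean(dv$candidate[mid >= 2e6 & mid < 4e6])
  }, double(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.99)
})
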