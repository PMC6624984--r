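test_that("normalization divides by the accession median and rejects dead tracks", {
  d <- make_depth(c(30L, 30L, 30L, 15L))
  expect_equal(normalize_depth(d)$norm_depth, c(1, 1, 1, 0.5))
  expect_equal(unique(normalize_depth(make_depth(rep(30L, 50)))$norm_depth), 1)
  expect_equal(median(normalize_depth(make_depth(rpois(501, 25) + 1L))$norm_depth), 1)
  expect_error(normalize_depth(make_depth(rep(0L, 10))), "uncallable")
})

test_that("window flags use strict thresholds and are mutually exclusive", {
  d <- make_depth(rep(1L, 6))
  d$norm_depth <- c(0.10, 0.24, 0.25, 1.00, 1.75, 1.76)
  f <- flag_windows(d)
  expect_equal(f$flag, c("DEL", "DEL", NA, NA, NA, "DUP"))
  d$norm_depth <- rep(1, 6)
  expect_true(all(is.na(flag_windows(d)$flag)))
  d$norm_depth <- rep(0, 6)
  expect_true(all(flag_windows(d)$flag == "DEL"))
})

test_that("five-of-seven chaining seeds, trims and emits the documented calls", {
  # helper: run chain_calls on an explicit flag pattern
  chain_pattern <- function(hits) {
    d <- make_depth(ifelse(hits, 0L, 30L))
    pad <- make_depth(rep(30L, 20))
    pad$window_start <- pad$window_start + 500 * length(hits)
    d <- dplyr::bind_rows(d, pad)
    calls <- chain_calls(flag_windows(normalize_depth(d)))
    calls[calls$kind == "DEL", c("start", "end", "n_windows")]
  }
  r <- chain_pattern(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(r$start, 0)
  expect_equal(r$end, 3500)    # trimmed to windows 0-5, window 5 covers [2500, 3500)
  expect_equal(r$n_windows, 6L)
  expect_equal(nrow(chain_pattern(c(rep(TRUE, 4), rep(FALSE, 6)))), 0)  # 4 flags never reach 5
  r7 <- chain_pattern(c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_equal(c(r7$start, r7$end), c(0, 4000))
  expect_error(chain_calls(tibble::tibble(flag = "DEL"), min_hits = 5, span = 3),
               "span")
})

test_that("call merging uses the 20%-of-combined-length rule to a fixed point", {
  calls <- tibble::tibble(accession = "a", chrom = "c", kind = "DEL",
                          start = c(0, 12000), end = c(10000, 20000),
                          n_windows = c(10L, 8L), mean_norm_depth = c(0, 0))
  m <- merge_calls(calls)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 20000))  # gap 2000 < 0.2 * 18000

  exact <- calls; exact$start[2] <- 13600       # gap 3600 = 0.2 * 18000 exactly
  expect_equal(nrow(merge_calls(exact)), 2)     # strict <, not merged

  # first merge enables the second
  chain3 <- tibble::tibble(accession = "a", chrom = "c", kind = "DEL",
                           start = c(0, 11000, 25000), end = c(10000, 21000, 33000),
                           n_windows = c(10L, 10L, 8L), mean_norm_depth = 0)
  m3 <- merge_calls(chain3)
  expect_equal(nrow(m3), 1)                     # [0,21000) then gap 4000 < 0.2*29000
  expect_equal(merge_calls(m3), m3)             # idempotent at the fixed point
})

test_that("flag-chain-merge equals the brute-force rule enumerator on random tracks", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(7:30, 1)
    hits <- runif(n) < runif(1, 0.2, 0.8)
    got <- cnv_pipeline_from_hits(hits)
    want <- oracle_cnv(hits)
    expect_equal(got$start, want$start, info = paste("pattern", rep))
    expect_equal(got$end, want$end, info = paste("pattern", rep))
  }
})

test_that("CNV regions form by strict >50% reciprocal overlap with the largest call representative", {
  mk <- function(acc, start, end) {
    tibble::tibble(accession = acc, chrom = "c", start = start, end = end,
                   kind = "DEL", n_windows = 1L, mean_norm_depth = 0)
  }
  # 60% mutual overlap, equal lengths: one region, representative = smaller start
  r <- build_cnvr(dplyr::bind_rows(mk("a", 0, 100000), mk("b", 40000, 140000)))
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 100000))
  expect_equal(r$carriers[[1]], c("a", "b"))
  # 40% of the shorter call: separate regions
  r2 <- build_cnvr(dplyr::bind_rows(mk("a", 0, 100000), mk("b", 60000, 260000)))
  expect_equal(nrow(r2), 2)
  # single linkage: A~B, B~C, not A~C -> one region of three
  r3 <- build_cnvr(dplyr::bind_rows(mk("a", 0, 100000), mk("b", 30000, 130000),
                                    mk("c", 60000, 160000)))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$carriers[[1]], c("a", "b", "c"))
  expect_equal(r3$n_calls, 3L)
  # exclusion drops any call touching an excluded interval
  r4 <- build_cnvr(dplyr::bind_rows(mk("a", 0, 100000), mk("b", 500000, 600000)),
                   exclude = genomic_intervals("c", 90000, 95000))
  expect_equal(nrow(r4), 1)
  expect_equal(r4$carriers[[1]], "b")
})

test_that("region carrier frequencies and RFD follow the |f_a - f_b| definition", {
  panel <- make_panel(LAW = sprintf("l%d", 1:5), VAR = sprintf("v%d", 1:5))
  carriers <- list(c(sprintf("l%d", 1:4), "v1"))  # 0.8 in landraces, 0.2 in varieties
  cnvr <- tibble::tibble(cnvr_id = "cnvr_0001", chrom = "c", start = 0, end = 1e5,
                         kind = "DEL", n_calls = 5L, carriers = carriers)
  r <- rfd(cnvr, panel, "LAW", "VAR")
  expect_equal(r$f_a, 0.8)
  expect_equal(r$f_b, 0.2)
  expect_equal(r$rfd, 0.6)
  cnvr$carriers <- list(c(sprintf("l%d", 1:5)))
  expect_equal(rfd(cnvr, panel, "LAW", "VAR")$rfd, 1)
  cnvr$carriers <- list(character())
  expect_equal(rfd(cnvr, panel, "LAW", "VAR")$rfd, 0)
  expect_error(rfd(cnvr, panel, "LAW", "NOPE"), "no accessions")
})

test_that("RFD thresholding selects strictly above the empirical top quantile", {
  rfd_tbl <- tibble::tibble(cnvr_id = sprintf("c%03d", 1:200), chrom = "c",
                            start = 1:200 * 1000, end = 1:200 * 1000 + 500,
                            kind = "DEL", f_a = 0, f_b = 0,
                            rfd = seq(0, 1, length.out = 200))
  scan <- rfd_threshold(rfd_tbl, q = 0.99)
  expect_equal(sum(tidy(scan)$selected), 2)
  expect_equal(glance(scan)$n_selected, 2L)
  same <- rfd_threshold(dplyr::mutate(rfd_tbl, rfd = 0.5))
  expect_equal(sum(tidy(same)$selected), 0)   # ties at the threshold excluded
})
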