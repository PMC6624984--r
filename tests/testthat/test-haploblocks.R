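test_that("block merging joins across sub-10-kb gaps transitively and rejects overlaps", {
  blocks <- genomic_intervals(rep("chr1", 2), c(0, 1008000), c(1000000, 2000000))
  m <- merge_blocks(blocks)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 2000000))
  expect_equal(m$member_blocks, 2L)

  exact <- genomic_intervals(rep("chr1", 2), c(0, 1010000), c(1000000, 2000000))
  expect_equal(nrow(merge_blocks(exact)), 2)   # gap exactly 10 kb: strict <

  chain <- genomic_intervals(rep("chr1", 3), c(0, 1005000, 2010000),
                             c(1000000, 2002000, 3000000))
  m3 <- merge_blocks(chain)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$member_blocks, 3L)
  # total length = inputs + merged gaps
  expect_equal(m3$end - m3$start,
               sum(chain$end - chain$start) + 5000 + 8000)

  overlapping <- genomic_intervals(rep("chr1", 2), c(0, 500000), c(1000000, 1500000))
  expect_error(merge_blocks(overlapping), "overlap")
})

test_that("haplotype clustering separates clean groups and respects the missing-data rule", {
  block <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  # two internally identical groups differing at every one of 100 sites
  gt <- cbind(matrix(0L, 100, 4), matrix(2L, 100, 4))
  colnames(gt) <- c(sprintf("g1_%d", 1:4), sprintf("g2_%d", 1:4))
  g <- make_geno(gt, pos = sort(sample(0:99999, 100)))
  cl <- cluster_haplotypes(g, block)
  expect_equal(cl$haplotype_diversity, 2L)
  expect_equal(sort(vapply(cl$clusters, length, integer(1))), c(4L, 4L))

  # all identical: one cluster
  same <- make_geno(matrix(1L, 50, 6, dimnames = list(NULL, sprintf("s%d", 1:6))),
                    pos = sort(sample(0:99999, 50)))
  expect_equal(cluster_haplotypes(same, block)$haplotype_diversity, 1L)

  # accession with > 20% missing left unclustered
  gt2 <- gt
  gt2[1:30, "g1_1"] <- NA_integer_
  g2 <- make_geno(gt2, pos = g$sites$pos)
  cl2 <- cluster_haplotypes(g2, block)
  expect_equal(cl2$unclustered, "g1_1")
  expect_false("g1_1" %in% unlist(cl2$clusters))

  # under 20 SNPs: skipped
  tiny <- make_geno(gt[1:10, ], pos = g$sites$pos[1:10])
  expect_message(res <- cluster_haplotypes(tiny, block), "skipped")
  expect_null(res)
})

test_that("clustering agrees with a brute-force connectivity oracle on well-separated fixtures", {
  block <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  set.seed(23)
  for (rep in 1:30) {
    k <- sample(2:3, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    protos <- matrix(sample(0:2, 60 * k, replace = TRUE), ncol = k)
    gt <- do.call(cbind, lapply(seq_len(k), function(ki) {
      m <- matrix(rep(protos[, ki], sizes[ki]), ncol = sizes[ki])
      # 2% within-group noise: well under the 0.1 cut
      flips <- matrix(runif(length(m)) < 0.02, nrow = nrow(m))
      m[flips] <- (m[flips] + 1L) %% 3L
      m
    }))
    colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
    truth <- rep(seq_len(k), sizes)
    # skip draws where random prototypes land too close to separate cleanly
    proto_mismatch <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b) {
      mean(protos[, a] != protos[, b])
    }))
    if (any(proto_mismatch[upper.tri(proto_mismatch)] < 0.3)) next
    g <- make_geno(gt, pos = sort(sample(0:99999, 60)))
    cl <- cluster_haplotypes(g, block)
    expect_equal(cl$haplotype_diversity, k)
    got <- integer(ncol(gt))
    for (ci in seq_along(cl$clusters)) got[match(cl$clusters[[ci]], colnames(gt))] <- ci
    expect_equal(length(unique(paste(got, truth))), k)   # same partition as the truth
  }
})

test_that("ancestry assignment yields donor, mix and unknown labels by the margin rule", {
  block <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  set.seed(41)
  pos <- sort(sample(0:99999, 80))
  nl <- matrix(rbinom(80 * 4, 2, 0.15), 80, 4)
  sl <- matrix(rbinom(80 * 4, 2, 0.85), 80, 4)
  derived_nl <- nl[, 1:2]                      # copied NL haplotypes
  gt <- cbind(nl, sl, derived_nl)
  colnames(gt) <- c(sprintf("nl%d", 1:4), sprintf("sl%d", 1:4), sprintf("bw%d", 1:2))
  g <- make_geno(gt, pos = pos)
  panels <- list(NL = sprintf("nl%d", 1:4), `SL-1` = sprintf("sl%d", 1:4))

  one <- assign_block_ancestry(g, block, list(sprintf("bw%d", 1:2)), panels)
  expect_equal(one$donor_label, "NL")

  # two clusters tracing to different donors -> mix
  gt2 <- cbind(gt[, 1:8], nl[, 1], sl[, 1])
  colnames(gt2) <- c(colnames(gt)[1:8], "bw1", "bw2")
  g2 <- make_geno(gt2, pos = pos)
  mix <- assign_block_ancestry(g2, block, list("bw1", "bw2"), panels)
  expect_equal(mix$donor_label, "mix")

  # equidistant cluster -> unknown
  far <- matrix(1L, 80, 1, dimnames = list(NULL, "bw1"))
  g3 <- make_geno(cbind(gt[, 1:8], far), pos = pos)
  unk <- assign_block_ancestry(g3, block, list("bw1"), panels)
  expect_equal(unk$donor_label, "unknown")
  expect_error(assign_block_ancestry(g, block, list("bw1"), panels[1]), "at least 2")
})

test_that("paint_haploblocks labels each merged block", {
  set.seed(61)
  pos <- sort(sample(0:199999, 160))
  nl <- matrix(rbinom(160 * 4, 2, 0.1), 160, 4)
  sl <- matrix(rbinom(160 * 4, 2, 0.9), 160, 4)
  bw <- nl[, 1:3]
  gt <- cbind(nl, sl, bw)
  colnames(gt) <- c(sprintf("nl%d", 1:4), sprintf("sl%d", 1:4), sprintf("bw%d", 1:3))
  g <- make_geno(gt, pos = pos)
  blocks <- merge_blocks(genomic_intervals(rep("chr1", 2), c(0, 102000),
                                           c(100000, 200000)))
  painted <- paint_haploblocks(g, blocks, derived = sprintf("bw%d", 1:3),
                               wild_panels = list(NL = sprintf("nl%d", 1:4),
                                                  SL = sprintf("sl%d", 1:4)))
  expect_equal(nrow(painted), 1)
  expect_equal(painted$donor_label, "NL")
  expect_gte(painted$haplotype_diversity, 1L)
})
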