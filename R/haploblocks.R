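# Long-range haploblocks. Upstream LD-block finders cap block length (e.g.
# 1 Mb), leaving small gaps (usually < 10 kb) between blocks that are really
# one haplotype structure; those are merged here, haplotypes inside a block
# are clustered by genotype sharing, and each cluster is traced to a
# candidate wild donor population by divergence.

#' Merge adjacent haplotype blocks
#'
#' Non-overlapping input blocks on one chromosome whose gap is strictly
#' below `max_gap` are merged transitively into one long-range haploblock.
#'
#' @param blocks Interval tibble (`chrom`, `start`, `end`), non-overlapping.
#' @param max_gap Maximum gap in bp (default 10 kb, strict `<`).
#' @return Tibble: `chrom`, `start`, `end`, `member_blocks`.
#' @export
merge_blocks <- function(blocks, max_gap = 10000L) {
  if (nrow(blocks) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  member_blocks = integer()))
  }
  blocks |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
        abort(paste0("input blocks overlap on ", key$chrom))
      }
      grp <- cumsum(c(TRUE, (g$start[-1] - g$end[-nrow(g)]) >= max_gap))
      g |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  member_blocks = n(), .groups = "drop") |>
        select(-".grp")
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Cluster accession haplotypes within a block
#'
#' Pairwise distance between accessions is the proportion of mismatching
#' genotype codes over co-called sites in the block; average-linkage
#' hierarchical clustering is cut at height `linkage_cut`. Accessions with
#' more than `max_missing` missing genotypes in the block are left
#' unclustered. Blocks with fewer than `min_snps` SNPs are skipped
#' (returns `NULL` with a message).
#'
#' @param geno A [geno_matrix()].
#' @param block One interval (`chrom`, `start`, `end`) as a 1-row tibble or
#'   list.
#' @param accessions Optional subset of accessions to cluster (default all).
#' @param linkage_cut Tree cut height (default 0.1 — accessions within a
#'   cluster differ at under ~10% of sites).
#' @param min_snps Minimum SNPs in the block (default 20).
#' @param max_missing Per-accession missing-fraction limit (default 0.2).
#' @return List: `clusters` (list of accession-id character vectors,
#'   partitioning the clustered accessions), `unclustered`,
#'   `haplotype_diversity` (number of clusters), `n_snps`.
#' @export
cluster_haplotypes <- function(geno, block, accessions = NULL,
                               linkage_cut = 0.1, min_snps = 20L,
                               max_missing = 0.2) {
  accessions <- accessions %||% colnames(geno$gt)
  sel <- geno$sites$chrom == block$chrom & geno$sites$pos >= block$start &
    geno$sites$pos < block$end
  g <- geno$gt[sel, accessions, drop = FALSE]
  if (nrow(g) < min_snps) {
    inform(sprintf("block %s:%g-%g has %d SNPs (< %d); skipped",
                   block$chrom, block$start, block$end, nrow(g), min_snps))
    return(NULL)
  }
  miss <- colMeans(is.na(g))
  unclustered <- accessions[miss > max_missing]
  use <- accessions[miss <= max_missing]
  if (length(use) == 0) {
    return(list(clusters = list(), unclustered = unclustered,
                haplotype_diversity = 0L, n_snps = nrow(g)))
  }
  if (length(use) == 1) {
    return(list(clusters = list(use), unclustered = unclustered,
                haplotype_diversity = 1L, n_snps = nrow(g)))
  }
  m <- g[, use, drop = FALSE]
  k <- length(use)
  dm <- matrix(0, k, k, dimnames = list(use, use))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    both <- !is.na(m[, i]) & !is.na(m[, j])
    dm[i, j] <- dm[j, i] <-
      if (any(both)) mean(m[both, i] != m[both, j]) else 1
  }
  hc <- hclust(as.dist(dm), method = "average")
  grp <- cutree(hc, h = linkage_cut)
  clusters <- unname(lapply(split(use, grp), sort))
  list(clusters = clusters, unclustered = unclustered,
       haplotype_diversity = length(clusters), n_snps = nrow(g))
}

#' Assign donor-population ancestry to a haploblock
#'
#' Each cluster of derived-wheat haplotypes gets the candidate wild panel
#' with the smallest mean dxy over the block, provided it beats the
#' runner-up by the relative `margin` (else the cluster is unassignable).
#' The block label is the single donor when every assignable cluster
#' agrees, `"mix"` when at least two different donors appear, and
#' `"unknown"` when no cluster can be assigned — haplotypes absent from all
#' sampled wild panels.
#'
#' @param geno A [geno_matrix()].
#' @param block One interval (`chrom`, `start`, `end`).
#' @param clusters List of accession-id vectors (from
#'   [cluster_haplotypes()] on the derived-wheat accessions).
#' @param wild_panels Named list of accession-id vectors, one per candidate
#'   donor population (e.g. `NL`, `SL-1`, `SL-2`).
#' @param margin Relative margin for assignment (default 0.2).
#' @return List: `donor_label` and `per_cluster` tibble (cluster index,
#'   size, best donor, dxy values, assignment).
#' @export
assign_block_ancestry <- function(geno, block, clusters, wild_panels,
                                  margin = 0.2) {
  if (length(wild_panels) < 2) abort("need at least 2 candidate donor panels")
  if (is.null(names(wild_panels))) abort("wild_panels must be named")
  per <- bind_rows(lapply(seq_along(clusters), function(ci) {
    d <- vapply(wild_panels, function(wp) {
      mean_dxy_region(geno, clusters[[ci]], wp, block$chrom, block$start, block$end)
    }, double(1))
    r <- donor_rank(d, margin = margin)
    tibble(cluster = ci, size = length(clusters[[ci]]),
           best_donor = r$ranking$donor[1], best_dxy = r$ranking$dxy[1],
           runner_up_dxy = r$ranking$dxy[2], assignment = r$assignment)
  }))
  assigned <- unique(per$assignment[per$assignment != "unassigned"])
  donor_label <- if (length(assigned) == 0) "unknown"
    else if (length(assigned) == 1) assigned
    else "mix"
  list(donor_label = donor_label, per_cluster = per)
}

#' Paint haploblocks with donor ancestry
#'
#' Convenience wrapper: for each merged haploblock, cluster the derived
#' accessions' haplotypes and assign a donor label.
#'
#' @param geno A [geno_matrix()].
#' @param haploblocks Tibble from [merge_blocks()].
#' @param derived Accession ids whose haplotypes are being traced.
#' @param wild_panels Named list of donor-panel accession vectors.
#' @param linkage_cut,min_snps,margin Passed through.
#' @return Haploblock tibble with `n_snps`, `haplotype_diversity` and
#'   `donor_label` columns (blocks skipped for SNP count get `NA`).
#' @export
paint_haploblocks <- function(geno, haploblocks, derived, wild_panels,
                              linkage_cut = 0.1, min_snps = 20L, margin = 0.2) {
  res <- lapply(seq_len(nrow(haploblocks)), function(i) {
    b <- haploblocks[i, ]
    cl <- cluster_haplotypes(geno, b, accessions = derived,
                             linkage_cut = linkage_cut, min_snps = min_snps)
    if (is.null(cl)) {
      return(tibble(n_snps = NA_integer_, haplotype_diversity = NA_integer_,
                    donor_label = NA_character_))
    }
    anc <- assign_block_ancestry(geno, b, cl$clusters, wild_panels, margin = margin)
    tibble(n_snps = cl$n_snps, haplotype_diversity = cl$haplotype_diversity,
           donor_label = anc$donor_label)
  })
  dplyr::bind_cols(haploblocks, bind_rows(res))
}
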