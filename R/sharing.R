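# Replicate-consistency filtering and shared/specific clade accounting
# across sites and vegetation stages (Venn-style region counts).

#' Replicate-consistency filter
#'
#' Within each (site, stage) group, a cluster passes if it has a nonzero
#' count in at least `min_replicates` of the group's biological replicates;
#' a cluster is retained globally if it passes in at least one group.
#'
#' @param otu_table Tibble with `otu_id` + per-sample count columns.
#' @param metadata Metadata mapping `sample_id` to `site`, `stage`,
#'   `replicate`.
#' @param min_replicates Minimum replicates a cluster must appear in
#'   (default 2).
#' @return A list with `otu_ids` (retained cluster ids), `presence`
#'   (tibble: otu_id, site, stage, pass) and the filtered `otu_table`.
#' @export
replicate_consistent <- function(otu_table, metadata, min_replicates = 2) {
  md <- metadata[metadata$sample_id %in% names(otu_table), ]
  grp <- md |> group_by(.data$site, .data$stage) |>
    summarise(n_rep = dplyr::n_distinct(.data$replicate), .groups = "drop")
  short <- grp[grp$n_rep < min_replicates, ]
  if (nrow(short)) {
    abort(sprintf("replicate_consistent(): group %s/%s has %d replicate(s), need %d",
                  short$site[1], short$stage[1], short$n_rep[1], min_replicates))
  }
  m <- otu_matrix(otu_table)
  presence <- purrr::pmap(grp, function(site, stage, n_rep) {
    cols <- md$sample_id[md$site == site & md$stage == stage]
    nz <- rowSums(m[, cols, drop = FALSE] > 0)
    tibble(otu_id = rownames(m), site = site, stage = stage,
           n_present = as.integer(nz), pass = nz >= min_replicates)
  }) |> bind_rows()
  keep <- presence |> group_by(.data$otu_id) |>
    summarise(pass = any(.data$pass)) |> filter(.data$pass) |> pull(.data$otu_id)
  smdiv_log("replicate_consistent: %d clusters -> %d retained", nrow(m),
            length(keep))
  list(otu_ids = keep,
       presence = presence,
       otu_table = otu_table[otu_table$otu_id %in% keep, ])
}

#' Venn region counts over presence sets
#'
#' Exact region counts for 2- to 5-set Venn partitions: every non-empty
#' subset of groups maps to the number of elements present in exactly those
#' groups. Percentages are normalized by the size of the union, one
#' decimal.
#'
#' @param sets Named list of character vectors (cluster ids per group).
#' @return Tibble: `region` (group names joined by `&`), `n_groups`,
#'   `count`, `percent`.
#' @export
venn_regions <- function(sets) {
  if (length(sets) < 2) abort("venn_regions(): need at least two sets")
  if (length(sets) > 5) {
    abort("venn_regions(): more than 5 groups; use a combinatorial report")
  }
  groups <- names(sets)
  if (is.null(groups) || any(!nzchar(groups))) {
    abort("venn_regions(): sets must be named")
  }
  all_el <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_el %in% s,
                   logical(length(all_el)))
  if (length(all_el) == 1L) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, groups))
  sig <- apply(member, 1, function(r) paste(groups[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(groups, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- vapply(combos, function(cb) sum(sig == cb), integer(1),
                   USE.NAMES = FALSE)
  total <- length(all_el)
  tibble(region = combos,
         n_groups = lengths(strsplit(combos, "&", fixed = TRUE)),
         count = counts,
         percent = if (total > 0) round(100 * counts / total, 1) else
           rep(NA_real_, length(counts)))
}

#' Stage-sharing report per site across identity thresholds
#'
#' For each clustering threshold, reads are clustered, replicate-filtered,
#' and per site the clusters present at both stages versus one stage are
#' counted; the percentage shared between emergence and senescence is
#' reported per site along with the across-site average.
#'
#' @param uniques Dereplicated sequence tibble (with `samples` bookkeeping).
#' @param metadata Sample metadata.
#' @param thresholds Identity thresholds (default `c(0.97, 0.90, 0.85)`).
#' @param min_replicates Replicate-consistency cutoff (default 2).
#' @param cluster_fn Clustering backend, `greedy_cluster` by default (a
#'   caching wrapper may be supplied).
#' @return Tibble: `threshold`, `site`, `n_clusters`, `shared`,
#'   `shared_pct`, plus rows with `site = "average"` carrying the mean
#'   percentage across sites.
#' @export
stage_sharing_report <- function(uniques, metadata,
                                 thresholds = c(0.97, 0.90, 0.85),
                                 min_replicates = 2,
                                 cluster_fn = greedy_cluster) {
  purrr::map(thresholds, function(th) {
    cl <- cluster_fn(uniques, th)
    tab <- build_otu_table(cl)
    rc <- replicate_consistent(tab, metadata, min_replicates)
    per_site <- purrr::map(unique(metadata$site), function(s) {
      pres <- rc$presence |> filter(.data$site == s, .data$pass)
      by_stage <- split(pres$otu_id, pres$stage)
      if (length(by_stage) < 2) {
        return(tibble(threshold = th, site = s, n_clusters = NA_integer_,
                      shared = NA_integer_, shared_pct = NA_real_))
      }
      vr <- venn_regions(by_stage)
      tot <- sum(vr$count)
      sh <- vr$count[vr$n_groups == 2]
      tibble(threshold = th, site = s, n_clusters = tot,
             shared = sh, shared_pct = round(100 * sh / tot, 1))
    }) |> bind_rows()
    bind_rows(per_site,
              tibble(threshold = th, site = "average",
                     n_clusters = sum(per_site$n_clusters),
                     shared = sum(per_site$shared),
                     shared_pct = round(mean(per_site$shared_pct), 1)))
  }) |> bind_rows()
}

#' Site-sharing Venn report at multiple thresholds
#'
#' Clusters the uniques at each threshold, applies the replicate filter,
#' pools stages, and reports Venn regions of cluster presence across sites.
#'
#' @inheritParams stage_sharing_report
#' @return Tibble of Venn regions per threshold.
#' @export
site_sharing_report <- function(uniques, metadata,
                                thresholds = c(0.97, 0.90, 0.85),
                                min_replicates = 2,
                                cluster_fn = greedy_cluster) {
  purrr::map(thresholds, function(th) {
    cl <- cluster_fn(uniques, th)
    tab <- build_otu_table(cl)
    rc <- replicate_consistent(tab, metadata, min_replicates)
    pres <- rc$presence |> filter(.data$pass)
    by_site <- lapply(split(pres$otu_id, pres$site), unique)
    vr <- venn_regions(by_site)
    vr$threshold <- th
    vr[, c("threshold", setdiff(names(vr), "threshold"))]
  }) |> bind_rows()
}
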