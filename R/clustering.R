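# Pairwise alignment identity, greedy centroid (UCLUST-style) clustering,
# OTU-table construction, representative picking, and query-vs-reference
# shared-cluster accounting.

ALN_MATCH <- 1; ALN_MISMATCH <- -1; ALN_GAP_OPEN <- 1; ALN_GAP_EXTEND <- 1

# Align one query against a set of sequences; return identity fractions.
# Identity = matching columns / alignment columns, with terminal-gap columns
# excluded; internal gap columns count as mismatching columns.
# When `min_identity` is given, pairs whose identity provably falls below it
# (the upper bound matches/(matches+mismatches) is already lower) skip the
# costly traceback and report that upper bound instead; values at or above
# `min_identity` are always exact.
identity_to_set <- function(query, targets, min_identity = NULL) {
  if (length(targets) == 0L) return(numeric(0))
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(targets),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = sm,
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXTEND)
  ni <- Biostrings::nindel(aln)
  n_gap_runs <- Biostrings::insertion(ni)[, "Length"] +
    Biostrings::deletion(ni)[, "Length"]
  m <- Biostrings::nmatch(aln)
  x <- Biostrings::nmismatch(aln)
  out <- numeric(length(targets))
  ub <- m / pmax(m + x, 1L)   # alignment columns >= m + x, so this bounds identity
  # gapless alignments need no traceback: identity = matches / columns
  fast <- n_gap_runs == 0
  if (!is.null(min_identity)) fast <- fast | ub < min_identity
  out[fast] <- ub[fast]
  if (any(!fast)) {
    p <- as.character(Biostrings::alignedPattern(aln[!fast]))
    s <- as.character(Biostrings::alignedSubject(aln[!fast]))
    out[!fast] <- vapply(seq_along(p), function(i)
      aligned_identity(p[i], s[i]), numeric(1))
  }
  out
}

aligned_identity <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  nong <- which(pc != "-" & sc != "-")
  if (!length(nong)) return(0)
  # terminal gap columns: before the first and after the last column where
  # both sequences have a base
  keep <- seq(min(nong), max(nong))
  sum(pc[keep] == sc[keep] & pc[keep] != "-") / length(keep)
}

#' Global-alignment identity between two DNA sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2 for
#' the first gap column, -1 per extension) computed with
#' \pkg{Biostrings}; identity is the fraction of matching columns over
#' alignment columns, excluding terminal-gap columns (internal gaps count as
#' non-matching columns). Symmetric in its arguments.
#'
#' @param a,b Non-empty plain DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("pairwise_identity(): empty sequence")
  identity_to_set(b, a)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Input sequences are sorted by (size desc, length desc, id asc); the first
#' seeds a centroid and each subsequent sequence joins the first existing
#' centroid (in creation order) with alignment identity at or above the
#' threshold, else seeds a new centroid. Deterministic for a fixed input
#' set.
#'
#' @param seqs Tibble with columns `id`, `sequence`, optional `size`
#'   (default 1); any further columns (e.g. `samples`, `origin`) are carried
#'   through.
#' @param threshold Identity threshold in `(0, 1]`.
#' @return A membership tibble: one row per input sequence with added
#'   `cluster_id`, `centroid_id`, `is_centroid`, `identity_to_centroid`;
#'   `threshold` is attached as an attribute.
#' @export
greedy_cluster <- function(seqs, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  seqs <- as_tibble(seqs)
  if (!"size" %in% names(seqs)) seqs$size <- 1L
  if (nrow(seqs) == 0L) {
    out <- dplyr::mutate(seqs, cluster_id = character(),
                         centroid_id = character(), is_centroid = logical(),
                         identity_to_centroid = numeric())
    attr(out, "threshold") <- threshold
    return(out)
  }
  ord <- order(-seqs$size, -nchar(seqs$sequence), seqs$id, method = "radix")
  seqs <- seqs[ord, ]
  n <- nrow(seqs)
  assign_idx <- integer(n)       # centroid index per sequence
  ident <- numeric(n)
  centroid_rows <- integer(0)    # row indices of centroids, creation order
  for (i in seq_len(n)) {
    if (length(centroid_rows)) {
      ids <- identity_to_set(seqs$sequence[i], seqs$sequence[centroid_rows],
                             min_identity = threshold)
      hit <- which(ids >= threshold)
    } else hit <- integer(0)
    if (length(hit)) {
      assign_idx[i] <- hit[1]
      ident[i] <- ids[hit[1]]
    } else {
      centroid_rows <- c(centroid_rows, i)
      assign_idx[i] <- length(centroid_rows)
      ident[i] <- 1
    }
  }
  cid <- sprintf("OTU_%04d", assign_idx)
  out <- dplyr::mutate(seqs,
    cluster_id = cid,
    centroid_id = seqs$id[centroid_rows][assign_idx],
    is_centroid = .data$id == .data$centroid_id,
    identity_to_centroid = ident)
  attr(out, "threshold") <- threshold
  smdiv_log("greedy_cluster: %d sequences -> %d clusters at %.2f",
            n, length(centroid_rows), threshold)
  out
}

#' Number of clusters in a membership tibble
#' @param clusters Output of [greedy_cluster()].
#' @return Integer count of distinct clusters.
#' @export
n_clusters <- function(clusters) dplyr::n_distinct(clusters$cluster_id)

#' Build an OTU count table from cluster membership
#'
#' Cell values are the summed per-sample duplicate counts of the cluster's
#' members. Per-sample counts come either from a `samples` list-column of
#' named integer vectors (as produced by [dereplicate()]) or, failing that,
#' from a `sample_id` + `size` pair of columns.
#'
#' @param clusters Membership tibble from [greedy_cluster()].
#' @return A tibble with `otu_id` and one integer column per sample, rows
#'   ordered by total abundance (descending), then `otu_id`.
#' @export
build_otu_table <- function(clusters) {
  if (nrow(clusters) == 0L) return(tibble(otu_id = character()))
  if ("samples" %in% names(clusters)) {
    long <- clusters |>
      dplyr::select("cluster_id", "samples") |>
      dplyr::mutate(.sm = purrr::map(.data$samples, function(v) {
        tibble(sample_id = names(v), n = as.integer(v))
      })) |>
      dplyr::select("cluster_id", ".sm") |>
      tidyr::unnest(".sm")
  } else if (all(c("sample_id", "size") %in% names(clusters))) {
    long <- clusters |>
      dplyr::transmute(cluster_id = .data$cluster_id,
                       sample_id = .data$sample_id, n = as.integer(.data$size))
  } else {
    abort("build_otu_table(): need a 'samples' list-column or sample_id+size")
  }
  wide <- long |>
    group_by(.data$cluster_id, .data$sample_id) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L, names_sort = TRUE) |>
    rename(otu_id = "cluster_id")
  tot <- rowSums(as.matrix(wide[, -1, drop = FALSE]))
  wide[order(-tot, wide$otu_id), ]
}

#' Pick representative (centroid) sequences per cluster
#'
#' Headers carry cluster id, total size and, when metadata is supplied, the
#' majority site and stage of the cluster's read mass (ties broken by label
#' sort order).
#'
#' @param clusters Membership tibble with a `samples` list-column or
#'   `sample_id` column.
#' @param metadata Optional sample metadata tibble (`sample_id`, `site`,
#'   `stage`).
#' @return Tibble with `id` (annotated header), `cluster_id`, `sequence`.
#' @export
pick_representatives <- function(clusters, metadata = NULL) {
  if (nrow(clusters) == 0L) {
    return(tibble(id = character(), cluster_id = character(),
                  sequence = character()))
  }
  cent <- clusters |> filter(.data$is_centroid) |> arrange(.data$cluster_id)
  sizes <- clusters |>
    group_by(.data$cluster_id) |>
    summarise(total = sum(.data$size), .groups = "drop")
  cent <- left_join(cent, sizes, by = "cluster_id")
  ann <- rep("", nrow(cent))
  if (!is.null(metadata)) {
    long <- cluster_sample_long(clusters)
    long <- left_join(long, metadata[, c("sample_id", "site", "stage")],
                      by = "sample_id")
    site_maj <- long |>
      group_by(.data$cluster_id, .data$site) |>
      summarise(n = sum(.data$n), .groups = "drop") |>
      group_by(.data$cluster_id) |>
      arrange(desc(.data$n), .data$site, .by_group = TRUE) |>
      dplyr::slice(1) |> select("cluster_id", site = "site")
    stage_maj <- long |>
      group_by(.data$cluster_id, .data$stage) |>
      summarise(n = sum(.data$n), .groups = "drop") |>
      group_by(.data$cluster_id) |>
      arrange(desc(.data$n), .data$stage, .by_group = TRUE) |>
      dplyr::slice(1) |> select("cluster_id", stage = "stage")
    cent <- cent |> left_join(site_maj, by = "cluster_id") |>
      left_join(stage_maj, by = "cluster_id")
    ann <- sprintf(";site=%s;stage=%s", cent$site, cent$stage)
  }
  tibble(
    id = sprintf("%s;size=%d%s", cent$cluster_id, as.integer(cent$total), ann),
    cluster_id = cent$cluster_id,
    sequence = cent$sequence)
}

# membership -> long (cluster_id, sample_id, n)
cluster_sample_long <- function(clusters) {
  if ("samples" %in% names(clusters)) {
    clusters |>
      dplyr::select("cluster_id", "samples") |>
      dplyr::mutate(.sm = purrr::map(.data$samples, function(v) {
        tibble(sample_id = names(v), n = as.integer(v))
      })) |>
      dplyr::select("cluster_id", ".sm") |>
      tidyr::unnest(".sm")
  } else {
    clusters |>
      dplyr::transmute(cluster_id = .data$cluster_id,
                       sample_id = .data$sample_id,
                       n = as.integer(.data$size))
  }
}

#' Shared-cluster accounting between a query set and a reference set
#'
#' Pools both sets and clusters at each threshold; a cluster is *shared* iff
#' it contains at least one query and one reference member. At every
#' threshold `query_only + reference_only + shared == total`.
#'
#' @param query,reference Tibbles with `id`, `sequence`, optional `size`.
#' @param thresholds Numeric vector of identity thresholds.
#' @return Tibble: `threshold`, `total`, `query_only`, `reference_only`,
#'   `shared`.
#' @export
shared_with_reference <- function(query, reference,
                                  thresholds = c(0.75, 0.85, 0.90, 0.97)) {
  q <- as_tibble(query);  q$origin <- "query"
  r <- as_tibble(reference); r$origin <- "reference"
  if (!"size" %in% names(q)) q$size <- 1L
  if (!"size" %in% names(r)) r$size <- 1L
  common <- intersect(names(q), names(r))
  pool <- bind_rows(q[common], r[common])
  pool$id <- make.unique(pool$id)
  purrr::map(thresholds, function(th) {
    cl <- greedy_cluster(pool, th)
    per <- cl |>
      group_by(.data$cluster_id) |>
      summarise(has_q = any(.data$origin == "query"),
                has_r = any(.data$origin == "reference"), .groups = "drop")
    tibble(threshold = th,
           total = nrow(per),
           query_only = sum(per$has_q & !per$has_r),
           reference_only = sum(!per$has_q & per$has_r),
           shared = sum(per$has_q & per$has_r))
  }) |> bind_rows()
}
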