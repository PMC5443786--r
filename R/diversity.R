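# Alpha diversity (observed richness, Chao1), iterated rarefaction,
# coverage ratios, and the alpha/gamma effective-species overlap model.

#' Chao1 richness estimate
#'
#' Bias-corrected Chao1: `S_obs + F1*(F1-1) / (2*(F2+1))`, where `F1` and
#' `F2` are the singleton and doubleton counts. The classic form
#' `S_obs + F1^2/(2*F2)` is available with `bias_corrected = FALSE` (it is
#' undefined at `F2 = 0`, where the corrected form is substituted).
#'
#' @param otu_counts Non-negative integer vector of per-OTU counts; zeros
#'   are ignored.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return A one-row tibble: `observed`, `chao1`, `F1`, `F2`,
#'   `coverage_pct` (= half-up-rounded `100 * observed / chao1`) and the
#'   raw `coverage` ratio.
#' @export
#' @examples
#' chao1(c(1, 1, 2, 2, 3))
chao1 <- function(otu_counts, bias_corrected = TRUE) {
  if (any(otu_counts < 0)) abort("chao1(): negative counts")
  x <- otu_counts[otu_counts > 0]
  obs <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  est <- if (obs == 0) {
    0
  } else if (bias_corrected || f2 == 0) {
    obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    obs + f1^2 / (2 * f2)
  }
  cov <- if (est > 0) obs / est else NA_real_
  tibble(observed = obs, chao1 = est, F1 = f1, F2 = f2,
         coverage = cov,
         coverage_pct = ifelse(is.na(cov), NA_real_, round_half_up(100 * cov)))
}

#' Iterated rarefaction of an OTU count vector
#'
#' Subsamples without replacement at each depth for `iterations` rounds and
#' reports mean observed richness and mean Chao1.
#'
#' @param otu_counts Non-negative integer counts.
#' @param depths Depths to rarefy to; each must not exceed the total count.
#' @param iterations Rounds per depth (default 10).
#' @param seed Integer seed.
#' @return Tibble: `depth`, `mean_observed`, `mean_chao1`.
#' @export
rarefy_curve <- function(otu_counts, depths, iterations = 10, seed = 1) {
  total <- sum(otu_counts)
  if (any(depths > total)) {
    abort(sprintf("rarefy_curve(): depth %d exceeds total count %d",
                  max(depths), total))
  }
  pool <- rep.int(seq_along(otu_counts), otu_counts)
  with_seed(seed, {
    res <- purrr::map(sort(depths), function(d) {
      per <- purrr::map(seq_len(iterations), function(i) {
        sub <- tabulate(sample(pool, d), nbins = length(otu_counts))
        chao1(sub)[, c("observed", "chao1")]
      }) |> bind_rows()
      tibble(depth = d, mean_observed = mean(per$observed),
             mean_chao1 = mean(per$chao1))
    }) |> bind_rows()
  })
  res
}

#' Effective-species overlap among N communities
#'
#' The alpha/gamma overlap model `(alpha/gamma - 1/N) / (1 - 1/N)`, where
#' `alpha` is the arithmetic mean of the per-community richness values and
#' `gamma` the pooled richness, both measured as effective numbers of
#' species. Equals 1 when all communities are identical and 0 when they are
#' completely distinct; the result is clipped to `[0, 1]`.
#'
#' @param alphas Numeric vector of per-community richness (length >= 2).
#' @param gamma Pooled richness (> 0).
#' @param N Number of communities (default `length(alphas)`).
#' @return Overlap fraction in `[0, 1]`.
#' @export
#' @examples
#' overlap_statistic(c(10, 10, 10), 10)   # identical -> 1
#' overlap_statistic(c(10, 10, 10), 30)   # disjoint  -> 0
overlap_statistic <- function(alphas, gamma, N = length(alphas)) {
  if (length(alphas) < 2 || N < 2) {
    abort("overlap_statistic(): need at least two communities")
  }
  if (gamma <= 0) abort("overlap_statistic(): gamma must be positive")
  if (gamma < max(alphas)) {
    warn("overlap_statistic(): gamma < max(alphas); richness estimator noise")
  }
  alpha <- mean(alphas)
  raw <- (alpha / gamma - 1 / N) / (1 - 1 / N)
  min(1, max(0, raw))
}

#' Per-site richness and overlap report
#'
#' Computes per-site and pooled Chao1 richness from OTU tables, the mean
#' alpha richness, per-site coverage ratios, and the effective-species
#' overlap among sites (computed on Chao1 richness, with observed-OTU
#' richness reported alongside).
#'
#' @param site_tables Named list of per-site OTU tables (tibbles with
#'   `otu_id` + count columns), or a single OTU table plus `metadata` to
#'   split by site.
#' @param metadata Optional metadata to map sample columns to sites.
#' @return A list with `per_site` (tibble: site, n_sequences, observed,
#'   chao1, coverage, coverage_pct), `pooled` (same for the pooled table),
#'   `mean_alpha` (half-up-rounded mean per-site Chao1), `overlap`
#'   (fraction, on Chao1), `overlap_pct` (half-up-rounded percent) and
#'   `overlap_observed` (same statistic on observed OTUs).
#' @export
site_overlap_report <- function(site_tables, metadata = NULL) {
  if (!is.null(metadata) && is.data.frame(site_tables)) {
    tab <- site_tables
    site_tables <- split_table_by_site(tab, metadata)
  }
  if (length(site_tables) < 2) {
    abort("site_overlap_report(): need OTU tables for at least two sites")
  }
  site_counts <- purrr::map(site_tables, function(t)
    rowSums(as.matrix(t[, -1, drop = FALSE])))
  per_site <- purrr::imap(site_counts, function(v, nm) {
    e <- chao1(v)
    dplyr::bind_cols(tibble(site = nm, n_sequences = sum(v)), e)
  }) |> bind_rows()
  pooled_counts <- pooled_otu_counts(site_tables)
  pooled <- dplyr::bind_cols(tibble(site = "pooled",
                                    n_sequences = sum(pooled_counts)),
                             chao1(pooled_counts))
  ov <- overlap_statistic(per_site$chao1, pooled$chao1)
  ov_obs <- overlap_statistic(per_site$observed, pooled$observed)
  list(per_site = per_site,
       pooled = pooled,
       mean_alpha = round_half_up(mean(per_site$chao1)),
       overlap = ov,
       overlap_pct = round_half_up(100 * ov),
       overlap_observed = ov_obs)
}

# sum per-OTU counts across site tables by otu_id
pooled_otu_counts <- function(site_tables) {
  long <- purrr::map(site_tables, function(t) {
    tibble(otu_id = t$otu_id, n = rowSums(as.matrix(t[, -1, drop = FALSE])))
  }) |> bind_rows()
  long |> group_by(.data$otu_id) |> summarise(n = sum(.data$n)) |> pull(.data$n)
}

split_table_by_site <- function(tab, metadata) {
  sites <- unique(metadata$site)
  setNames(lapply(sites, function(s) {
    cols <- metadata$sample_id[metadata$site == s]
    cols <- intersect(cols, names(tab))
    tab[, c("otu_id", cols)]
  }), sites)
}
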