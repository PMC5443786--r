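# Per-OTU negative-binomial regression with likelihood-ratio ANOVA, a
# multivariate sum-of-LRT statistic, bootstrap resampling inference, and
# Spearman correlation of differentially abundant OTUs across marker and
# biosynthetic-gene tables.

# ---- internal NB fitting -------------------------------------------------

# TRUE when the design matrix encodes a saturated group structure (each
# distinct row its own parameter), in which case the NB MLE of the means is
# the per-group sample mean.
is_group_design <- function(X) {
  ur <- unique(as.data.frame(X))
  nrow(ur) == qr(X)$rank && nrow(ur) == ncol(X)
}

safe_theta <- function(y, mu, cap = 1e5) {
  if (all(y == 0)) return(cap)
  th <- tryCatch(
    suppressWarnings(MASS::theta.ml(y, pmax(mu, 1e-10), limit = 25)),
    error = function(e) cap)
  min(as.numeric(th), cap)
}

# ML fit of an NB log-linear model; returns mu, theta, logLik.
nb_fit <- function(y, X) {
  if (sum(y) == 0) {
    return(list(mu = rep(1e-10, length(y)), theta = 1e5, loglik = 0,
                converged = TRUE))
  }
  if (is_group_design(X)) {
    g <- interaction(as.data.frame(X), drop = TRUE)
    mu <- stats::ave(y, g)
    theta <- safe_theta(y, mu)
    ll <- sum(dnbinom(y, size = theta, mu = pmax(mu, 1e-10), log = TRUE))
    return(list(mu = mu, theta = theta, loglik = ll, converged = TRUE))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu = NULL, theta = NA, loglik = NA, converged = FALSE))
  }
  mu <- pmax(fit$fitted.values, 1e-10)
  ll_old <- -Inf; theta <- 10; ok <- TRUE
  for (it in 1:25) {
    theta <- safe_theta(y, mu)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y,
                                      family = MASS::negative.binomial(theta))),
      error = function(e) NULL)
    if (is.null(fit)) { ok <- FALSE; break }
    mu <- pmax(fit$fitted.values, 1e-10)
    ll <- sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
    if (is.finite(ll) && abs(ll - ll_old) < 1e-8) break
    ll_old <- ll
  }
  if (!ok || !is.finite(ll_old) && !is.finite(ll)) {
    return(list(mu = NULL, theta = NA, loglik = NA, converged = FALSE))
  }
  list(mu = mu, theta = theta, loglik = ll, converged = TRUE)
}

# randomized PIT residuals of an NB fit (uniform under the fitted model)
pit_residuals <- function(y, mu, theta) {
  lo <- pnbinom(y - 1, size = theta, mu = mu)
  hi <- pnbinom(y, size = theta, mu = mu)
  u <- lo + runif(length(y)) * (hi - lo)
  pmin(pmax(u, 1e-10), 1 - 1e-10)
}

#' Per-OTU negative-binomial differential-abundance test with bootstrap
#' inference
#'
#' Fits, per OTU, a negative-binomial log-linear regression of counts on
#' the requested sample factors (per-OTU dispersion by maximum
#' likelihood). Each factor is tested by a likelihood-ratio test of the
#' full model against the model with that factor dropped; a multivariate,
#' community-level statistic per factor is the sum of per-OTU LRT
#' statistics. Significance is assessed by residual resampling: randomized
#' PIT (probability integral transform) residuals of the null model are
#' permuted across samples (one permutation shared by all OTUs, preserving
#' between-OTU association) and mapped back through the null NB quantile
#' function; `p = (1 + #{stat* >= stat}) / (n_boot + 1)`.
#'
#' @param otu_table Tibble with `otu_id` + per-sample integer counts.
#' @param metadata Sample metadata containing the factor columns.
#' @param factors Factor names to test (default `c("site", "stage")`); each
#'   needs at least two levels.
#' @param n_boot Bootstrap resamples (default 999).
#' @param seed Integer seed.
#' @return An object of class `smdiv_diff`: `per_otu` tibble (`otu_id`,
#'   `factor`, `lrt`, `p_boot`, `p_adj` (Benjamini-Hochberg), `converged`),
#'   `multivariate` tibble (`factor`, `stat`, `p_boot`), `n_otu_excluded`.
#' @export
fit_differential <- function(otu_table, metadata,
                             factors = c("site", "stage"),
                             n_boot = 999, seed = 1) {
  m <- otu_matrix(otu_table)
  samples <- colnames(m)
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) abort("fit_differential(): samples missing from metadata")
  for (f in factors) {
    if (!f %in% names(md)) abort(sprintf("fit_differential(): no factor '%s'", f))
    if (length(unique(md[[f]])) < 2) {
      abort(sprintf("fit_differential(): factor '%s' has a single level", f))
    }
  }
  fml_full <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  X_full <- stats::model.matrix(fml_full, data = md)
  X_red <- lapply(factors, function(f) {
    others <- setdiff(factors, f)
    fml <- if (length(others)) {
      stats::as.formula(paste("~", paste(others, collapse = " + ")))
    } else ~1
    stats::model.matrix(fml, data = md)
  })
  names(X_red) <- factors

  n_otu <- nrow(m); n_s <- ncol(m)
  fit_all <- function(Y) {
    # returns list(loglik vector, fits list) for a design, per OTU
    function(X) {
      fits <- lapply(seq_len(nrow(Y)), function(i) nb_fit(Y[i, ], X))
      list(ll = vapply(fits, function(f)
        ifelse(f$converged, f$loglik, NA_real_), numeric(1)), fits = fits)
    }
  }
  obs_full <- fit_all(m)(X_full)
  res <- with_seed(seed, {
    purrr::map(factors, function(f) {
      obs_red <- fit_all(m)(X_red[[f]])
      lrt <- 2 * (obs_full$ll - obs_red$ll)
      lrt[!is.na(lrt) & lrt < 0] <- 0
      conv <- !is.na(lrt)
      stat_obs <- sum(lrt[conv])
      # bootstrap under the null for this factor
      mu0 <- do.call(rbind, lapply(obs_red$fits, function(ft)
        if (is.null(ft$mu)) rep(NA_real_, n_s) else ft$mu))
      th0 <- vapply(obs_red$fits, function(ft) ft$theta, numeric(1))
      U <- do.call(rbind, lapply(seq_len(n_otu), function(i) {
        if (!conv[i]) return(rep(NA_real_, n_s))
        pit_residuals(m[i, ], mu0[i, ], th0[i])
      }))
      stat_boot <- numeric(n_boot)
      lrt_boot_ge <- rep(0L, n_otu)
      for (b in seq_len(n_boot)) {
        perm <- sample.int(n_s)
        lrt_b <- rep(NA_real_, n_otu)
        for (i in which(conv)) {
          ystar <- qnbinom(U[i, perm], size = th0[i], mu = mu0[i, ])
          ff <- nb_fit(ystar, X_full)
          fr <- nb_fit(ystar, X_red[[f]])
          if (ff$converged && fr$converged) {
            lrt_b[i] <- max(0, 2 * (ff$loglik - fr$loglik))
          }
        }
        stat_boot[b] <- sum(lrt_b, na.rm = TRUE)
        lrt_boot_ge <- lrt_boot_ge +
          as.integer(!is.na(lrt_b) & lrt_b >= lrt - 1e-12)
      }
      p_multi <- (1 + sum(stat_boot >= stat_obs - 1e-9)) / (n_boot + 1)
      p_otu <- (1 + lrt_boot_ge) / (n_boot + 1)
      p_otu[!conv] <- NA_real_
      list(per_otu = tibble(otu_id = rownames(m), factor = f, lrt = lrt,
                            p_boot = p_otu,
                            p_adj = p.adjust(p_otu, "BH"),
                            converged = conv),
           multivariate = tibble(factor = f, stat = stat_obs,
                                 p_boot = p_multi))
    })
  })
  per_otu <- bind_rows(purrr::map(res, "per_otu"))
  multivariate <- bind_rows(purrr::map(res, "multivariate"))
  n_exc <- sum(!per_otu$converged)
  if (n_exc > 0) {
    smdiv_log("fit_differential: %d OTU fit(s) did not converge; excluded", n_exc)
  }
  structure(list(per_otu = per_otu, multivariate = multivariate,
                 factors = factors, n_boot = n_boot,
                 n_otu = n_otu, n_otu_excluded = n_exc,
                 fitted = do.call(rbind, lapply(obs_full$fits, function(ft)
                   if (is.null(ft$mu)) rep(NA_real_, n_s) else ft$mu)),
                 counts = m),
            class = "smdiv_diff")
}

#' @export
print.smdiv_diff <- function(x, ...) {
  cat(sprintf("Negative-binomial differential abundance (%d OTUs, %d bootstraps)\n",
              x$n_otu, x$n_boot))
  print(x$multivariate)
  invisible(x)
}

#' Model diagnostics: fitted values vs randomized residuals
#'
#' @param x A `smdiv_diff` object.
#' @return Tibble: `otu_id`, `sample_id`, `fitted`, `observed`, `residual`
#'   (Pearson).
#' @export
diff_diagnostics <- function(x) {
  stopifnot(inherits(x, "smdiv_diff"))
  fitted <- x$fitted; obs <- x$counts
  tibble(otu_id = rep(rownames(obs), ncol(obs)),
         sample_id = rep(colnames(obs), each = nrow(obs)),
         fitted = as.vector(fitted),
         observed = as.vector(obs),
         residual = as.vector((obs - fitted) / sqrt(pmax(fitted, 1e-10))))
}

#' Default taxon-pairing rules for correlation analysis
#'
#' Marker (16S rRNA) OTUs assigned to Firmicutes are evaluated against
#' ACP-derived genes, while OTUs from Actinobacteria, Firmicutes and
#' Proteobacteria are evaluated against KS, met-mal-CoA and AD (NRPS)
#' derived genes.
#'
#' @return Named list: domain -> admissible marker phyla.
#' @export
default_pairing_rules <- function() {
  list(ACP = "Firmicutes",
       KS = c("Actinobacteria", "Firmicutes", "Proteobacteria"),
       `met-mal-CoA` = c("Actinobacteria", "Firmicutes", "Proteobacteria"),
       AD = c("Actinobacteria", "Firmicutes", "Proteobacteria"))
}

#' Spearman correlation of differentially abundant marker and SM-gene OTUs
#'
#' Restricts both tables to differentially abundant OTUs (bootstrap p below
#' `p_cutoff` for any tested factor), keeps marker OTUs whose genus has
#' mean relative abundance above `min_genus_abundance` and whose phylum is
#' admissible for the SM domain under the pairing rules, and computes
#' tie-corrected Spearman correlations across the shared samples.
#'
#' @param sm_results,marker_results `smdiv_diff` objects for the SM-gene
#'   and marker tables.
#' @param sm_table,marker_table The corresponding OTU tables.
#' @param marker_taxonomy Tibble: `otu_id`, `phylum`, `genus`.
#' @param sm_domain Domain of the SM table (`"ACP"`, `"KS"`,
#'   `"met-mal-CoA"`, `"AD"`).
#' @param p_cutoff Differential-abundance cutoff on unadjusted bootstrap p
#'   (default 0.05).
#' @param min_genus_abundance Minimum mean relative genus abundance
#'   (default 0.01).
#' @param pairing_rules See [default_pairing_rules()].
#' @return Long tibble: `otu_sm`, `otu_marker`, `genus`, `rho`, `p`.
#' @export
correlate_differential <- function(sm_results, marker_results,
                                   sm_table, marker_table, marker_taxonomy,
                                   sm_domain = "ACP",
                                   p_cutoff = 0.05,
                                   min_genus_abundance = 0.01,
                                   pairing_rules = default_pairing_rules()) {
  shared <- intersect(names(sm_table)[-1], names(marker_table)[-1])
  if (length(shared) < 3) abort("correlate_differential(): fewer than 3 shared samples")
  da_sm <- sm_results$per_otu |>
    filter(!is.na(.data$p_boot), .data$p_boot < p_cutoff) |>
    pull(.data$otu_id) |> unique()
  da_mk <- marker_results$per_otu |>
    filter(!is.na(.data$p_boot), .data$p_boot < p_cutoff) |>
    pull(.data$otu_id) |> unique()
  # genus relative-abundance filter on the marker table
  mk <- otu_matrix(marker_table)[, shared, drop = FALSE]
  rel <- sweep(mk, 2, pmax(colSums(mk), 1), "/")
  tax <- as_tibble(marker_taxonomy)
  genus_of <- setNames(tax$genus, tax$otu_id)
  phylum_of <- setNames(tax$phylum, tax$otu_id)
  gmean <- tapply(rowMeans(rel), genus_of[rownames(mk)], sum)
  good_genera <- names(gmean)[gmean > min_genus_abundance]
  allowed_phyla <- pairing_rules[[sm_domain]]
  if (is.null(allowed_phyla)) {
    abort(sprintf("correlate_differential(): no pairing rule for domain '%s'",
                  sm_domain))
  }
  mk_keep <- intersect(da_mk, rownames(mk))
  mk_keep <- mk_keep[genus_of[mk_keep] %in% good_genera &
                       phylum_of[mk_keep] %in% allowed_phyla]
  sm <- otu_matrix(sm_table)[, shared, drop = FALSE]
  sm_keep <- intersect(da_sm, rownames(sm))
  if (!length(sm_keep) || !length(mk_keep)) {
    return(tibble(otu_sm = character(), otu_marker = character(),
                  genus = character(), rho = numeric(), p = numeric()))
  }
  grid <- tidyr::expand_grid(otu_sm = sm_keep, otu_marker = mk_keep)
  grid |>
    mutate(res = purrr::map2(.data$otu_sm, .data$otu_marker, function(a, b) {
      ct <- suppressWarnings(
        stats::cor.test(sm[a, ], mk[b, ], method = "spearman", exact = FALSE))
      tibble(rho = unname(ct$estimate), p = ct$p.value)
    }),
    genus = unname(genus_of[.data$otu_marker])) |>
    tidyr::unnest("res") |>
    dplyr::select("otu_sm", "otu_marker", "genus", "rho", "p")
}
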