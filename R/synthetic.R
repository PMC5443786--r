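# Synthetic amplicon-community generator with known ground truth: gene
# families with controlled between-site overlap, lognormal abundances,
# stage-dependent shifts, exact primer binding sites, pyrosequencing-style
# errors (substitutions + homopolymer indels) and two-parent chimeras.

#' Specify a synthetic amplicon community
#'
#' The defaults mirror the surveyed study system: three sampling sites, two
#' vegetation stages (emergence, senescence), three biological replicates,
#' and an aggregate per-base error rate of 5% typical of 454
#' pyrosequencing. Family sequences carry exact binding sites for the
#' chosen primer pair flanking a random domain core.
#'
#' @param n_sites,n_stages,n_replicates Community layout (defaults 3/2/3).
#' @param n_families_per_site Gene families per site (default 50).
#' @param between_site_overlap Target effective-species overlap among sites
#'   in `[0, 1]` (default 0.3). `round(between_site_overlap *
#'   n_families_per_site)` families are shared by all sites; additional
#'   families shared by exactly two sites are added so that the
#'   alpha/gamma overlap statistic on true per-site family richness equals
#'   this value (see the package vignette for the algebra).
#' @param stage_shift Fraction of families whose abundance differs between
#'   stages (default 0.2).
#' @param stage_factor Fold-change applied to shifted families at
#'   senescence (their weight is divided by this; default 4).
#' @param abundance_mu,abundance_sigma Lognormal abundance parameters.
#' @param reads_per_sample Reads emitted per sample (default 300).
#' @param error_rate Aggregate per-base error rate (default 0.05).
#' @param homopolymer_indel_weight Fraction of errors realized as indels in
#'   homopolymer runs of length >= 3 (default 0.5).
#' @param chimera_rate Fraction of reads formed as two-parent chimeras
#'   (default 0).
#' @param amplicon_length Amplicon length including primers (default 200,
#'   the ACP-domain scale; ~700 for AD, ~1400 for the KS amplicon).
#' @param domain Primer pair to embed, one of `"ACP"`, `"AD"`, `"KS"`.
#' @param cluster_threshold Identity threshold the families are built to be
#'   recoverable at (default 0.95, i.e. 5% divergence).
#' @param margin Required identity gap between the threshold and the
#'   inter-family identity floor (default 0.15).
#' @param variants_per_family Within-family lineages (default 3).
#' @param seed Integer seed; fully determines all output.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_sites = 3, n_stages = 2, n_replicates = 3,
                           n_families_per_site = 50,
                           between_site_overlap = 0.3,
                           stage_shift = 0.2, stage_factor = 4,
                           abundance_mu = 0, abundance_sigma = 1,
                           reads_per_sample = 300,
                           error_rate = 0.05,
                           homopolymer_indel_weight = 0.5,
                           chimera_rate = 0,
                           amplicon_length = 200,
                           domain = c("ACP", "AD", "KS"),
                           cluster_threshold = 0.95,
                           margin = 0.15,
                           variants_per_family = 3,
                           seed = 1) {
  domain <- match.arg(domain)
  fr <- c(between_site_overlap = between_site_overlap,
          stage_shift = stage_shift, error_rate = error_rate,
          homopolymer_indel_weight = homopolymer_indel_weight,
          chimera_rate = chimera_rate)
  bad <- fr < 0 | fr > 1
  if (any(bad)) abort(sprintf("community_spec(): %s must be in [0,1]",
                              names(fr)[bad][1]))
  if (amplicon_length <= 0 || reads_per_sample < 0 || n_families_per_site < 1) {
    abort("community_spec(): lengths/counts must be positive")
  }
  spec <- as.list(environment())
  structure(spec, class = "community_spec")
}

# Site-membership design calibrated so that the alpha/gamma effective-
# species overlap statistic on true per-site family counts equals o.
# a = families shared by all N sites (= round(o*n) per the generator
# contract); b = per-site count of families shared by exactly two sites,
# solved from gamma = N*n / (1 + (N-1)*o).
site_design <- function(n, o, N) {
  a <- round(o * n)
  gamma_t <- N * n / (1 + (N - 1) * o)
  b0 <- 2 * (a + N * (n - a) - gamma_t) / N
  b <- max(0, 2 * round(b0 / 2))          # per-site pair participation, even
  if (a + b > n) b <- max(0, 2 * floor((n - a) / 2))
  c_ <- n - a - b
  list(all_shared = a, pair_per_site = b, private = c_)
}

#' Generate synthetic gene families with site membership
#'
#' Each family is an ancestral random domain core flanked by exact
#' (concretized) primer binding sites, diversified into
#' `variants_per_family` lineages by point mutations on a star phylogeny so
#' that within-family identity stays above `cluster_threshold` while
#' between-family identity stays below `cluster_threshold - margin`.
#'
#' @param spec A [community_spec()].
#' @return A list with `families` (tibble: `family_id`, `sites` list-column,
#'   `shifted`, `variants` list-column of sequences) and `membership`
#'   (tibble: `family_id`, `site`).
#' @export
generate_families <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  pp <- primer_pairs()
  pair <- pp[pp$domain == spec$domain, ]
  lf <- nchar(pair$forward); lr <- nchar(pair$reverse)
  core_len <- spec$amplicon_length - lf - lr
  if (core_len < 20) abort("generate_families(): amplicon_length too short for primers")
  # identity floor for unrelated cores: shared primers + ~55% residual
  # alignment identity of random DNA
  floor_est <- (lf + lr) / spec$amplicon_length +
    0.55 * core_len / spec$amplicon_length
  if (spec$cluster_threshold - spec$margin <= floor_est) {
    abort(sprintf(paste0("generate_families(): threshold - margin (%.2f) is not ",
                         "above the random-identity floor (~%.2f); increase the ",
                         "threshold or shorten the primers' share of the amplicon"),
                  spec$cluster_threshold - spec$margin, floor_est))
  }
  n <- spec$n_families_per_site
  N <- spec$n_sites
  sites <- paste0("P", seq_len(N))
  des <- site_design(n, spec$between_site_overlap, N)
  memberships <- list()
  # all-shared families
  for (i in seq_len(des$all_shared)) memberships[[length(memberships) + 1L]] <- sites
  # pair-shared families, cyclic over site pairs
  if (N >= 2 && des$pair_per_site > 0) {
    n_pair_fam <- N * des$pair_per_site / 2
    prs <- cbind(seq_len(N), c(seq_len(N)[-1], 1L))
    for (i in seq_len(n_pair_fam)) {
      k <- ((i - 1L) %% nrow(prs)) + 1L
      memberships[[length(memberships) + 1L]] <- sites[prs[k, ]]
    }
  }
  # private families
  for (s in sites) for (i in seq_len(des$private)) {
    memberships[[length(memberships) + 1L]] <- s
  }
  n_fam <- length(memberships)
  d_mut <- (1 - spec$cluster_threshold) / 4  # per-lineage mutation rate
  with_seed(derive_seed(spec$seed, "families"), {
    fwd_conc <- vapply(seq_len(n_fam), function(i)
      concretize_primer(pair$forward), character(1))
    rev_conc <- vapply(seq_len(n_fam), function(i)
      concretize_primer(pair$reverse), character(1))
    cores <- vapply(seq_len(n_fam), function(i) random_dna(core_len), character(1))
    variants <- lapply(seq_len(n_fam), function(i) {
      vapply(seq_len(spec$variants_per_family), function(v) {
        paste0(fwd_conc[i], point_mutate(cores[i], d_mut), revcomp(rev_conc[i]))
      }, character(1))
    })
    shifted_n <- round(spec$stage_shift * n_fam)
    shifted <- rep(FALSE, n_fam)
    if (shifted_n > 0) shifted[sample.int(n_fam, shifted_n)] <- TRUE
  })
  fams <- tibble(
    family_id = sprintf("fam%04d", seq_len(n_fam)),
    sites = memberships,
    shifted = shifted,
    variants = variants)
  membership <- fams |>
    dplyr::select("family_id", "sites") |>
    tidyr::unnest_longer("sites", values_to = "site") |>
    rename(site = "site")
  structure(list(families = fams, membership = membership, spec = spec),
            class = "smdiv_families")
}

# pick one concrete expansion of a degenerate primer uniformly at random
concretize_primer <- function(primer) {
  ch <- check_iupac(primer)
  paste(vapply(IUPAC_MAP[ch], function(s)
    if (length(s) == 1L) s else sample(s, 1L), character(1)), collapse = "")
}

point_mutate <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

# 454-style per-base errors: substitutions plus indels restricted to
# homopolymer runs of length >= 3
apply_read_errors <- function(seq, error_rate, hp_weight) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_err <- rbinom(1, length(ch), error_rate)
  if (n_err == 0) return(seq)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  hp_pos <- unlist(mapply(function(len, end) {
    if (len >= 3) (end - len + 1L):end else integer(0)
  }, r$lengths, ends, SIMPLIFY = FALSE), use.names = FALSE)
  for (e in seq_len(n_err)) {
    as_indel <- length(hp_pos) > 0 && runif(1) < hp_weight
    if (as_indel) {
      p <- sample(hp_pos, 1L)
      p <- min(p, length(ch))
      if (runif(1) < 0.5) {
        ch <- append(ch, ch[p], after = p)      # duplicate within the run
      } else if (length(ch) > 1) {
        ch <- ch[-p]
      }
      # positions drift after an indel; refresh run index cheaply
      r <- rle(ch); ends <- cumsum(r$lengths)
      hp_pos <- unlist(mapply(function(len, end) {
        if (len >= 3) (end - len + 1L):end else integer(0)
      }, r$lengths, ends, SIMPLIFY = FALSE), use.names = FALSE)
    } else {
      p <- sample.int(length(ch), 1L)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Sample reads from generated families
#'
#' Per sample, family abundances are lognormal draws (per family and site)
#' normalized to probabilities; shifted families have their weight divided
#' by `stage_factor` at senescence. Reads are exact copies of a uniformly
#' chosen family lineage, optionally chimerized (two distinct same-sample
#' parents joined at a uniform interior breakpoint) and then subjected to
#' the error model.
#'
#' @param spec A [community_spec()].
#' @param families Output of [generate_families()]; generated if missing.
#' @return A list with `reads` (tibble: `id`, `sequence`, `quality`,
#'   `sample_id`), `truth` (tibble: `read_id`, `family_id`, `family_id2`,
#'   `site`, `stage`, `replicate`, `is_chimera`), `metadata` (sample
#'   metadata with barcodes) and `families`.
#' @export
sample_reads <- function(spec, families = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.null(families)) families <- generate_families(spec)
  fams <- families$families
  sites <- paste0("P", seq_len(spec$n_sites))
  stages <- c("emergence", "senescence")[seq_len(spec$n_stages)]
  metadata <- tidyr::expand_grid(site = sites, stage = stages,
                                 replicate = seq_len(spec$n_replicates)) |>
    mutate(sample_id = sprintf("%s_%s_%d", .data$site, .data$stage,
                               .data$replicate))
  with_seed(derive_seed(spec$seed, "barcodes"), {
    repeat {
      bc <- vapply(seq_len(nrow(metadata)), function(i) random_dna(10),
                   character(1))
      if (!anyDuplicated(bc)) break
    }
  })
  metadata$barcode <- bc
  metadata <- metadata[, c("sample_id", "site", "stage", "replicate", "barcode")]
  # per family-site lognormal base weights
  with_seed(derive_seed(spec$seed, "abundance"), {
    w_tab <- families$membership |>
      mutate(w = rlnorm(dplyr::n(), spec$abundance_mu, spec$abundance_sigma))
  })
  if (spec$reads_per_sample == 0) {
    warn("sample_reads(): reads_per_sample = 0; all samples are empty")
  }
  reads_list <- list(); truth_list <- list()
  for (si in seq_len(nrow(metadata))) {
    srow <- metadata[si, ]
    fam_here <- w_tab |> filter(.data$site == srow$site) |>
      left_join(fams[, c("family_id", "shifted", "variants")], by = "family_id")
    w <- fam_here$w
    if (srow$stage == "senescence") {
      w[fam_here$shifted] <- w[fam_here$shifted] / spec$stage_factor
    }
    if (spec$reads_per_sample == 0) next
    with_seed(derive_seed(spec$seed, paste0("reads_", srow$sample_id)), {
      counts <- as.vector(stats::rmultinom(1, spec$reads_per_sample, w / sum(w)))
      fam_idx <- rep(seq_len(nrow(fam_here)), counts)
      n_reads <- length(fam_idx)
      is_chi <- runif(n_reads) < spec$chimera_rate & nrow(fam_here) >= 2
      seqs <- character(n_reads); fam2 <- rep(NA_character_, n_reads)
      for (k in seq_len(n_reads)) {
        f1 <- fam_idx[k]
        v1 <- sample(fam_here$variants[[f1]], 1L)
        if (is_chi[k]) {
          f2 <- sample(setdiff(seq_len(nrow(fam_here)), f1), 1L,
                       prob = (w / sum(w))[setdiff(seq_len(nrow(fam_here)), f1)])
          v2 <- sample(fam_here$variants[[f2]], 1L)
          L <- min(nchar(v1), nchar(v2))
          b <- sample(seq(30L, L - 30L), 1L)
          seqs[k] <- paste0(substr(v1, 1, b), substr(v2, b + 1, nchar(v2)))
          fam2[k] <- fam_here$family_id[f2]
        } else {
          seqs[k] <- v1
        }
        seqs[k] <- apply_read_errors(seqs[k], spec$error_rate,
                                     spec$homopolymer_indel_weight)
      }
      quals <- lapply(nchar(seqs), function(L) sample(30:40, L, replace = TRUE))
    })
    ids <- sprintf("%s_r%05d", srow$sample_id, seq_along(seqs))
    reads_list[[si]] <- tibble(id = ids, sequence = seqs, quality = quals,
                               sample_id = srow$sample_id)
    truth_list[[si]] <- tibble(read_id = ids,
                               family_id = fam_here$family_id[fam_idx],
                               family_id2 = fam2,
                               site = srow$site, stage = srow$stage,
                               replicate = srow$replicate,
                               is_chimera = is_chi)
  }
  reads <- bind_rows(reads_list)
  truth <- bind_rows(truth_list)
  smdiv_log("sample_reads: %d reads across %d samples", nrow(reads),
            nrow(metadata))
  list(reads = reads, truth = truth, metadata = metadata,
       families = families)
}

#' Pool per-sample reads into a barcoded multiplexed read set
#'
#' Prepends each sample's 10-nt barcode to its reads (the amplicons already
#' start with the forward primer), emulating the multiplexed pool that
#' [demultiplex()] re-splits.
#'
#' @param reads Read tibble from [sample_reads()].
#' @param metadata Metadata with `sample_id` and `barcode`.
#' @return Read tibble with barcoded sequences and no `sample_id`.
#' @export
pool_reads <- function(reads, metadata) {
  bc <- setNames(metadata$barcode, metadata$sample_id)
  tibble(
    id = reads$id,
    sequence = paste0(bc[reads$sample_id], reads$sequence),
    quality = purrr::map2(reads$sample_id, reads$quality,
                          function(s, q) c(rep(38L, 10L), q)))
}

#' One-call synthetic community simulation
#'
#' @param spec A [community_spec()].
#' @return See [sample_reads()].
#' @export
simulate_community <- function(spec) sample_reads(spec)
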