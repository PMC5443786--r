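# End-to-end orchestration: simulate (or load) -> prep -> cluster ->
# diversity -> sharing -> phylo -> stats -> annotate, with a per-stage
# record-count manifest.

#' Build and validate a pipeline configuration
#'
#' Either supply `reads_fastq` + `metadata_tsv` for real data, or leave
#' them `NULL` to simulate a community from `spec`. All stochastic stages
#' derive their seeds from `seed`.
#'
#' @param outdir Output directory (created if needed).
#' @param spec A [community_spec()] used when simulating.
#' @param reads_fastq,metadata_tsv Optional input paths (pooled barcoded
#'   FASTQ and sample metadata TSV); validated at config time.
#' @param domain Primer pair / domain label (`"ACP"`, `"AD"`, `"KS"`).
#' @param cluster_thresholds Identity thresholds for the multi-threshold
#'   clustering report.
#' @param otu_threshold Threshold for the ordination/GLM OTU table
#'   (default 0.97).
#' @param phylo_threshold Threshold for representative picking and the NJ
#'   tree (default 0.85).
#' @param diversity_threshold Threshold for richness/overlap estimates
#'   (default 0.95, i.e. 5% divergence).
#' @param q_cutoff,q_window Quality-filter parameters.
#' @param min_size Dereplication minimum duplicate count (default 2).
#' @param abundance_skew Chimera abundance-skew parameter (default 1.9).
#' @param min_replicates Replicate-consistency cutoff (default 2).
#' @param n_boot Bootstrap resamples for the differential test
#'   (default 199).
#' @param seed Global seed.
#' @return A validated `smdiv_config` list.
#' @export
pipeline_config <- function(outdir,
                            spec = community_spec(),
                            reads_fastq = NULL, metadata_tsv = NULL,
                            domain = spec$domain,
                            cluster_thresholds = c(0.75, 0.85, 0.90, 0.97),
                            otu_threshold = 0.97,
                            phylo_threshold = 0.85,
                            diversity_threshold = 0.95,
                            q_cutoff = 20, q_window = 50,
                            min_size = 2, abundance_skew = 1.9,
                            min_replicates = 2, n_boot = 199,
                            seed = 1) {
  for (p in c(reads_fastq, metadata_tsv)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("pipeline_config(): input path does not exist: %s", p))
    }
  }
  cfg <- as.list(environment())
  structure(cfg, class = "smdiv_config")
}

#' Run the full pipeline
#'
#' Executes the stages in fixed order, writes stage outputs (FASTA/FASTQ,
#' OTU tables, TSV reports, Newick tree) under `config$outdir`, and
#' records input/output record counts per stage in `manifest.tsv`. Reruns
#' with identical config and seed reproduce identical output files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results plus the
#'   `manifest` tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "smdiv_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out)
  }
  out <- list()
  pair <- primer_pairs()
  pair <- pair[pair$domain == config$domain, ]
  # clustering results are reused across stages that share a threshold
  cl_cache <- new.env(parent = emptyenv())
  cluster_at <- function(x, th) {
    key <- sprintf("%.6f", th)
    if (is.null(cl_cache[[key]])) cl_cache[[key]] <- greedy_cluster(x, th)
    cl_cache[[key]]
  }

  # -- stage 1: simulate or load ------------------------------------------
  if (is.null(config$reads_fastq)) {
    sim <- simulate_community(config$spec)
    pooled <- pool_reads(sim$reads, sim$metadata)
    metadata <- sim$metadata
    write_fastq(pooled, file.path(config$outdir, "reads.fastq"))
    write_metadata(metadata, file.path(config$outdir, "metadata.tsv"))
    utils::write.table(sim$truth, file.path(config$outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$truth <- sim$truth
    note("simulate", NA_integer_, nrow(pooled))
  } else {
    pooled <- read_fastq(config$reads_fastq)
    metadata <- read_metadata(config$metadata_tsv)
    note("load", NA_integer_, nrow(pooled))
  }
  out$metadata <- metadata

  # -- stage 2: seqprep ----------------------------------------------------
  qf <- quality_filter(pooled, config$q_cutoff, config$q_window)
  note("quality_filter", nrow(pooled), nrow(qf))
  dm <- demultiplex(qf, metadata, forward_primer = pair$forward)
  dm <- dm[dm$sample_id != "unassigned", ]
  note("demultiplex", nrow(qf), nrow(dm))
  dr <- dereplicate(dm, min_size = config$min_size)
  note("dereplicate", nrow(dm), nrow(dr))
  ch <- flag_chimeras(dr, abundance_skew = config$abundance_skew)
  note("flag_chimeras", nrow(dr), nrow(ch$clean))
  tr <- trim_to_common_length(ch$clean)
  note("trim", nrow(ch$clean), nrow(tr))
  out$uniques <- tr
  write_fasta(dplyr::transmute(tr, id = sprintf("%s;size=%d", .data$id,
                                                .data$size),
                               sequence = .data$sequence),
              file.path(config$outdir, "uniques.fasta"))

  # -- stage 3: clustering -------------------------------------------------
  out$cluster_counts <- purrr::map(config$cluster_thresholds, function(th) {
    tibble(threshold = th, clusters = n_clusters(cluster_at(tr, th)))
  }) |> bind_rows()
  utils::write.table(out$cluster_counts,
                     file.path(config$outdir, "cluster_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl_otu <- cluster_at(tr, config$otu_threshold)
  otu_tab <- build_otu_table(cl_otu)
  write_otu_table(otu_tab, file.path(config$outdir, "otu_table.tsv"))
  out$otu_table <- otu_tab
  note("cluster", nrow(tr), nrow(otu_tab))

  # -- stage 4: diversity --------------------------------------------------
  cl_div <- cluster_at(tr, config$diversity_threshold)
  div_tab <- build_otu_table(cl_div)
  site_tabs <- split_table_by_site(div_tab, metadata)
  site_mass <- vapply(site_tabs, function(t)
    sum(as.matrix(t[, -1, drop = FALSE])), numeric(1))
  if (any(site_mass == 0)) {
    smdiv_log("diversity: empty site table(s) after filtering; stage skipped")
  }
  if (length(site_tabs) >= 2 && all(site_mass > 0)) {
    out$diversity <- site_overlap_report(site_tabs)
    div_out <- bind_rows(out$diversity$per_site, out$diversity$pooled) |>
      mutate(overlap_pct = out$diversity$overlap_pct)
    utils::write.table(div_out, file.path(config$outdir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("diversity", nrow(div_tab), NA_integer_)

  # -- stage 5: sharing ----------------------------------------------------
  out$site_sharing <- site_sharing_report(
    tr, metadata, thresholds = c(0.97, 0.90, 0.85),
    min_replicates = config$min_replicates, cluster_fn = cluster_at)
  utils::write.table(out$site_sharing,
                     file.path(config$outdir, "site_sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("sharing", nrow(otu_tab), nrow(out$site_sharing))

  # -- stage 6: phylogeny --------------------------------------------------
  cl_ph <- cluster_at(tr, config$phylo_threshold)
  reps <- pick_representatives(cl_ph, metadata)
  write_fasta(reps[, c("id", "sequence")],
              file.path(config$outdir, "representatives.fasta"))
  if (nrow(reps) >= 3) {
    D <- distance_matrix(tibble(id = reps$cluster_id, sequence = reps$sequence))
    tree <- neighbor_joining(D)
    write_newick(tree, path = file.path(config$outdir, "tree.nwk"))
    out$tree <- tree
  }
  note("phylo", nrow(cl_ph), nrow(reps))

  # -- stage 7: statistics -------------------------------------------------
  if (ncol(otu_tab) - 1 >= 3 && nrow(otu_tab) >= 2) {
    D_bc <- bray_curtis_matrix(otu_tab)
    out$ordination <- nmds(D_bc, seed = derive_seed(config$seed, "nmds"))
    utils::write.table(tidy(out$ordination),
                       file.path(config$outdir, "nmds_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$differential <- fit_differential(
      otu_tab, metadata, factors = intersect(c("site", "stage"),
                                             names(metadata)),
      n_boot = config$n_boot, seed = derive_seed(config$seed, "glm"))
    utils::write.table(tidy(out$differential),
                       file.path(config$outdir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("stats", nrow(otu_tab), NA_integer_)

  # -- stage 8: annotation -------------------------------------------------
  cl_100 <- cluster_at(tr, 1.0)
  reps100 <- pick_representatives(cl_100)
  ann <- assign_functions(tibble(id = reps100$cluster_id,
                                 sequence = reps100$sequence))
  out$annotation <- ann
  utils::write.table(ann$assignments,
                     file.path(config$outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$summary, file.path(config$outdir, "annotation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("annotate", nrow(reps100), ann$summary$n_passing)

  out$manifest <- bind_rows(manifest)
  utils::write.table(out$manifest, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
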