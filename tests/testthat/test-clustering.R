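test_that("pairwise identity is 1 for identical sequences and symmetric", {
  s <- random_dna_str(50)
  expect_equal(pairwise_identity(s, s), 1)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  set.seed(8)
  for (i in 1:15) {
    a <- random_dna_str(sample(20:40, 1))
    b <- random_dna_str(sample(20:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("alignment identity agrees with the exhaustive DP oracle on short pairs", {
  set.seed(9)
  for (i in 1:12) {
    a <- random_dna_str(sample(4:8, 1))
    b <- random_dna_str(sample(4:8, 1))
    got <- pairwise_identity(a, b)
    opt <- oracle_optimal_identities(a, b)
    expect_true(any(abs(opt - got) < 1e-9),
                info = sprintf("%s vs %s: got %.4f, optimal {%s}", a, b, got,
                               paste(round(opt, 4), collapse = ", ")))
  }
})

test_that("scattered substitutions give the expected ungapped identity", {
  set.seed(10)
  pr <- mutated_pair(100, 20)
  expect_equal(pairwise_identity(pr$a, pr$b), 0.80)
  pr2 <- mutated_pair(150, 15)
  expect_equal(pairwise_identity(pr2$a, pr2$b), 0.90)
})

test_that("greedy clustering separates and merges at the right thresholds", {
  set.seed(11)
  pr <- mutated_pair(100, 20)  # verified identity 0.80
  seqs <- tibble::tibble(id = c("x", "y"), sequence = c(pr$a, pr$b),
                         size = c(5L, 3L))
  expect_equal(n_clusters(greedy_cluster(seqs, 0.75)), 1L)
  expect_equal(n_clusters(greedy_cluster(seqs, 0.85)), 2L)
  # duplicates only -> one cluster
  dup <- tibble::tibble(id = c("a", "b", "c"), sequence = rep(pr$a, 3))
  cl <- greedy_cluster(dup, 0.97)
  expect_equal(n_clusters(cl), 1L)
  # the centroid is the first in (size desc, length desc, id asc) order
  expect_equal(unique(cl$centroid_id), "a")
})

test_that("cluster count is non-increasing as the threshold drops", {
  sim <- simulate_community(
    community_spec(n_families_per_site = 8, reads_per_sample = 60,
                   error_rate = 0.03, seed = 31))
  dr <- dereplicate(sim$reads[sim$reads$sample_id == "P1_emergence_1", ],
                    min_size = 1)
  counts <- sapply(c(0.97, 0.90, 0.85, 0.75), function(th)
    n_clusters(greedy_cluster(dr, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("error-free clustering recovers the exact planted family count", {
  sp <- community_spec(n_families_per_site = 12, reads_per_sample = 100,
                       error_rate = 0, seed = 17)
  sim <- simulate_community(sp)
  for (s in c("P1_emergence_1", "P2_senescence_3")) {
    rd <- sim$reads[sim$reads$sample_id == s, ]
    truth_n <- length(unique(sim$truth$family_id[sim$truth$read_id %in% rd$id]))
    cl <- greedy_cluster(dereplicate(rd, min_size = 1), sp$cluster_threshold)
    expect_equal(n_clusters(cl), truth_n, info = s)
  }
})

test_that("OTU tables sum member sizes per sample and conserve read mass", {
  uni <- tibble::tibble(
    id = c("u1", "u2"), sequence = c(strrep("A", 30), strrep("A", 30)),
    size = c(3L, 2L),
    samples = list(c(s1 = 3L), c(s2 = 2L)))
  cl <- greedy_cluster(uni, 0.97)
  tab <- build_otu_table(cl)
  expect_equal(nrow(tab), 1L)
  expect_equal(unlist(tab[1, c("s1", "s2")], use.names = FALSE), c(3L, 2L))
  expect_equal(nrow(build_otu_table(cl[0, ])), 0L)
  # conservation on simulated data
  sim <- simulate_community(
    community_spec(n_families_per_site = 6, reads_per_sample = 40,
                   error_rate = 0, seed = 23))
  dr <- dereplicate(sim$reads, min_size = 1)
  tab2 <- build_otu_table(greedy_cluster(dr, 0.95))
  per_sample <- colSums(as.matrix(tab2[, -1]))
  expected <- table(sim$reads$sample_id)
  expect_equal(per_sample[names(expected)], c(expected)[names(per_sample)],
               ignore_attr = TRUE)
})

test_that("representatives carry size and majority annotations and round-trip", {
  md <- toy_metadata(n_sites = 2, n_stages = 2, n_reps = 1)
  uni <- tibble::tibble(
    id = c("u1", "u2", "u3"),
    sequence = c(random_dna_str(60), random_dna_str(60), random_dna_str(60)),
    size = c(4L, 3L, 2L),
    samples = list(c(P1_emergence_1 = 4L),
                   c(P2_senescence_1 = 3L),
                   c(P1_emergence_1 = 1L, P2_senescence_1 = 1L)))
  cl <- greedy_cluster(uni, 0.97)
  reps <- pick_representatives(cl, md)
  expect_equal(nrow(reps), 3L)
  expect_match(reps$id[1], "size=\\d+;site=P\\d;stage=")
  # equal masses tie-break to the first site/stage label
  tied <- reps[grepl("u3", reps$cluster_id) | reps$sequence == uni$sequence[3], ]
  expect_match(reps$id[reps$sequence == uni$sequence[3]],
               "site=P1;stage=emergence")
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reps[, c("id", "sequence")], p)
  expect_equal(read_fasta(p)$id, reps$id)
})

test_that("query/reference shared-cluster counts partition the total", {
  set.seed(12)
  # disjoint toy sets: random 60-mers never reach 75% identity
  q <- tibble::tibble(id = paste0("q", 1:3),
                      sequence = replicate(3, random_dna_str(60)))
  r <- tibble::tibble(id = paste0("r", 1:3),
                      sequence = replicate(3, random_dna_str(60)))
  sh <- shared_with_reference(q, r, thresholds = c(0.75, 0.9))
  expect_true(all(sh$shared == 0))
  expect_true(all(sh$query_only + sh$reference_only + sh$shared == sh$total))
  # identical sequences in both sets leave no query-only clusters
  sh2 <- shared_with_reference(q, q, thresholds = c(0.9))
  expect_equal(sh2$query_only, 0L)
  expect_equal(sh2$reference_only, 0L)
  expect_equal(sh2$shared, 3L)
  # planted shared families: references built from k of the query families
  sp <- community_spec(n_families_per_site = 6, between_site_overlap = 1,
                       reads_per_sample = 50, error_rate = 0, seed = 41)
  fam <- generate_families(sp)
  k <- 3
  refs <- tibble::tibble(
    id = paste0("ref", seq_len(k)),
    sequence = vapply(fam$families$variants[seq_len(k)], `[[`, character(1), 1))
  sim <- sample_reads(sp, fam)
  qry <- dereplicate(sim$reads[sim$reads$sample_id == "P1_emergence_1", ],
                     min_size = 1)
  sh3 <- shared_with_reference(qry, refs, thresholds = sp$cluster_threshold)
  expect_equal(sh3$shared, k)
})
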