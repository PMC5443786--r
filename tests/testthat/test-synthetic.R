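small_spec <- function(reads_per_sample = 60, error_rate = 0,
                       chimera_rate = 0, seed = 99, ...) {
  community_spec(n_families_per_site = 10,
                 reads_per_sample = reads_per_sample,
                 error_rate = error_rate, chimera_rate = chimera_rate,
                 seed = seed, ...)
}

test_that("spec validation rejects out-of-range parameters", {
  expect_error(community_spec(between_site_overlap = 1.2), "\\[0,1\\]")
  expect_error(community_spec(error_rate = -0.1), "\\[0,1\\]")
  expect_error(community_spec(amplicon_length = 0), "positive")
  # a threshold too close to the random-identity floor is infeasible
  expect_error(generate_families(small_spec(cluster_threshold = 0.70,
                                            margin = 0.15)),
               "floor")
})

test_that("site membership honours the overlap parameter", {
  fam1 <- generate_families(small_spec(between_site_overlap = 1))
  expect_true(all(lengths(fam1$families$sites) == 3))
  fam0 <- generate_families(small_spec(between_site_overlap = 0))
  expect_true(all(lengths(fam0$families$sites) == 1))
  per_site <- table(fam0$membership$site)
  expect_true(all(per_site == 10))
  fam3 <- generate_families(small_spec(between_site_overlap = 0.3))
  expect_equal(sum(lengths(fam3$families$sites) == 3), 3)  # round(0.3 * 10)
  expect_true(all(table(fam3$membership$site) == 10))
})

test_that("generated families are recoverable at the build threshold", {
  sp <- small_spec()
  fam <- generate_families(sp)
  # within-family identity above, between-family identity below threshold
  v <- fam$families$variants[[1]]
  expect_true(all(sapply(2:length(v), function(i)
    pairwise_identity(v[1], v[i])) > sp$cluster_threshold))
  other <- fam$families$variants[[2]][1]
  expect_lt(pairwise_identity(v[1], other),
            sp$cluster_threshold - sp$margin)
  # exact primer binding sites flank every variant
  acp <- primer_pairs()[primer_pairs()$domain == "ACP", ]
  amp <- extract_amplicons(acp, c(x = v[1]))
  expect_equal(nrow(amp), 1L)
  expect_equal(nchar(amp$amplicon), nchar(v[1]))
})

test_that("identical spec and seed give byte-identical output", {
  s1 <- simulate_community(small_spec())
  s2 <- simulate_community(small_spec())
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_community(small_spec(seed = 100))
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("error-free reads are exact family-lineage copies with full truth", {
  sim <- simulate_community(small_spec())
  expect_equal(nrow(sim$reads), nrow(sim$truth))       # truth conservation
  expect_equal(nrow(sim$reads), 60 * 18)
  fam <- sim$families$families
  var_by_fam <- setNames(fam$variants, fam$family_id)
  ok <- mapply(function(s, f) s %in% var_by_fam[[f]],
               sim$reads$sequence,
               sim$truth$family_id[match(sim$reads$id, sim$truth$read_id)])
  expect_true(all(ok))
  expect_false(any(sim$truth$is_chimera))
})

test_that("chimera_rate = 1 marks every read as chimeric", {
  sim <- simulate_community(small_spec(chimera_rate = 1))
  expect_true(all(sim$truth$is_chimera))
  expect_true(all(!is.na(sim$truth$family_id2)))
  expect_true(all(sim$truth$family_id != sim$truth$family_id2))
})

test_that("zero read depth warns and yields an empty sample set", {
  expect_warning(sim <- simulate_community(small_spec(reads_per_sample = 0)),
                 "empty")
  expect_equal(nrow(sim$reads), 0L)
})

test_that("errors change sequences at roughly the requested rate", {
  sp <- small_spec(error_rate = 0.05, reads_per_sample = 30)
  sim <- simulate_community(sp)
  fam <- sim$families$families
  var_by_fam <- setNames(fam$variants, fam$family_id)
  exact <- mapply(function(s, f) s %in% var_by_fam[[f]],
                  sim$reads$sequence,
                  sim$truth$family_id[match(sim$reads$id, sim$truth$read_id)])
  # P(no error in a 200 bp read) at 5%/base is essentially zero
  expect_lt(mean(exact), 0.05)
})

test_that("pooled reads carry the sample barcode and demultiplex back", {
  sim <- simulate_community(small_spec(reads_per_sample = 20))
  pooled <- pool_reads(sim$reads, sim$metadata)
  expect_true(all(nchar(pooled$sequence) == nchar(sim$reads$sequence) + 10))
  dm <- demultiplex(pooled, sim$metadata)
  expect_equal(dm$sample_id, sim$reads$sample_id)
})

test_that("overlap statistic on true family counts recovers the overlap dial", {
  for (o in c(0, 0.25, 0.5, 0.75, 1)) {
    sp <- community_spec(n_families_per_site = 50, between_site_overlap = o,
                         seed = 5)
    fam <- generate_families(sp)
    alphas <- as.numeric(table(fam$membership$site))
    est <- overlap_statistic(alphas, nrow(fam$families))
    expect_lt(abs(est - o), 0.05)
  }
})
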