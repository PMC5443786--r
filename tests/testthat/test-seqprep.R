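test_that("rolling-window quality truncation follows its stated rule", {
  r_good <- make_reads(random_dna_str(100))
  expect_equal(quality_filter(r_good)$sequence, r_good$sequence)
  r_bad <- make_reads(random_dna_str(100),
                      quals = list(rep(10L, 100)))
  expect_equal(nrow(quality_filter(r_bad)), 0L)
  # 200 bp, Q40 for 150 then Q0: cut per an independent simulation of the
  # rolling mean (truncate just before the first failing window's start)
  q <- c(rep(40L, 150), rep(0L, 50))
  expected <- {
    keep <- 200L
    for (j in 1:(200 - 50 + 1)) {
      if (mean(q[j:(j + 49)]) < 20) { keep <- j - 1L; break }
    }
    keep
  }
  r <- make_reads(random_dna_str(200), quals = list(q))
  out <- quality_filter(r)
  expect_equal(nchar(out$sequence), expected)
  expect_equal(expected, 126L)
  # ambiguous bases cause removal; missing qualities error
  r_amb <- make_reads(paste0(random_dna_str(99), "N"))
  expect_equal(nrow(quality_filter(r_amb)), 0L)
  expect_error(quality_filter(tibble::tibble(id = "x", sequence = "ACGT")),
               "quality")
})

test_that("demultiplexing assigns by exact barcode and clips barcode+primer", {
  md <- toy_metadata(n_sites = 2, n_stages = 1, n_reps = 1)
  md$barcode <- c("AAAAAAAAAA", "CCCCCCCCCC")
  primer <- "ACGTAC"
  insert <- random_dna_str(40)
  reads <- make_reads(c(paste0("AAAAAAAAAA", primer, insert),
                        paste0("CCCCCCCCCC", primer, insert),
                        paste0("GGGGGGGGGG", primer, insert)))
  dm <- demultiplex(reads, md, forward_primer = primer)
  expect_equal(dm$sample_id,
               c(md$sample_id[1], md$sample_id[2], "unassigned"))
  expect_equal(dm$sequence[1], insert)
  expect_equal(length(dm$quality[[1]]), nchar(insert))
  # swapping barcodes swaps assignments
  md_sw <- md; md_sw$barcode <- rev(md_sw$barcode)
  dm_sw <- demultiplex(reads, md_sw, forward_primer = primer)
  expect_equal(dm_sw$sample_id[1:2], rev(dm$sample_id[1:2]))
  md_dup <- md; md_dup$barcode <- rep("AAAAAAAAAA", 2)
  expect_error(demultiplex(reads, md_dup), "duplicate")
})

test_that("dereplication groups exact sequences and drops rare uniques", {
  reads <- make_reads(c("ACGT", "ACGT", "ACGA"))
  dr <- dereplicate(reads, min_size = 2)
  expect_equal(dr$sequence, "ACGT")
  expect_equal(dr$size, 2L)
  expect_equal(nrow(dereplicate(make_reads(c("AA", "CC", "GG")), 2)), 0L)
  dr1 <- dereplicate(make_reads(c("AA", "CC", "GG")), min_size = 1)
  expect_equal(sort(dr1$sequence), c("AA", "CC", "GG"))
  expect_true(all(dr1$size == 1L))
  # per-sample bookkeeping survives pooled dereplication
  reads2 <- make_reads(rep("ACGT", 3), sample_id = c("s1", "s1", "s2"))
  dr2 <- dereplicate(reads2, min_size = 1)
  expect_equal(dr2$samples[[1]], c(s1 = 2L, s2 = 1L))
})

test_that("two-parent chimeras are flagged, parents and originals are not", {
  set.seed(3)
  a <- random_dna_str(200); b <- random_dna_str(200)
  chi <- paste0(substr(a, 1, 100), substr(b, 101, 200))
  uni <- tibble::tibble(id = c("A", "B", "chi"),
                        sequence = c(a, b, chi),
                        size = c(50L, 40L, 3L))
  fc <- flag_chimeras(uni)
  expect_equal(fc$flagged$id, "chi")
  expect_setequal(c(fc$flagged$parent_a, fc$flagged$parent_b), c("A", "B"))
  # a read identical to a parent is never flagged
  uni2 <- tibble::tibble(id = c("A", "B", "dup"),
                         sequence = c(a, b, a), size = c(50L, 40L, 2L))
  expect_equal(nrow(flag_chimeras(uni2)$flagged), 0L)
  # no candidate parents above the abundance skew -> not flagged
  uni3 <- tibble::tibble(id = c("A", "B", "chi"),
                         sequence = c(a, b, chi), size = c(4L, 4L, 3L))
  expect_equal(nrow(flag_chimeras(uni3)$flagged), 0L)
})

test_that("chimera flagging attains high recall and low FPR on generator output", {
  recalls <- c(); fprs <- c()
  for (seed in c(11, 13)) {
    sp <- community_spec(n_families_per_site = 15, reads_per_sample = 400,
                         error_rate = 0, chimera_rate = 0.2, seed = seed)
    sim <- simulate_community(sp)
    rd <- sim$reads[sim$reads$sample_id == "P1_emergence_1", ]
    tru <- sim$truth[sim$truth$read_id %in% rd$id, ]
    dr <- dereplicate(rd, min_size = 1)
    is_chi <- setNames(tru$is_chimera, tru$read_id)
    seq2chi <- tapply(is_chi[rd$id], rd$sequence, function(v) mean(v) > 0.5)
    fc <- flag_chimeras(dr)
    truth_u <- seq2chi[dr$sequence]
    flagged <- dr$id %in% fc$flagged$id
    recalls <- c(recalls, sum(flagged & truth_u) / sum(truth_u))
    fprs <- c(fprs, sum(flagged & !truth_u) / sum(!truth_u))
  }
  expect_true(all(recalls >= 0.9))
  expect_true(all(fprs <= 0.05))
})

test_that("common-length trimming applies the floor then the minimum", {
  r <- make_reads(c(random_dna_str(210), random_dna_str(205),
                    random_dna_str(207)))
  out <- trim_to_common_length(r)
  expect_true(all(nchar(out$sequence) == 205))
  one <- make_reads(random_dna_str(99))
  expect_equal(trim_to_common_length(one)$sequence, one$sequence)
  r2 <- make_reads(c(random_dna_str(150), random_dna_str(210),
                     random_dna_str(220)))
  out2 <- trim_to_common_length(r2, floor_len = 200)
  expect_equal(nrow(out2), 2L)
  expect_true(all(nchar(out2$sequence) == 210))
})

test_that("read mass is non-increasing through the prep pipeline", {
  sp <- community_spec(n_families_per_site = 8, reads_per_sample = 80,
                       error_rate = 0.02, chimera_rate = 0.05, seed = 21)
  sim <- simulate_community(sp)
  pooled <- pool_reads(sim$reads, sim$metadata)
  mass <- nrow(pooled)
  qf <- quality_filter(pooled)
  expect_lte(nrow(qf), mass)
  dm <- demultiplex(qf, sim$metadata)
  dm <- dm[dm$sample_id != "unassigned", ]
  expect_lte(nrow(dm), nrow(qf))
  dr <- dereplicate(dm, min_size = 2)
  expect_lte(sum(dr$size), nrow(dm))
  fc <- flag_chimeras(dr)
  expect_lte(sum(fc$clean$size), sum(dr$size))
  tr <- trim_to_common_length(fc$clean, floor_len = 100)
  expect_lte(sum(tr$size), sum(fc$clean$size))
})
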