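test_that("degenerate expansion matches IUPAC semantics", {
  expect_equal(expand_degenerate("ACGT"), "ACGT")
  expect_equal(expand_degenerate("AR"), c("AA", "AG"))
  expect_error(expand_degenerate("ACX"), "position 3")
  a3 <- primer_pairs()$forward[1]
  expect_equal(length(expand_degenerate(a3)), 128)
  expect_equal(expand_degenerate(a3), enumerate_primer(a3))
})

test_that("degeneracy equals enumeration size without materializing", {
  expect_equal(degeneracy("NN"), 16)
  expect_equal(degeneracy("GCNGGNCAYWSNYTNGGNGARTAYA"), 65536)
  # per-position product cross-checked by enumerating a truncated prefix
  expect_equal(degeneracy("GCNGGNCAYWS"),
               length(enumerate_primer("GCNGGNCAYWS")))
  # the K1 primer has S, S, B as its only degenerate positions
  expect_equal(degeneracy("TSAAGTCSAACATCGGBCA"), 12)
  expect_equal(degeneracy("TSAAGTCSAACATCGGBCA"),
               length(enumerate_primer("TSAAGTCSAACATCGGBCA")))
  set.seed(42)
  for (i in 1:20) {
    p <- random_iupac(sample(3:10, 1))
    expect_equal(degeneracy(p), length(enumerate_primer(p)), info = p)
  }
})

test_that("primer matching finds hits on both strands in forward coordinates", {
  h <- match_primer("AR", c(s1 = "CAAG"))
  expect_equal(h$start[h$strand == "+"], c(1L, 2L))
  h2 <- match_primer("ACGT", c(s1 = "ACGA"), max_mismatch = 1)
  expect_equal(nrow(h2[h2$strand == "+", ]), 1L)
  expect_equal(h2$mismatches[h2$strand == "+"], 1L)
  # a primer embedded reverse-complemented is reported on the minus strand
  # with forward coordinates
  tgt <- paste0("TTT", revcomp("ACGGT"), "AAAA")
  h3 <- match_primer("ACGGT", c(s1 = tgt))
  minus <- h3[h3$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(substr(tgt, minus$start + 1, minus$end), revcomp("ACGGT"))
})

test_that("mismatch-0 matching agrees with the expand-and-scan oracle", {
  set.seed(7)
  for (rep in 1:10) {
    primer <- random_iupac(sample(4:6, 1))
    tgt <- random_dna_str(60)
    hits <- match_primer(primer, c(x = tgt))
    # oracle: scan every expansion at every offset on both strands
    vars <- enumerate_primer(primer)
    L <- nchar(primer)
    plus <- sort(unique(unlist(lapply(vars, function(v) {
      which(vapply(1:(60 - L + 1), function(i)
        substr(tgt, i, i + L - 1) == v, logical(1))) - 1L
    }))))
    rc <- revcomp(tgt)
    minus_rc <- sort(unique(unlist(lapply(vars, function(v) {
      which(vapply(1:(60 - L + 1), function(i)
        substr(rc, i, i + L - 1) == v, logical(1))) - 1L
    }))))
    minus <- sort(60 - minus_rc - L)
    expect_equal(sort(hits$start[hits$strand == "+"]), plus, info = primer)
    expect_equal(sort(hits$start[hits$strand == "-"]), minus, info = primer)
  }
})

test_that("amplicon extraction spans primer to primer and re-orients", {
  set.seed(1)
  acp <- primer_pairs()[primer_pairs()$domain == "ACP", ]
  Fc <- conc_primer(acp$forward)
  Rc <- conc_primer(acp$reverse)
  insert <- random_dna_str(100)
  tmpl <- paste0("TT", Fc, insert, revcomp(Rc), "CCC")
  amp <- extract_amplicons(acp, c(t = tmpl))
  expect_equal(nrow(amp), 1L)
  expect_equal(nchar(amp$amplicon), nchar(Fc) + 100 + nchar(Rc))
  expect_equal(amp$orientation, "+")
  # reverse-complementing the template flips orientation, same amplicon
  amp_rc <- extract_amplicons(acp, c(t = revcomp(tmpl)))
  expect_equal(amp_rc$orientation, "-")
  expect_equal(amp_rc$amplicon, amp$amplicon)
  # template lacking the reverse site yields nothing
  expect_equal(nrow(extract_amplicons(acp, c(t = paste0(Fc, insert)))), 0L)
  # two forward sites -> two candidates, flagged
  tmpl2 <- paste0(Fc, random_dna_str(40), Fc, insert, revcomp(Rc))
  amp2 <- extract_amplicons(acp, c(t = tmpl2))
  expect_equal(nrow(amp2), 2L)
  expect_true(all(amp2$multi_hit))
})

test_that("reference-set construction filters on per-primer identity and dereplicates", {
  set.seed(5)
  acp <- primer_pairs()[primer_pairs()$domain == "ACP", ]
  Fc <- conc_primer(acp$forward)
  Rc <- conc_primer(acp$reverse)
  insert <- random_dna_str(120)
  good <- paste0("AA", Fc, insert, revcomp(Rc))
  # 3 mismatches at *fixed* (non-degenerate) primer positions: identity
  # 22/25 = 0.88 < 0.90
  Fbad <- Fc
  fixed_pos <- which(lengths(iupac_sets[strsplit(acp$forward, "")[[1]]]) == 1)
  for (p in fixed_pos[1:3]) {
    substr(Fbad, p, p) <- setdiff(c("A", "C", "G", "T"), substr(Fc, p, p))[1]
  }
  bad <- paste0("AA", Fbad, insert, revcomp(Rc))
  dup <- paste0("GGGG", Fc, insert, revcomp(Rc))  # same amplicon as `good`
  cand <- tibble::tibble(id = c("c1", "c2", "c3"),
                         sequence = c(good, bad, dup))
  db <- build_reference_db(cand, acp, identity_threshold = 0.90)
  expect_equal(nrow(db), 1L)
  expect_equal(db$sequence, paste0(Fc, insert, revcomp(Rc)))
  # with a permissive threshold the mismatched candidate is admitted
  db2 <- build_reference_db(cand, acp, identity_threshold = 0.85)
  expect_equal(nrow(db2), 2L)
})
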