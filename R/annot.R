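# Rule-based functional assignment: six-frame translation, local protein
# alignment against a characterized-domain fixture, identity/length/E-value
# pass rules, and the fraction of representatives linked to known
# compounds.

# Karlin-Altschul constants for BLOSUM62 with affine gaps (open 11,
# extend 1), the standard published pair for this matrix
KA_LAMBDA <- 0.267
KA_K <- 0.041
AA_GAP_OPEN <- 11
AA_GAP_EXTEND <- 1

#' Six-frame translation of a DNA sequence
#'
#' Standard genetic code; stop codons appear as `*`; frames -1..-3
#' translate the reverse complement. Trailing partial codons are dropped.
#'
#' @param dna Plain DNA string.
#' @return Named character vector of six proteins (`+1`,`+2`,`+3`,
#'   `-1`,`-2`,`-3`).
#' @export
#' @examples
#' six_frame_translate("ATGGCC")[["+1"]]  # "MA"
six_frame_translate <- function(dna) {
  dna <- toupper(dna)
  assert_plain_dna(dna, "six_frame_translate() input")
  rc <- revcomp(dna)
  tr1 <- function(s, off) {
    s <- substr(s, off, nchar(s))
    L <- nchar(s) - nchar(s) %% 3
    if (L < 3) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, L)),
                                       if.fuzzy.codon = "solve"))
  }
  c(`+1` = tr1(dna, 1), `+2` = tr1(dna, 2), `+3` = tr1(dna, 3),
    `-1` = tr1(rc, 1), `-2` = tr1(rc, 2), `-3` = tr1(rc, 3))
}

#' Optimal local protein alignment with BLAST-style statistics
#'
#' Smith-Waterman affine-gap local alignment (BLOSUM62, gap open 11,
#' extend 1, via \pkg{Biostrings}); identity is identical positions over
#' alignment columns. The bit score is `(lambda*S - ln K) / ln 2` with the
#' published Karlin-Altschul constants for this matrix, and the E-value is
#' `m * n * 2^(-bitscore)` where `m` is the query length and `n` the total
#' search-space residue count. The statistics follow the BLAST conventions
#' but bit-for-bit agreement with any external aligner is not implied.
#'
#' @param query_protein,ref_protein Non-empty protein strings.
#' @param search_space Total residues `n` of the database searched
#'   (default: length of `ref_protein`).
#' @return One-row tibble: `score`, `bitscore`, `e_value`,
#'   `percent_identity`, `alignment_length`.
#' @export
local_protein_align <- function(query_protein, ref_protein,
                                search_space = nchar(ref_protein)) {
  if (!nzchar(query_protein) || !nzchar(ref_protein)) {
    abort("local_protein_align(): empty protein")
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query_protein),
    subject = Biostrings::AAString(ref_protein),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = AA_GAP_OPEN, gapExtension = AA_GAP_EXTEND)
  aln_stats(aln, nchar(query_protein), search_space)
}

aln_stats <- function(aln, m, n) {
  s <- Biostrings::score(aln)
  p <- as.character(Biostrings::alignedPattern(aln))
  q <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(p)
  idf <- vapply(seq_along(p), function(i) {
    if (len[i] == 0) return(0)
    pc <- strsplit(p[i], "", fixed = TRUE)[[1]]
    qc <- strsplit(q[i], "", fixed = TRUE)[[1]]
    sum(pc == qc & pc != "-") / len[i]
  }, numeric(1))
  bit <- (KA_LAMBDA * unname(s) - log(KA_K)) / log(2)
  tibble(score = unname(s), bitscore = bit,
         e_value = m * n * 2^(-bit),
         percent_identity = 100 * idf,
         alignment_length = unname(len))
}

#' Synthetic characterized-domain fixture
#'
#' A deterministic stand-in for a curated database of functionally
#' characterized biosynthetic domains: ~50 random proteins labelled with
#' real compound names from the NRPS/PKS literature and assigned to the
#' four domain classes. The sequences are synthetic; only the record
#' *shape* (domain_id, protein, compound, class) mirrors a real
#' characterized-domain collection, and users should supply their own
#' database in the same format for real analyses.
#'
#' @param seed Integer seed (default 20170524).
#' @return Tibble: `domain_id`, `protein`, `compound`, `class`.
#' @export
domain_fixture <- function(seed = 20170524) {
  compounds <- c(
    "thanamycin", "syringopeptin", "syringafactin", "scabichelin",
    "glycopeptidolipid", "coelichelin", "arthrofactin", "rifamycin",
    "heterobactin", "mycobactin", "amychelin", "albachelin", "pyoverdine",
    "bacillaene", "difficidin", "macrolactin", "reveromycin", "bafilomycin",
    "sangifehrin", "hygrocin", "avermectin", "concanamycin", "nemdectin",
    "anthracimycin", "skallamycin", "lobophorin", "chlorothricin",
    "annimycin", "erythromycin", "meridamycin", "delfitibactin",
    "tubulysin", "anabaenopeptin", "gramicidin", "aeruginoside",
    "echinomycin", "puwainophycin", "ajudazol", "virginiamycin",
    "xenortide", "surfactin", "fengycin", "iturin", "bacitracin",
    "daptomycin", "vancomycin", "bleomycin", "actinomycin",
    "pristinamycin", "enterobactin")
  classes <- rep(c("AD", "KS", "met-mal-CoA", "ACP"),
                 length.out = length(compounds))
  lens <- c(AD = 320L, KS = 260L, `met-mal-CoA` = 260L, ACP = 130L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    prot <- vapply(classes, function(cl)
      paste(sample(aa, lens[[cl]], replace = TRUE), collapse = ""),
      character(1), USE.NAMES = FALSE)
  })
  tibble(domain_id = sprintf("dom%03d_%s", seq_along(compounds), compounds),
         protein = prot, compound = compounds, class = classes)
}

#' Minimum alignment lengths per domain class
#' @return Named integer vector of amino-acid length cutoffs.
#' @export
class_min_length <- function() {
  c(AD = 200L, KS = 100L, `met-mal-CoA` = 100L, ACP = 100L)
}

#' Assign representative sequences to characterized domains
#'
#' For each query, the best frame-by-fixture local alignment (by bitscore;
#' ties broken by identity, then domain id) is retained; an assignment
#' *passes* iff identity >= `min_identity` percent, alignment length is at
#' least the class minimum (200 aa for AD, 100 aa for KS, met-mal-CoA and
#' ACP), and E-value <= `max_evalue`. The E-value search space is the total
#' residue count of the fixture.
#'
#' @param representatives Tibble with `id`, `sequence` (DNA), typically
#'   clustered at 100% identity upstream.
#' @param fixture Characterized-domain tibble (see [domain_fixture()]).
#' @param min_identity Percent identity cutoff (default 70).
#' @param max_evalue E-value cutoff (default 1e-25).
#' @param min_length Named per-class alignment-length cutoffs (default
#'   [class_min_length()]).
#' @return A list: `assignments` (tibble: `query_id`, `domain_id`,
#'   `compound`, `class`, `frame`, `percent_identity`, `alignment_length`,
#'   `bitscore`, `e_value`, `passes`) and `summary` (one-row tibble:
#'   `n_searched`, `n_passing`, `fraction_linked`, `percent_linked`,
#'   `n_compounds`).
#' @export
assign_functions <- function(representatives, fixture = domain_fixture(),
                             min_identity = 70, max_evalue = 1e-25,
                             min_length = class_min_length()) {
  reps <- as_sequence_tbl(representatives)
  if (nrow(fixture) == 0L) {
    warn("assign_functions(): empty fixture; nothing can pass")
    summary <- tibble(n_searched = nrow(reps), n_passing = 0L,
                      fraction_linked = 0, percent_linked = 0, n_compounds = 0L)
    return(list(assignments = tibble(), summary = summary))
  }
  n_space <- sum(nchar(fixture$protein))
  refs <- Biostrings::AAStringSet(setNames(fixture$protein, fixture$domain_id))
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  best <- purrr::map(seq_len(nrow(reps)), function(qi) {
    prots <- six_frame_translate(reps$sequence[qi])
    # score-only pass over all frames and references (raw score is
    # monotone in bitscore, so the best hit is found without traceback)
    sc <- purrr::map(frames, function(fr) {
      p <- prots[[fr]]
      if (!nzchar(p)) return(NULL)
      s <- Biostrings::pairwiseAlignment(
        pattern = refs, subject = Biostrings::AAString(p),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = AA_GAP_OPEN, gapExtension = AA_GAP_EXTEND,
        scoreOnly = TRUE)
      tibble(frame = fr, domain_id = fixture$domain_id,
             protein = fixture$protein, score = s)
    }) |> bind_rows()
    if (nrow(sc) == 0L) return(NULL)
    ties <- sc[sc$score >= max(sc$score) - 1e-9, ]
    cand <- purrr::map(seq_len(nrow(ties)), function(ti) {
      p <- prots[[ties$frame[ti]]]
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(ties$protein[ti]),
        subject = Biostrings::AAString(p),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = AA_GAP_OPEN, gapExtension = AA_GAP_EXTEND)
      st <- aln_stats(aln, nchar(p), n_space)
      st$domain_id <- ties$domain_id[ti]
      st$frame <- ties$frame[ti]
      st
    }) |> bind_rows()
    cand <- cand[order(-cand$bitscore, -cand$percent_identity,
                       cand$domain_id), ]
    out <- cand[1, ]
    out$query_id <- reps$id[qi]
    out
  }) |> bind_rows()
  best <- left_join(best, fixture[, c("domain_id", "compound", "class")],
                    by = "domain_id")
  best$passes <- best$percent_identity >= min_identity &
    best$alignment_length >= min_length[best$class] &
    best$e_value <= max_evalue
  assignments <- best[, c("query_id", "domain_id", "compound", "class",
                          "frame", "percent_identity", "alignment_length",
                          "bitscore", "e_value", "passes")]
  n_pass <- sum(assignments$passes)
  summary <- tibble(
    n_searched = nrow(reps),
    n_passing = n_pass,
    fraction_linked = n_pass / max(1, nrow(reps)),
    percent_linked = round_half_up(100 * n_pass / max(1, nrow(reps))),
    n_compounds = dplyr::n_distinct(assignments$compound[assignments$passes]))
  smdiv_log("assign_functions: %d searched, %d passing (%.1f%%)",
            nrow(reps), n_pass, 100 * summary$fraction_linked)
  list(assignments = assignments, summary = summary)
}

#' Reverse-translate a protein into DNA
#'
#' Picks, deterministically, the alphabetically first codon for each amino
#' acid; useful for constructing DNA queries with known translations.
#'
#' @param protein Protein string over the 20-letter alphabet.
#' @return A DNA string whose frame +1 translation is `protein`.
#' @export
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  codons <- vapply(by_aa, function(cs) sort(cs)[1], character(1))
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(codons))
  if (any(bad)) abort(sprintf("reverse_translate(): unknown residue '%s'",
                              ch[which(bad)[1]]))
  paste(codons[ch], collapse = "")
}
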