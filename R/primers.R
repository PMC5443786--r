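# IUPAC degenerate-primer arithmetic, mismatch-tolerant matching on both
# strands, in-silico amplicon extraction, and reference-set construction.

#' Bundled degenerate primer pairs
#'
#' The three primer pairs used to amplify biosynthetic domains from
#' rhizosphere DNA: `A3`/`A7R` targeting the NRPS adenylation (AD) domain
#' (~700 bp), `K1`/`M6R` targeting the PKS ketosynthase / methyl-malonyl-CoA
#' transferase amplicon (~1200-1400 bp), and `Pks_firmi` targeting the
#' Firmicutes PKS acyl carrier protein (ACP) domain (~200 bp).
#'
#' @return A tibble with columns `name`, `domain`, `forward`, `reverse`
#'   (both written 5'->3').
#' @export
#' @examples
#' primer_pairs()
primer_pairs <- function() {
  tibble(
    name    = c("A3_A7R", "K1_M6R", "Pks_firmi"),
    domain  = c("AD", "KS", "ACP"),
    forward = c("GCSTACSYSATSTACACSTCSGG",
                "TSAAGTCSAACATCGGBCA",
                "GCNGGNCAYWSNYTNGGNGARTAYA"),
    reverse = c("SASGTCVCCSGTSCGGTAS",
                "CGCAGGTTSCSGTACCAGTA",
                "CATRWANCKNSWRTGRAANGCNCC")
  )
}

check_iupac <- function(primer) {
  ch <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(IUPAC_MAP))
  if (any(bad)) {
    abort(sprintf("invalid IUPAC character '%s' at position %d",
                  ch[which(bad)[1]], which(bad)[1]))
  }
  ch
}

#' Expand a degenerate primer into all plain-DNA variants
#'
#' @param primer IUPAC DNA string.
#' @param max_variants Safety cap on the expansion size.
#' @return Character vector of all plain-DNA oligos matching the primer.
#' @export
#' @examples
#' expand_degenerate("AR")  # "AA" "AG"
expand_degenerate <- function(primer, max_variants = 2^20) {
  ch <- check_iupac(primer)
  d <- degeneracy(primer)
  if (d > max_variants) {
    abort(sprintf("expand_degenerate(): %s has %.0f variants (> max_variants)",
                  primer, d))
  }
  sets <- IUPAC_MAP[ch]
  out <- ""
  for (s in sets) {
    out <- as.vector(outer(out, s, paste0))
  }
  sort(out)
}

#' Number of plain-DNA variants of a degenerate primer
#'
#' Product of per-position degeneracies; computed without materializing the
#' variant set.
#'
#' @param primer IUPAC DNA string.
#' @return A number.
#' @export
#' @examples
#' degeneracy("NN")  # 16
degeneracy <- function(primer) {
  ch <- check_iupac(primer)
  prod(vapply(IUPAC_MAP[ch], length, integer(1)))
}

# Per-window mismatch counts of `primer` against plain-DNA `seq_chars`
# (character vector). Returns integer vector over start offsets.
window_mismatches <- function(primer_sets, seq_chars) {
  L <- length(primer_sets)
  n <- length(seq_chars)
  if (n < L) return(integer(0))
  n_win <- n - L + 1L
  mm <- integer(n_win)
  for (k in seq_len(L)) {
    mm <- mm + !(seq_chars[k:(k + n_win - 1L)] %in% primer_sets[[k]])
  }
  mm
}

#' Match a degenerate primer against a sequence on both strands
#'
#' A mismatch is any position where the target base is not in the primer
#' position's IUPAC-allowed set; matching is ungapped. Minus-strand hits
#' (the primer matching the reverse complement) are reported in forward
#' coordinates.
#'
#' @param primer IUPAC DNA string.
#' @param sequences Tibble with `id`, `sequence` (plain DNA), or a named
#'   character vector.
#' @param max_mismatch Maximum mismatches allowed per hit.
#' @return Tibble of hits: `sequence_id`, `start` (0-based), `end`
#'   (exclusive), `strand` (`+`/`-`), `mismatches`; sorted by
#'   `(sequence_id, start)`.
#' @export
match_primer <- function(primer, sequences, max_mismatch = 0) {
  seqs <- as_sequence_tbl(sequences)
  ch <- check_iupac(primer)
  sets <- IUPAC_MAP[ch]
  L <- length(sets)
  hits <- purrr::map2(seqs$id, seqs$sequence, function(id, s) {
    s <- toupper(s)
    fwd <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(fwd)
    mmf <- window_mismatches(sets, fwd)
    okf <- which(mmf <= max_mismatch)
    rev_ <- strsplit(revcomp(s), "", fixed = TRUE)[[1]]
    mmr <- window_mismatches(sets, rev_)
    okr <- which(mmr <= max_mismatch)
    bind_rows(
      if (length(okf)) tibble(sequence_id = id, start = okf - 1L,
                              end = okf - 1L + L, strand = "+",
                              mismatches = mmf[okf]),
      # hit at revcomp offset i (0-based i-1) covers forward [n-i-L+1, n-i+1)
      if (length(okr)) tibble(sequence_id = id, start = n - (okr - 1L) - L,
                              end = n - (okr - 1L), strand = "-",
                              mismatches = mmr[okr])
    )
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(sequence_id = character(), start = integer(),
                  end = integer(), strand = character(), mismatches = integer()))
  }
  arrange(out, .data$sequence_id, .data$start, .data$strand)
}

as_sequence_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% as.character(seq_along(x))
    if (is.null(names(x))) ids <- paste0("seq", seq_along(x))
    return(tibble(id = ids, sequence = unname(x)))
  }
  stopifnot(all(c("id", "sequence") %in% names(x)))
  as_tibble(x[, c("id", "sequence")])
}

#' Extract in-silico amplicons delimited by a primer pair
#'
#' An amplicon spans from the forward-primer start to the end of the
#' reverse-primer binding site (primers included). Both template
#' orientations are searched; output sequences are re-oriented so the
#' forward primer is 5'. Multiple candidate amplicons on one template are
#' all reported and flagged.
#'
#' @param pair A one-row tibble with `forward`/`reverse` IUPAC primers (see
#'   [primer_pairs()]), or a list with those elements.
#' @param sequences Tibble with `id`, `sequence`, or named character vector.
#' @param min_len,max_len Length bounds on reported amplicons (primers
#'   included).
#' @param max_mismatch Per-primer mismatch tolerance.
#' @return Tibble: `id`, `amplicon`, `orientation` (`+` if the forward
#'   primer matched the given strand), `start`, `end`, `multi_hit` flag.
#' @export
extract_amplicons <- function(pair, sequences, min_len = 0, max_len = Inf,
                              max_mismatch = 0) {
  seqs <- as_sequence_tbl(sequences)
  fwd <- pair$forward[[1]]
  rev_ <- pair$reverse[[1]]
  fh <- match_primer(fwd, seqs, max_mismatch)
  rh <- match_primer(rev_, seqs, max_mismatch)
  out <- purrr::map(seqs$id, function(id) {
    s <- toupper(seqs$sequence[seqs$id == id][1])
    f <- fh[fh$sequence_id == id, ]
    r <- rh[rh$sequence_id == id, ]
    cand <- list()
    # orientation +: forward primer on + strand, reverse primer on - strand,
    # reverse site downstream of forward site
    fp <- f[f$strand == "+", ]; rm_ <- r[r$strand == "-", ]
    if (nrow(fp) && nrow(rm_)) {
      for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(rm_))) {
        if (rm_$end[j] > fp$start[i]) {
          cand[[length(cand) + 1L]] <- tibble(
            id = id,
            amplicon = substr(s, fp$start[i] + 1L, rm_$end[j]),
            orientation = "+", start = fp$start[i], end = rm_$end[j])
        }
      }
    }
    # orientation -: forward primer on - strand, reverse primer on + strand
    fm <- f[f$strand == "-", ]; rp <- r[r$strand == "+", ]
    if (nrow(fm) && nrow(rp)) {
      for (i in seq_len(nrow(fm))) for (j in seq_len(nrow(rp))) {
        if (fm$end[i] > rp$start[j]) {
          cand[[length(cand) + 1L]] <- tibble(
            id = id,
            amplicon = revcomp(substr(s, rp$start[j] + 1L, fm$end[i])),
            orientation = "-", start = rp$start[j], end = fm$end[i])
        }
      }
    }
    if (!length(cand)) return(NULL)
    cc <- bind_rows(cand)
    cc$multi_hit <- nrow(cc) > 1L
    cc
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(id = character(), amplicon = character(),
                  orientation = character(), start = integer(),
                  end = integer(), multi_hit = logical()))
  }
  len <- nchar(out$amplicon)
  out <- out[len >= min_len & len <= max_len, ]
  arrange(out, .data$id, .data$start)
}

#' Build a primer-anchored reference set from candidate sequences
#'
#' Keeps candidates where both primers of the pair match with per-primer
#' ungapped identity at least `identity_threshold` (identity = 1 -
#' mismatches / primer length, over the full primer length), trims to the
#' amplicon region, removes exact duplicates, and returns records ordered
#' by id.
#'
#' @param candidates Tibble with `id`, `sequence` (plain DNA).
#' @param pair Primer pair (as in [extract_amplicons()]).
#' @param identity_threshold Minimum per-primer identity (default 0.90).
#' @param min_len,max_len Amplicon length bounds.
#' @return Tibble with `id`, `sequence` of dereplicated trimmed references.
#' @export
build_reference_db <- function(candidates, pair, identity_threshold = 0.90,
                               min_len = 0, max_len = Inf) {
  mmf <- floor((1 - identity_threshold) * nchar(pair$forward[[1]]))
  mmr <- floor((1 - identity_threshold) * nchar(pair$reverse[[1]]))
  amps <- extract_amplicons(pair, candidates, min_len = min_len,
                            max_len = max_len, max_mismatch = max(mmf, mmr))
  if (nrow(amps) == 0L) {
    return(tibble(id = character(), sequence = character()))
  }
  # enforce the identity threshold per primer (the extraction pass used the
  # looser of the two mismatch budgets): the amplicon is oriented with the
  # forward primer as prefix and revcomp(reverse) as suffix
  fsets <- IUPAC_MAP[check_iupac(pair$forward[[1]])]
  rsets <- IUPAC_MAP[check_iupac(revcomp(pair$reverse[[1]]))]
  ok <- vapply(amps$amplicon, function(a) {
    ch <- strsplit(a, "", fixed = TRUE)[[1]]
    pre <- head(ch, length(fsets))
    suf <- tail(ch, length(rsets))
    sum(!mapply(`%in%`, pre, fsets)) <= mmf &&
      sum(!mapply(`%in%`, suf, rsets)) <= mmr
  }, logical(1), USE.NAMES = FALSE)
  amps <- amps[ok, ]
  out <- amps |>
    dplyr::transmute(id = .data$id, sequence = .data$amplicon) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE) |>
    arrange(.data$id)
  smdiv_log("build_reference_db: %d candidates -> %d dereplicated references",
            nrow(candidates), nrow(out))
  out
}
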