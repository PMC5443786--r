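# Read quality control: rolling-window quality truncation, barcode
# demultiplexing with primer clipping, dereplication with singleton
# removal, abundance-skew two-parent chimera flagging, and common-length
# trimming. Stage order is fixed: quality_filter -> demultiplex ->
# dereplicate -> flag_chimeras -> trim_to_common_length; total read mass
# is non-increasing at every stage.

#' Rolling-window quality filtering
#'
#' Each read is scanned with a trailing window of `window` bases; at the
#' first window whose mean PHRED quality drops below `q_cutoff` the read is
#' truncated just before that window's start. Reads shorter than `window`
#' after truncation are dropped, as are reads containing any ambiguous
#' (non-ACGT) base.
#'
#' @param reads Tibble with `id`, `sequence` and list-column `quality`.
#' @param q_cutoff Mean-quality cutoff (default 20).
#' @param window Window size in bases (default 50).
#' @return Filtered/truncated read tibble.
#' @export
quality_filter <- function(reads, q_cutoff = 20, window = 50) {
  if (!"quality" %in% names(reads) || any(vapply(reads$quality, is.null, logical(1)))) {
    abort("quality_filter(): reads carry no quality scores")
  }
  n_in <- nrow(reads)
  keep_len <- vapply(reads$quality, function(q) {
    L <- length(q)
    if (L < window) return(if (mean(q) < q_cutoff) 0L else L)
    cs <- cumsum(c(0, q))
    wmean <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
    bad <- which(wmean < q_cutoff)     # window i spans bases i..i+window-1
    if (!length(bad)) L else bad[1] - 1L
  }, integer(1))
  out <- reads
  out$sequence <- substr(out$sequence, 1L, keep_len)
  out$quality <- purrr::map2(out$quality, keep_len, function(q, l) q[seq_len(l)])
  keep <- keep_len >= window & !grepl("[^ACGT]", out$sequence)
  out <- out[keep, ]
  smdiv_log("quality_filter: %d reads in, %d retained", n_in, nrow(out))
  out
}

#' Demultiplex barcoded reads and clip barcode + forward primer
#'
#' Barcodes must match exactly at the 5' end. After the barcode is removed
#' the forward primer, when it matches the new 5' end within
#' `max_primer_mismatch` under IUPAC semantics, is clipped as well. Reads
#' matching no barcode are routed to sample `"unassigned"`.
#'
#' @param reads Read tibble (`id`, `sequence`, optional `quality`).
#' @param metadata Metadata with unique equal-length `barcode`s.
#' @param forward_primer IUPAC forward primer to clip (optional).
#' @param max_primer_mismatch Mismatch tolerance for primer clipping
#'   (default 2).
#' @return Read tibble with `sample_id` assigned and barcode/primer clipped.
#' @export
demultiplex <- function(reads, metadata, forward_primer = NULL,
                        max_primer_mismatch = 2) {
  bcs <- metadata$barcode
  if (anyDuplicated(bcs)) abort("demultiplex(): duplicate barcode in metadata")
  if (length(unique(nchar(bcs))) != 1L) {
    abort("demultiplex(): barcodes must have equal length")
  }
  bl <- nchar(bcs[1])
  lookup <- setNames(metadata$sample_id, bcs)
  pre <- substr(reads$sequence, 1L, bl)
  sample_id <- unname(lookup[pre])
  sample_id[is.na(sample_id)] <- "unassigned"
  out <- reads
  out$sample_id <- sample_id
  hit <- sample_id != "unassigned"
  clip <- ifelse(hit, bl, 0L)
  if (!is.null(forward_primer) && any(hit)) {
    sets <- IUPAC_MAP[check_iupac(forward_primer)]
    L <- length(sets)
    pseq <- substr(out$sequence, clip + 1L, clip + L)
    pmm <- vapply(pseq, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      if (length(ch) < L) return(L)
      sum(!mapply(`%in%`, ch, sets))
    }, numeric(1), USE.NAMES = FALSE)
    clip <- clip + ifelse(hit & pmm <= max_primer_mismatch, L, 0L)
  }
  out$sequence <- substr(out$sequence, clip + 1L, nchar(out$sequence))
  if ("quality" %in% names(out)) {
    out$quality <- purrr::map2(out$quality, clip, function(q, cl)
      if (is.null(q)) NULL else q[-seq_len(cl)])
  }
  smdiv_log("demultiplex: %d reads, %d assigned, %d unassigned",
            nrow(out), sum(hit), sum(!hit))
  out
}

#' Dereplicate reads and drop rare uniques
#'
#' Exact-sequence dereplication pooled across samples with per-sample size
#' bookkeeping; groups with total size below `min_size` (singletons by
#' default) are removed. Output is sorted by size descending, then sequence.
#'
#' @param reads Read tibble with `sequence` and optional `sample_id`.
#' @param min_size Minimum duplicate count to retain (default 2).
#' @return Tibble of unique reads: `id`, `sequence`, `size`, `samples`
#'   (list-column of named per-sample counts).
#' @export
dereplicate <- function(reads, min_size = 2) {
  n_in <- nrow(reads)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "all"
  grp <- reads |>
    group_by(.data$sequence) |>
    summarise(size = dplyr::n(),
              samples = list(table_to_named(.data$sample_id)),
              .groups = "drop") |>
    filter(.data$size >= min_size) |>
    arrange(desc(.data$size), .data$sequence)
  grp$id <- sprintf("uniq%05d", seq_len(nrow(grp)))
  out <- grp[, c("id", "sequence", "size", "samples")]
  smdiv_log("dereplicate: %d reads -> %d uniques (min_size=%d)",
            n_in, nrow(out), min_size)
  out
}

table_to_named <- function(x) {
  t <- table(x)
  setNames(as.integer(t), names(t))
}

#' Flag chimeric uniques by a two-parent abundance-skew test
#'
#' A simplified de-novo chimera test retaining the core ideas of the
#' abundance-skew approach: queries are visited in ascending abundance;
#' candidate parents are uniques with size at least `abundance_skew` times
#' the query's size. A query is flagged when some parent pair (A, B) and
#' breakpoint give a chimeric model (prefix vs A, suffix vs B, ungapped and
#' left/right anchored) whose segment identities both exceed the best
#' single-parent full-length identity by at least `min_crossover_gain`.
#' This is an explicit simplification of UCHIME de novo, not a
#' reimplementation.
#'
#' @param uniques Dereplicated tibble (`id`, `sequence`, `size`, ...).
#' @param abundance_skew Parent/query abundance ratio (default 1.9).
#' @param min_crossover_gain Required identity improvement of the chimeric
#'   model over the best single parent, per segment (default 0.05).
#' @param min_segment Minimum segment length considered (default 20).
#' @return List with `clean` and `flagged` tibbles (flagged rows gain
#'   `parent_a`, `parent_b`).
#' @export
flag_chimeras <- function(uniques, abundance_skew = 1.9,
                          min_crossover_gain = 0.05, min_segment = 20) {
  stopifnot(abundance_skew > 1)
  n <- nrow(uniques)
  if (n == 0L) return(list(clean = uniques, flagged = uniques[0, ]))
  ord <- order(uniques$size, uniques$sequence, method = "radix")
  flagged <- logical(n)
  pa <- rep(NA_character_, n); pb <- rep(NA_character_, n)
  seq_chars <- lapply(uniques$sequence, function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  for (qi in ord) {
    cand <- which(uniques$size >= abundance_skew * uniques$size[qi] &
                    seq_len(n) != qi & !flagged)
    if (length(cand) < 2L) next
    q <- seq_chars[[qi]]; Lq <- length(q)
    # left-anchored cumulative matches and right-anchored tail matches
    pref <- matrix(0, nrow = length(cand), ncol = Lq)
    suff <- matrix(0, nrow = length(cand), ncol = Lq + 1L)
    full_id <- numeric(length(cand))
    for (ci in seq_along(cand)) {
      p <- seq_chars[[cand[ci]]]
      L <- min(Lq, length(p))
      m_left <- c(q[seq_len(L)] == p[seq_len(L)], rep(FALSE, Lq - L))
      pref[ci, ] <- cumsum(m_left)
      # right-anchored: compare tails of equal length
      m_right <- c(rep(FALSE, Lq - L),
                   rev(rev(q)[seq_len(L)] == rev(p)[seq_len(L)]))
      suff[ci, ] <- c(rev(cumsum(rev(m_right))), 0)
      full_id[ci] <- pref[ci, Lq] / Lq
    }
    best_single <- max(full_id)
    hit <- FALSE
    for (b in seq(min_segment, Lq - min_segment)) {
      pid <- pref[, b] / b
      sid <- suff[, b + 1L] / (Lq - b)
      # null model: the best *single* parent may explain both segments
      # (tolerating an alignment shift, e.g. a homopolymer indel), so the
      # chimeric model must beat max_P min(prefix_P, suffix_P) as well as
      # the best full-length single-parent identity
      single_b <- max(best_single, max(pmin(pid, sid)))
      ia <- which.max(pid)
      ib <- which.max(sid)
      if (ia == ib) {
        # force distinct parents: take second best on the weaker side
        if (length(cand) < 2L) next
        alt_s <- order(sid, decreasing = TRUE)
        alt_p <- order(pid, decreasing = TRUE)
        if (pid[ia] - pid[alt_p[2]] <= sid[ib] - sid[alt_s[2]]) ia <- alt_p[2]
        else ib <- alt_s[2]
      }
      if (pid[ia] >= single_b + min_crossover_gain &&
          sid[ib] >= single_b + min_crossover_gain) {
        flagged[qi] <- TRUE
        pa[qi] <- uniques$id[cand[ia]]; pb[qi] <- uniques$id[cand[ib]]
        hit <- TRUE
        break
      }
    }
    if (hit) next
  }
  fl <- uniques[flagged, ]
  if (nrow(fl)) { fl$parent_a <- pa[flagged]; fl$parent_b <- pb[flagged] }
  smdiv_log("flag_chimeras: %d uniques, %d flagged", n, sum(flagged))
  list(clean = uniques[!flagged, ], flagged = fl)
}

#' Trim retained reads to a common length
#'
#' Reads shorter than `floor_len` are dropped first; the rest are cut to
#' the length of the shortest survivor.
#'
#' @param reads Tibble with `sequence` (and optional `quality`).
#' @param floor_len Minimum acceptable read length (default 0).
#' @return Trimmed read tibble.
#' @export
trim_to_common_length <- function(reads, floor_len = 0) {
  n_in <- nrow(reads)
  keep <- nchar(reads$sequence) >= floor_len
  out <- reads[keep, ]
  if (nrow(out) == 0L) return(out)
  L <- min(nchar(out$sequence))
  out$sequence <- substr(out$sequence, 1L, L)
  if ("quality" %in% names(out)) {
    out$quality <- purrr::map(out$quality, function(q)
      if (is.null(q)) NULL else q[seq_len(min(L, length(q)))])
  }
  smdiv_log("trim_to_common_length: %d in, %d out at %d bp", n_in, nrow(out), L)
  out
}
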