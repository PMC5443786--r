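# Independent oracles and small fixture builders used across the suite.

options(smdiv.verbose = FALSE)

# --- enumeration oracle for degenerate primers ---------------------------

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

enumerate_primer <- function(primer) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  grid <- do.call(expand.grid, c(rev(iupac_sets[ch]),
                                 stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(ch)), drop = FALSE], 1, paste, collapse = ""))
}

random_iupac <- function(len) {
  paste(sample(names(iupac_sets), len, replace = TRUE), collapse = "")
}

# --- brute-force affine-gap global alignment (gap of length k costs
# open + k*ext, i.e. first gap column open+ext) ---------------------------

oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = 1, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# enumerate every optimal global alignment of short sequences and return
# the set of identities (terminal-gap columns excluded)
oracle_optimal_identities <- function(a, b, match = 1, mismatch = -1,
                                      open = 1, ext = 1) {
  best <- oracle_global_score(a, b, match, mismatch, open, ext)
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  out <- new.env(); out$ids <- numeric(0)
  # depth-first over alignment columns, tracking score with affine bookkeeping
  rec <- function(i, j, ap, bp, score, state) {
    # prune: remaining best possible gain
    rem <- max(length(A) - i, length(B) - j)
    if (score + rem * match < best - 1e-9) return()
    if (i == length(A) && j == length(B)) {
      if (abs(score - best) < 1e-9) {
        pc <- ap; qc <- bp
        nong <- which(pc != "-" & qc != "-")
        if (length(nong)) {
          keep <- seq(min(nong), max(nong))
          out$ids <- c(out$ids,
                       sum(pc[keep] == qc[keep] & pc[keep] != "-") / length(keep))
        }
      }
      return()
    }
    if (i < length(A) && j < length(B)) {
      s <- if (A[i + 1] == B[j + 1]) match else mismatch
      rec(i + 1, j + 1, c(ap, A[i + 1]), c(bp, B[j + 1]), score + s, "M")
    }
    if (i < length(A)) {
      pen <- if (state == "X") -ext else -(open + ext)
      rec(i + 1, j, c(ap, A[i + 1]), c(bp, "-"), score + pen, "X")
    }
    if (j < length(B)) {
      pen <- if (state == "Y") -ext else -(open + ext)
      rec(i, j + 1, c(ap, "-"), c(bp, B[j + 1]), score + pen, "Y")
    }
  }
  rec(0, 0, character(0), character(0), 0, "M")
  unique(round(out$ids, 10))
}

# --- brute-force Smith-Waterman with affine gaps and a substitution
# matrix (protein local alignment oracle) ---------------------------------

oracle_local_score <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(0, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1); Iy <- Ix
  bestv <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- submat[A[i], B[j]]
    M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    bestv <- max(bestv, M[i + 1, j + 1])
  }
  bestv
}

# --- random additive tree -> path-length distance matrix -----------------
# built by sequential joining, independently of any phylogenetics package

random_additive_distances <- function(n) {
  clusters <- lapply(seq_len(n), function(i) setNames(0, paste0("t", i)))
  labs <- paste0("t", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1) {
    pick <- sample.int(length(clusters), 2)
    A <- clusters[[pick[1]]]; B <- clusters[[pick[2]]]
    e1 <- runif(1, 0.2, 1); e2 <- runif(1, 0.2, 1)
    A <- A + e1; B <- B + e2
    for (x in names(A)) for (y in names(B)) {
      D[x, y] <- D[y, x] <- A[[x]] + B[[y]]
    }
    clusters <- c(clusters[-pick], list(c(A, B)))
  }
  D
}

# --- misc fixtures --------------------------------------------------------

# deterministic concretization: first allowed base at each position
conc_primer <- function(primer) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  paste(vapply(iupac_sets[ch], `[[`, character(1), 1L), collapse = "")
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# a sequence pair differing by exactly k scattered substitutions (no two
# adjacent), so that the optimal alignment is the ungapped one
mutated_pair <- function(len, k) {
  a <- random_dna_str(len)
  pos <- sort(sample(seq(1, len, by = 2), k))
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  list(a = a, b = paste(ch, collapse = ""))
}

make_reads <- function(seqs, quals = NULL, ids = NULL, sample_id = NULL) {
  n <- length(seqs)
  tb <- tibble::tibble(
    id = ids %||% paste0("r", seq_len(n)),
    sequence = seqs,
    quality = quals %||% lapply(nchar(seqs), function(L) rep(40L, L)))
  if (!is.null(sample_id)) tb$sample_id <- sample_id
  tb
}

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_metadata <- function(n_sites = 3, n_stages = 2, n_reps = 3) {
  md <- expand.grid(replicate = seq_len(n_reps),
                    stage = c("emergence", "senescence")[seq_len(n_stages)],
                    site = paste0("P", seq_len(n_sites)),
                    stringsAsFactors = FALSE)
  md$sample_id <- sprintf("%s_%s_%d", md$site, md$stage, md$replicate)
  tibble::as_tibble(md[, c("sample_id", "site", "stage", "replicate")])
}
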