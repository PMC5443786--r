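# Shared low-level helpers: sequence alphabet handling, rounding, seeded RNG.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of a DNA string
#'
#' Accepts plain or IUPAC-degenerate DNA; complement follows IUPAC rules
#' (e.g. `R` -> `Y`, `S` -> `S`).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
#' revcomp("ARN")
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    comp <- IUPAC_COMPLEMENT[ch]
    if (anyNA(comp)) {
      abort(sprintf("revcomp(): invalid DNA character(s) in %s", s))
    }
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round half away from zero (the convention used when mirroring printed
# percentage tables); base round() is banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic local RNG: runs `expr` under a private seed without
# disturbing the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed below 2^31 from a parent seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

assert_plain_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (first offender: %s)",
                  what, x[which(bad)[1]]))
  }
  invisible(x)
}
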