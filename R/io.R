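# Readers/writers for FASTA, FASTQ (PHRED+33), sample metadata and OTU
# tables. All return tibbles; all round-trip losslessly for valid inputs.

#' Read a FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; line wrapping is
#' ignored. Gzipped files are handled transparently.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (full header line after `>`) and
#'   `sequence`. An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_fasta(): no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(id = character(), sequence = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort(sprintf("read_fasta(): malformed header at line 1 of %s (expected '>')", path))
  }
  rec <- cumsum(is_header)
  ids <- sub("^>", "", lines[is_header])
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste, character(1), collapse = "")
  # headers with no sequence lines get empty strings
  out <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  out[names(seqs)] <- seqs
  seqs <- chartr("u", "t", toupper(unname(out)))
  seqs <- chartr("U", "T", seqs)
  tibble(id = ids, sequence = seqs)
}

#' Write a FASTA file
#'
#' @param x A tibble/data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes one line per sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = Inf) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Read a FASTQ file (PHRED+33)
#'
#' @param path Path to a 4-line-per-record FASTQ file.
#' @return A tibble of amplicon reads: `id`, `sequence`, `quality`
#'   (list-column of integer PHRED scores). Sequence and quality lengths
#'   always agree.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_fastq(): no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble(id = character(), sequence = character(), quality = list()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("read_fastq(): truncated record at end of %s (%d lines)",
                  path, length(lines)))
  }
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  quals <- lines[seq(4, length(lines), 4)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    abort(sprintf("read_fastq(): sequence/quality length mismatch in record '%s'",
                  ids[which(bad)[1]]))
  }
  qlist <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  tibble(id = ids, sequence = seqs, quality = qlist)
}

#' Write a FASTQ file (PHRED+33)
#'
#' @param reads Tibble with `id`, `sequence` and list-column `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  qc <- vapply(reads$quality, function(q) intToUtf8(q + 33L), character(1))
  txt <- rbind(paste0("@", reads$id), reads$sequence, "+", qc)
  writeLines(as.vector(txt), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with required columns `sample_id`, `site`, `stage`,
#' `replicate` and optional `barcode`; unknown columns are preserved.
#' `(site, stage, replicate)` triples must be unique and barcodes, when
#' present, must be plain DNA.
#'
#' @param path Path to a TSV file.
#' @return A tibble of sample metadata.
#' @export
read_metadata <- function(path) {
  md <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                    check.names = FALSE, colClasses = "character"))
  req <- c("sample_id", "site", "stage", "replicate")
  miss <- setdiff(req, names(md))
  if (length(miss)) abort(paste0("read_metadata(): missing column(s): ",
                                 paste(miss, collapse = ", ")))
  md$replicate <- as.integer(md$replicate)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  key <- paste(md$site, md$stage, md$replicate)
  if (anyDuplicated(key)) {
    abort(sprintf("metadata: duplicate (site, stage, replicate) triple: %s",
                  key[anyDuplicated(key)]))
  }
  if (anyDuplicated(md$sample_id)) abort("metadata: duplicate sample_id")
  if ("barcode" %in% names(md)) {
    bc <- md$barcode[!is.na(md$barcode) & nzchar(md$barcode)]
    if (length(bc)) assert_plain_dna(bc, "metadata barcode")
  }
  as_tibble(md)
}

#' Write sample metadata as TSV
#' @param md Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU count table
#'
#' Tab-separated, first header cell `#OTU_ID`, remaining columns one per
#' sample, cells non-negative integer counts.
#'
#' @param path Path to a TSV OTU table.
#' @return A tibble with column `otu_id` followed by one integer column per
#'   sample.
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort(sprintf("read_otu_table(): empty file: %s", path))
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#OTU_ID") {
    abort("read_otu_table(): first header cell must be '#OTU_ID'")
  }
  samples <- hdr[-1]
  if (anyDuplicated(samples)) abort("read_otu_table(): duplicate sample columns")
  if (length(lines) == 1L) {
    out <- c(list(otu_id = character()),
             setNames(rep(list(integer()), length(samples)), samples))
    return(as_tibble(out))
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(hdr))) {
    abort(sprintf("read_otu_table(): row %d is not rectangular",
                  which(nc != length(hdr))[1] + 1L))
  }
  ids <- vapply(cells, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) abort("read_otu_table(): duplicate OTU row labels")
  mat <- do.call(rbind, lapply(cells, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
      abort(sprintf("read_otu_table(): non-count cell in row '%s'", r[1]))
    }
    as.integer(v)
  }))
  colnames(mat) <- samples
  dplyr::bind_cols(tibble(otu_id = ids), as_tibble(mat))
}

#' Write an OTU count table
#' @param tab Tibble with `otu_id` column and per-sample count columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(tab, path) {
  stopifnot(names(tab)[1] == "otu_id")
  hdr <- c("#OTU_ID", names(tab)[-1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(tab)) {
    body <- apply(tab, 1, function(r) paste(r, collapse = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

# Internal: OTU tibble <-> integer matrix with otu_id rownames.
otu_matrix <- function(tab) {
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$otu_id
  m
}
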