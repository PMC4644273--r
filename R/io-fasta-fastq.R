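#' Read a FASTA file
#'
#' Parses a FASTA file into a data frame of sequence records.  Sequences are
#' uppercased and whitespace-stripped; records are returned in file order.
#' Malformed headers and empty sequences raise errors naming the offending
#' line.
#'
#' @param path path to a FASTA file.
#' @return a data frame with columns `id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA header at line ", nonblank[1], ": expected '>'")
  }
  hdr <- which(startsWith(lines, ">"))
  # every record must have at least one non-empty sequence character
  ends <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    if (nchar(trimws(sub("^>", "", lines[hdr[i]]))) == 0L) {
      stop("malformed FASTA header at line ", hdr[i], ": empty header")
    }
    body <- if (ends[i] >= hdr[i] + 1L) lines[(hdr[i] + 1L):ends[i]] else character(0)
    if (sum(nchar(gsub("\\s", "", body))) == 0L) {
      stop("empty sequence for record at line ", hdr[i])
    }
  }
  x <- Biostrings::readBStringSet(path)
  full <- names(x)
  data.frame(
    id = sub("\\s.*$", "", full),
    sequence = toupper(gsub("\\s", "", as.character(x))),
    description = ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write sequences to a FASTA file
#'
#' @param records data frame with columns `id`, `sequence` and optionally
#'   `description`, or a named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          description = "", stringsAsFactors = FALSE)
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records with Phred+33 qualities into a read table.
#' Sequence/quality length mismatches and out-of-range quality characters
#' raise errors naming the offending line.
#'
#' @param path path to a FASTQ file.
#' @param platform platform tag to attach to every read (`"A_long_single"`,
#'   `"B_short_paired"`, or `NA`).
#' @return a read data frame with columns `id`, `platform`, `sequence`,
#'   `quality`, `mate_id`.
#' @export
read_fastq <- function(path, platform = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at line ", 4L * (length(lines) %/% 4L) + 1L)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(empty_reads(platform))
  }
  h <- lines[seq(1L, by = 4L, length.out = n)]
  s <- lines[seq(2L, by = 4L, length.out = n)]
  q <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(h, "@"))
  if (length(bad)) {
    stop("malformed FASTQ header at line ", (bad[1] - 1L) * 4L + 1L,
         ": expected '@'")
  }
  mism <- which(nchar(s) != nchar(q))
  if (length(mism)) {
    stop("sequence/quality length mismatch at line ", (mism[1] - 1L) * 4L + 2L)
  }
  qr <- vapply(q, function(z) {
    if (nchar(z) == 0L) return(TRUE)
    r <- range(utf8ToInt(z))
    r[1] >= 33L && r[2] <= 74L
  }, logical(1), USE.NAMES = FALSE)
  if (any(!qr)) {
    stop("non-Phred+33 quality character at line ",
         (which(!qr)[1] - 1L) * 4L + 4L)
  }
  data.frame(
    id = sub("\\s.*$", "", sub("^@", "", h)),
    platform = platform,
    sequence = toupper(s),
    quality = q,
    mate_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads read data frame (columns `id`, `sequence`, `quality`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+",
                         reads$quality))
  writeLines(out, path)
  invisible(path)
}

empty_reads <- function(platform = NA_character_) {
  data.frame(id = character(0), platform = character(0),
             sequence = character(0), quality = character(0),
             mate_id = character(0), stringsAsFactors = FALSE)[
    , c("id", "platform", "sequence", "quality", "mate_id")]
}
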