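#' Read a GenBank flat file (minimal dialect)
#'
#' Parses the subset of the GenBank flat-file format needed for genome
#' statistics: the LOCUS length, the ORIGIN sequence, and CDS/tRNA/rRNA/tmRNA
#' features with `complement(...)`/`join(...)` locations and their
#' qualifiers.  Other feature keys are kept with type `"misc"`.  Partial
#' location markers (`<`, `>`) are treated as exact with a warning;
#' unparseable locations skip the feature with a warning quoting the raw
#' location string.
#'
#' @param path path to a GenBank flat file.
#' @return an `AnnotatedRecord`: a list with elements `id`, `length`,
#'   `sequence`, and `features` (a list of features, each a list with
#'   `type`, `key`, `strand`, `segments` (matrix of 1-based inclusive
#'   start/end rows), `qualifiers`, `pseudo`).
#' @export
read_genbank_lite <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  bp_i <- match("bp", locus)
  if (is.na(bp_i) || bp_i < 3L) stop("cannot parse LOCUS length in ", path)
  declared_len <- as.integer(gsub(",", "", locus[bp_i - 1L]))

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) stop("missing ORIGIN section in ", path)
  origin_i <- origin_i[1]

  # --- sequence ---
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L
  seq_lines <- lines[seq(origin_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != declared_len) {
    stop("ORIGIN sequence length (", nchar(sequence),
         ") does not match LOCUS length (", declared_len, ")")
  }

  # --- features ---
  features <- list()
  if (length(feat_i) > 0L && feat_i[1] < origin_i) {
    block <- lines[seq(feat_i[1] + 1L, origin_i - 1L)]
    is_key <- grepl("^ {5}\\S", block)
    starts <- which(is_key)
    for (fi in seq_along(starts)) {
      from <- starts[fi]
      to <- if (fi < length(starts)) starts[fi + 1L] - 1L else length(block)
      flines <- block[from:to]
      m <- regmatches(flines[1], regexec("^ {5}(\\S+)\\s+(\\S.*)$", flines[1]))[[1]]
      if (length(m) < 3L) next
      key <- m[2]
      # location may continue until the first qualifier line
      rest <- flines[-1]
      qual_start <- which(grepl("^\\s+/", rest))
      loc_extra <- if (length(qual_start)) {
        if (qual_start[1] > 1L) rest[seq_len(qual_start[1] - 1L)] else character(0)
      } else rest
      loc_str <- gsub("\\s", "", paste(c(m[3], loc_extra), collapse = ""))
      qlines <- if (length(qual_start)) rest[qual_start[1]:length(rest)] else character(0)

      if (key == "source") next
      loc <- tryCatch(parse_gb_location(loc_str),
                      error = function(e) NULL)
      if (is.null(loc)) {
        warning("skipping ", key, " feature with unparseable location: ",
                loc_str, call. = FALSE)
        next
      }
      bad <- loc$segments[, 1] < 1L | loc$segments[, 2] > declared_len |
        loc$segments[, 1] > loc$segments[, 2]
      if (any(bad)) {
        warning("skipping ", key, " feature with out-of-range location: ",
                loc_str, call. = FALSE)
        next
      }
      quals <- parse_gb_qualifiers(qlines)
      features[[length(features) + 1L]] <- list(
        type = if (key %in% c("CDS", "tRNA", "rRNA", "tmRNA")) key else "misc",
        key = key,
        strand = loc$strand,
        segments = loc$segments,
        qualifiers = quals$values,
        pseudo = quals$pseudo
      )
    }
  }

  structure(list(id = id, length = declared_len, sequence = sequence,
                 features = features),
            class = "AnnotatedRecord")
}

# Location grammar: N | N..M | join(...) | order(...) | complement(...),
# with nesting; '<'/'>' markers stripped (treated as exact, with a warning).
parse_gb_location <- function(s) {
  if (grepl("[<>]", s)) {
    warning("partial-location markers treated as exact in: ", s,
            call. = FALSE)
    s <- gsub("[<>]", "", s)
  }
  parse1 <- function(x, strand) {
    if (grepl("^complement\\(", x)) {
      inner <- substr(x, 12L, nchar(x) - 1L)
      return(parse1(inner, if (strand == "+") "-" else "+"))
    }
    if (grepl("^(join|order)\\(", x)) {
      open <- regexpr("\\(", x)
      inner <- substr(x, open + 1L, nchar(x) - 1L)
      parts <- split_top_level(inner)
      segs <- lapply(parts, function(p) parse1(p, strand)$segments)
      return(list(strand = strand, segments = do.call(rbind, segs)))
    }
    if (grepl("^\\d+\\.\\.\\d+$", x)) {
      ab <- as.integer(strsplit(x, "\\.\\.")[[1]])
      return(list(strand = strand, segments = matrix(ab, nrow = 1)))
    }
    if (grepl("^\\d+$", x)) {
      a <- as.integer(x)
      return(list(strand = strand, segments = matrix(c(a, a), nrow = 1)))
    }
    stop("unparseable location: ", x)
  }
  parse1(s, "+")
}

split_top_level <- function(s) {
  depth <- 0L
  cuts <- integer(0)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "(") depth <- depth + 1L
    else if (c == ")") depth <- depth - 1L
    else if (c == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

parse_gb_qualifiers <- function(qlines) {
  vals <- list()
  pseudo <- FALSE
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) {
      v <- gsub('^"|"$', "", cur_val)
      vals[[cur_key]] <<- v
    }
  }
  for (ln in qlines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      flush()
      eq <- regexpr("=", t)
      if (eq > 0L) {
        cur_key <- substr(t, 2L, eq - 1L)
        cur_val <- substr(t, eq + 1L, nchar(t))
      } else {
        cur_key <- substr(t, 2L, nchar(t))
        cur_val <- "TRUE"
        if (cur_key == "pseudo") pseudo <- TRUE
      }
    } else if (!is.null(cur_key)) {
      sep <- if (cur_key %in% c("translation")) "" else " "
      cur_val <- paste(cur_val, t, sep = sep)
    }
  }
  flush()
  list(values = vals, pseudo = pseudo)
}

#' @export
print.AnnotatedRecord <- function(x, ...) {
  cat("AnnotatedRecord", x$id, "-", format(x$length, big.mark = ","),
      "bp,", length(x$features), "features\n")
  invisible(x)
}
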