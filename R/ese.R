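# Exonic splice enhancer (ESE) hexamer sets and window statistics.

.ESE_SET_NAMES <- c("RESCUE-ESE", "ESR", "Ke-ESE400", "PESE", "INT3")

.builtin_ese_path <- function(name) {
  fname <- paste0(gsub("[^A-Za-z0-9]+", "_", tolower(name)), ".txt")
  system.file("extdata", "ese_sets", fname, package = "intronless")
}

#' List the recognized predefined ESE set names
#'
#' The five published hexamer ESE collections the design method recognizes:
#' RESCUE-ESE, ESR, Ke-ESE400, PESE, and their at-least-3-of-4 intersection
#' INT3. A set is usable only if its motif file is bundled or supplied by
#' the user; the published lists are distributed as supplements of their
#' source papers.
#'
#' @return A data frame with columns `name` and `bundled`.
#' @export
list_ese_sets <- function() {
  data.frame(
    name = .ESE_SET_NAMES,
    bundled = vapply(.ESE_SET_NAMES,
                     function(n) nzchar(.builtin_ese_path(n)), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Load a set of hexamer ESE motifs
#'
#' Accepts a predefined set name (see [list_ese_sets()]), a motif-list file,
#' or motif lines directly. The file format is one hexamer per line; `#`
#' comments and blank lines are ignored. U is normalized to T (some
#' published lists use the RNA alphabet), motifs are upper-cased and
#' deduplicated. Every motif must have length exactly 6 over ACGT.
#'
#' @param name One of the five predefined set names.
#' @param file Path to a motif-list file.
#' @param motifs Character vector of motifs (or raw lines).
#' @param label Set label used in reports (defaults to name/file/"user").
#' @return An object of class `ese_set` with fields `name` and `motifs`.
#' @export
load_ese_set <- function(name = NULL, file = NULL, motifs = NULL,
                         label = NULL) {
  n_src <- sum(!is.null(name), !is.null(file), !is.null(motifs))
  if (n_src != 1L) {
    stop("supply exactly one of 'name', 'file' or 'motifs'", call. = FALSE)
  }
  if (!is.null(name)) {
    if (!name %in% .ESE_SET_NAMES) {
      stop("unknown ESE set '", name, "'; recognized sets: ",
           paste(.ESE_SET_NAMES, collapse = ", "), call. = FALSE)
    }
    path <- .builtin_ese_path(name)
    if (!nzchar(path)) {
      stop("ESE set '", name, "' is not bundled with this installation; ",
           "supply its published motif list via 'file'", call. = FALSE)
    }
    file <- path
    if (is.null(label)) label <- name
  }
  lines <- if (!is.null(file)) readLines(file) else .as_lines(motifs)
  lines <- sub("#.*$", "", lines)
  lines <- gsub("[[:space:]]", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty ESE motif set", call. = FALSE)
  m <- chartr("u", "t", lines)
  m <- toupper(chartr("U", "T", m))
  bad_len <- nchar(m) != 6L
  if (any(bad_len)) {
    i <- which(bad_len)[1]
    stop("motif '", lines[i], "' (line ", i, ") has length ",
         nchar(m[i]), ", expected 6", call. = FALSE)
  }
  bad_chr <- grepl("[^ACGT]", m)
  if (any(bad_chr)) {
    stop("motif '", lines[which(bad_chr)[1]],
         "' contains characters outside ACGT/U", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (!is.null(file)) basename(file) else "user"
  }
  structure(list(name = label, motifs = unique(m)), class = "ese_set")
}

#' @export
print.ese_set <- function(x, ...) {
  cat("<ese_set> ", x$name, ": ", length(x$motifs), " hexamers\n", sep = "")
  invisible(x)
}

#' Hexamer windows covering a position
#'
#' All 0-based start offsets of hexamer windows that contain `position` and
#' fit inside a sequence of length `seq_length`.
#'
#' @param position 0-based nucleotide offset.
#' @param seq_length Sequence length.
#' @return Integer vector of 0-based window starts (possibly empty).
#' @export
overlapping_windows <- function(position, seq_length) {
  stopifnot(position >= 0L, position < seq_length)
  lo <- max(0L, position - 5L)
  hi <- min(position, seq_length - 6L)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

.new_ese_density <- function(match_count, window_count) {
  structure(
    list(match_count = as.integer(match_count),
         window_count = as.integer(window_count),
         density = if (window_count > 0) match_count / window_count else 0),
    class = "ese_density"
  )
}

#' Count ESE hexamer matches in a region
#'
#' Counts the hexamer windows lying fully within the region whose 6-mer is
#' in the motif set. All overlapping matches count (no masking). The number
#' of windows is `max(0, region length - 5)`; the density is the matched
#' fraction (0 for degenerate regions shorter than 6 nt).
#'
#' @param seq Nucleotide string.
#' @param set An [load_ese_set()] object.
#' @param start,end Region bounds, 1-based inclusive (default: whole
#'   sequence).
#' @return An `ese_density` object with fields `match_count`,
#'   `window_count`, `density`.
#' @export
ese_match_count <- function(seq, set, start = 1L, end = nchar(seq)) {
  stopifnot(inherits(set, "ese_set"), start >= 1L, end <= nchar(seq))
  seq <- toupper(seq)
  len <- end - start + 1L
  if (len < 6L) return(.new_ese_density(0L, 0L))
  region <- substr(seq, start, end)
  starts <- seq_len(len - 5L)
  windows <- substring(region, starts, starts + 5L)
  .new_ese_density(sum(windows %in% set$motifs), len - 5L)
}
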