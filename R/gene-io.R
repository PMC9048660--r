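# Reading genes from GenBank / FASTA, intron removal, output writing.
#
# Coordinates are 0-based half-open internally; user-facing reports are
# 1-based inclusive.

#' Construct a gene record
#'
#' A gene body as ordered exons and introns, plus optional fixed 5'/3'
#' flanking sequences. The concatenated exons are the CDS: they must have
#' length a positive multiple of 3 and contain only ACGT. A missing ATG
#' start or terminal stop is a warning unless `allow_partial` is set.
#'
#' @param exons Character vector of exon sequences, transcript order.
#' @param introns Character vector of intron sequences; must be one shorter
#'   than `exons` (zero introns allowed for a single exon).
#' @param id,description Identifier and free-text description.
#' @param five_prime_flank,three_prime_flank Optional flanking sequences;
#'   never modified or recoded downstream.
#' @param allow_partial Suppress the start/stop warning for partial CDSs.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(exons, introns = character(0), id = "gene",
                        description = "", five_prime_flank = "",
                        three_prime_flank = "", allow_partial = FALSE) {
  exons <- toupper(as.character(exons))
  introns <- toupper(as.character(introns))
  if (length(exons) < 1L) stop("at least one exon is required", call. = FALSE)
  if (length(introns) != length(exons) - 1L) {
    stop("expected ", length(exons) - 1L, " introns for ", length(exons),
         " exons, got ", length(introns), call. = FALSE)
  }
  seqs <- c(exons, introns,
            toupper(five_prime_flank), toupper(three_prime_flank))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("sequence contains characters outside ACGT", call. = FALSE)
  }
  if (any(nchar(c(exons, introns)) == 0L)) {
    stop("exons and introns must be non-empty", call. = FALSE)
  }
  cds <- paste(exons, collapse = "")
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3", call. = FALSE)
  }
  if (!allow_partial) {
    if (substr(cds, 1L, 3L) != "ATG") {
      warning("CDS does not begin with ATG (partial CDS?)", call. = FALSE)
    }
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% .STOP_CODONS) {
      warning("CDS does not end with a stop codon (partial CDS?)",
              call. = FALSE)
    }
  }
  structure(
    list(id = id, description = description, exons = exons,
         introns = introns,
         five_prime_flank = toupper(five_prime_flank),
         three_prime_flank = toupper(three_prime_flank)),
    class = "gene_record"
  )
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record> ", x$id, "\n", sep = "")
  cat("  exons:  ", length(x$exons), " (", sum(nchar(x$exons)), " nt CDS)\n",
      sep = "")
  cat("  introns:", length(x$introns), "\n")
  if (nzchar(x$five_prime_flank) || nzchar(x$three_prime_flank)) {
    cat("  flanks: 5'=", nchar(x$five_prime_flank), " nt, 3'=",
        nchar(x$three_prime_flank), " nt\n", sep = "")
  }
  invisible(x)
}

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
}

#' Parse a FASTA gene body
#'
#' Exon/intron structure is encoded by case: UPPERCASE runs are exons,
#' lowercase runs are introns (soft-masking-style convention). The record
#' must start and end in an exon. Sequence is normalized to upper case
#' internally.
#'
#' @param text FASTA content (single string or character vector of lines).
#'   Exactly one of `text`/`file`.
#' @param file Path to a FASTA file.
#' @param allow_partial Tolerate a CDS without ATG start / stop end.
#' @return A [gene_record()].
#' @export
parse_fasta <- function(text = NULL, file = NULL, allow_partial = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  }
  src <- if (is.null(file)) textConnection(.as_lines(text)) else file
  recs <- seqinr::read.fasta(src, forceDNAtolower = FALSE, as.string = TRUE,
                             seqtype = "DNA")
  if (length(recs) != 1L) {
    stop("expected exactly 1 FASTA record, found ", length(recs),
         call. = FALSE)
  }
  s <- as.character(recs[[1]])
  annot <- sub("^>\\s*\\S*\\s*", "", attr(recs[[1]], "Annot"))
  chars <- strsplit(s, "")[[1]]
  if (any(!toupper(chars) %in% c("A", "C", "G", "T"))) {
    stop("sequence contains characters outside ACGT/acgt", call. = FALSE)
  }
  lower <- chars %in% letters
  runs <- rle(lower)
  if (runs$values[1] || runs$values[length(runs$values)]) {
    stop("gene body must start and end in an exon (uppercase)",
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  segs <- toupper(substring(s, starts, ends))
  gene_record(
    exons = segs[!runs$values], introns = segs[runs$values],
    id = attr(recs[[1]], "name"), description = annot,
    allow_partial = allow_partial
  )
}

# --- GenBank flat-file subset: LOCUS / FEATURES CDS (join, complement) /
# ORIGIN. Other features and qualifiers are ignored.

.parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  comp <- FALSE
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- lapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2L)
    } else {
      stop("cannot parse CDS location part '", p, "'", call. = FALSE)
    }
  })
  list(complement = comp, intervals = iv)
}

#' Parse a GenBank flat file
#'
#' Honors a minimal dialect: a single LOCUS, the first CDS feature under
#' FEATURES (with `join()` and `complement()` locations), and the ORIGIN
#' sequence. Minus-strand CDS features are reverse-complemented into sense
#' orientation. Gaps between joined CDS intervals become introns.
#'
#' @inheritParams parse_fasta
#' @return A [gene_record()].
#' @export
parse_genbank <- function(text = NULL, file = NULL, allow_partial = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  }
  lines <- if (is.null(file)) .as_lines(text) else readLines(file)
  n_locus <- sum(grepl("^LOCUS", lines))
  if (n_locus != 1L) {
    stop("expected exactly 1 locus, found ", n_locus, call. = FALSE)
  }
  id <- sub("^LOCUS\\s+(\\S+).*", "\\1", lines[grepl("^LOCUS", lines)][1])
  def <- lines[grepl("^DEFINITION", lines)]
  description <- if (length(def)) sub("^DEFINITION\\s+", "", def[1]) else ""

  # CDS location: feature line plus indented continuation lines that are
  # not qualifiers and not a new feature key
  cds_at <- grep("^\\s{5}CDS\\s", lines)
  if (length(cds_at) == 0L) stop("no CDS feature found", call. = FALSE)
  loc <- sub("^\\s{5}CDS\\s+", "", lines[cds_at[1]])
  i <- cds_at[1] + 1L
  while (i <= length(lines) &&
         grepl("^\\s{10,}", lines[i]) &&
         !grepl("^\\s+/", lines[i])) {
    loc <- paste0(loc, gsub("\\s", "", lines[i]))
    i <- i + 1L
  }

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) stop("no ORIGIN sequence found", call. = FALSE)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1] else length(lines) + 1L
  seq_lines <- lines[seq(origin_at[1] + 1L, end_at - 1L)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  parsed <- .parse_location(loc)
  iv <- parsed$intervals
  starts <- vapply(iv, `[`, integer(1), 1L)
  ends <- vapply(iv, `[`, integer(1), 2L)
  if (any(starts > ends) || is.unsorted(starts, strictly = TRUE)) {
    stop("CDS intervals must be ordered and non-reversed", call. = FALSE)
  }
  if (any(starts < 1L) || any(ends > nchar(genome))) {
    stop("CDS interval outside sequence bounds (1..", nchar(genome), ")",
         call. = FALSE)
  }
  exons <- substring(genome, starts, ends)
  introns <- if (length(iv) > 1L) {
    substring(genome, head(ends, -1L) + 1L, tail(starts, -1L) - 1L)
  } else {
    character(0)
  }
  if (any(nchar(introns) == 0L)) {
    stop("adjacent CDS intervals leave no intron between them",
         call. = FALSE)
  }
  if (parsed$complement) {
    exons <- rev(vapply(exons, reverse_complement, character(1)))
    introns <- rev(vapply(introns, reverse_complement, character(1)))
  }
  gene_record(exons = unname(exons), introns = unname(introns), id = id,
              description = description, allow_partial = allow_partial)
}

#' Read a gene from file, auto-detecting the format
#'
#' @param path Input path.
#' @param format `"auto"` (GenBank if the file starts with LOCUS),
#'   `"genbank"` or `"fasta"`.
#' @param allow_partial Tolerate partial CDSs.
#' @return A [gene_record()].
#' @export
read_gene <- function(path, format = c("auto", "genbank", "fasta"),
                      allow_partial = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "fasta"
  }
  if (format == "genbank") {
    parse_genbank(file = path, allow_partial = allow_partial)
  } else {
    parse_fasta(file = path, allow_partial = allow_partial)
  }
}

#' Remove introns from a gene record
#'
#' Concatenates the exons into an intronless CDS and records the former
#' exon-exon junction offsets; these anchor the ESE vicinity windows. With
#' `keep_first` (the default) the first intron is retained for re-insertion
#' at output time and its boundary is *not* a junction (the intron still
#' exists, so no ESE adjustment applies there).
#'
#' @param gene A [gene_record()].
#' @param keep_first Retain the first intron (default `TRUE`).
#' @return An object of class `processed_gene` with fields `cds`,
#'   `junctions` (0-based CDS offsets of the first nucleotide after each
#'   removed intron), `retained_intron` (`NULL` or `list(seq, offset)`),
#'   and the flanks.
#' @export
remove_introns <- function(gene, keep_first = TRUE) {
  stopifnot(inherits(gene, "gene_record"))
  cds <- paste(gene$exons, collapse = "")
  n_introns <- length(gene$introns)
  boundary <- cumsum(nchar(gene$exons))[seq_len(n_introns)]
  retained <- NULL
  removed <- seq_len(n_introns)
  if (keep_first && n_introns >= 1L) {
    retained <- list(seq = gene$introns[1], offset = boundary[1])
    removed <- removed[-1L]
  }
  structure(
    list(cds = cds,
         junctions = as.integer(boundary[removed]),
         retained_intron = retained,
         five_prime_flank = gene$five_prime_flank,
         three_prime_flank = gene$three_prime_flank,
         id = gene$id),
    class = "processed_gene"
  )
}

#' @export
print.processed_gene <- function(x, ...) {
  cat("<processed_gene> ", x$id, ": ", nchar(x$cds), " nt CDS, ",
      length(x$junctions), " removed junction(s)",
      if (!is.null(x$retained_intron)) ", first intron retained" else "",
      "\n", sep = "")
  invisible(x)
}

# full construct: flanks + CDS with retained intron spliced back in
.assemble_construct <- function(processed, cds = processed$cds,
                                lower_intron = TRUE) {
  body <- cds
  if (!is.null(processed$retained_intron)) {
    ri <- processed$retained_intron
    intr <- if (lower_intron) tolower(ri$seq) else ri$seq
    body <- paste0(substr(cds, 1L, ri$offset), intr,
                   substr(cds, ri$offset + 1L, nchar(cds)))
  }
  paste0(processed$five_prime_flank, body, processed$three_prime_flank)
}

.write_fasta <- function(seqs, names, path) {
  seqinr::write.fasta(as.list(seqs), names, path, nbchar = 60L,
                      as.string = TRUE)
  invisible(path)
}

#' Write design outputs
#'
#' Writes four files under `prefix`: the best-variant FASTA (flanks and any
#' retained first intron re-inserted, intron in lowercase), a multi-FASTA of
#' all distinct variants, a per-site change table (TSV; 1-based CDS
#' positions) and a JSON summary with achieved GC3, ESE density before and
#' after, and the objective.
#'
#' @param best The best [variant].
#' @param cloud The full `variant_cloud`.
#' @param processed The `processed_gene` the cloud was generated from.
#' @param prefix Output path prefix.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_outputs <- function(best, cloud, processed, prefix) {
  stopifnot(inherits(cloud, "variant_cloud"),
            inherits(processed, "processed_gene"))
  paths <- c(best = paste0(prefix, "_best.fasta"),
             cloud = paste0(prefix, "_variants.fasta"),
             changes = paste0(prefix, "_changes.tsv"),
             summary = paste0(prefix, "_summary.json"))
  hdr <- function(v, i) {
    sprintf("%s|variant_%d|objective=%.6g|changes=%d",
            processed$id, i, v$objective, nrow(v$changes))
  }
  .write_fasta(.assemble_construct(processed, best$cds),
               hdr(best, cloud$best_index), paths["best"])

  seqs <- vapply(cloud$variants, `[[`, character(1), "cds")
  keep <- !duplicated(seqs)
  .write_fasta(
    lapply(which(keep), function(i) {
      .assemble_construct(processed, cloud$variants[[i]]$cds)
    }),
    vapply(which(keep), function(i) hdr(cloud$variants[[i]], i),
           character(1)),
    paths["cloud"]
  )

  ch <- best$changes
  tab <- data.frame(
    cds_position = if (nrow(ch)) ch$codon_index * 3L + 1L else integer(0),
    original_codon = ch$from, new_codon = ch$to,
    reason = ch$reason, stringsAsFactors = FALSE
  )
  utils::write.table(tab, paths["changes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summary <- list(
    gene = processed$id,
    n_variants = length(cloud$variants),
    n_distinct = sum(keep),
    best = list(
      objective = best$objective,
      n_changes = nrow(best$changes),
      gc3 = best$achieved_gc3,
      ese_density_vicinity = best$ese_density_vicinity$density
    ),
    input = list(
      gc3 = cloud$input_gc3,
      ese_density_vicinity = cloud$input_ese_density
    )
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
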