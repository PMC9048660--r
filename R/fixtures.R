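# Synthetic fixtures: toy genes with controlled GC3 and seeded ESE
# matches, and training corpora drawn from known position-dependent
# curves. Everything is a deterministic function of its seed, so tests
# need no external data.

# pick a third nucleotide for a box: GC-ending with probability p_gc,
# uniform within the chosen class; boxes offering one class use it
.draw_third <- function(box, p_gc) {
  gc <- intersect(box$nts, .GC_NUCS)
  at <- setdiff(box$nts, .GC_NUCS)
  pool <- if (length(gc) == 0L) at
  else if (length(at) == 0L) gc
  else if (stats::runif(1) < p_gc) gc else at
  pool[sample.int(length(pool), 1L)]
}

#' Generate a toy gene record
#'
#' A random gene with a valid CDS (ATG start, single terminal stop, no
#' internal stops), third positions G/C with probability `gc3_bias` at
#' degenerate sites, and introns with canonical GT..AG ends. Exon lengths
#' need not be codon-aligned; frame is tracked across junctions.
#' Optionally plants ESE motif matches (codon-aligned, non-stop-creating)
#' inside the vicinity windows of the exon junctions.
#'
#' @param exon_lengths Integer vector of exon lengths; their sum must be a
#'   multiple of 3 and at least 9 (start + 1 codon + stop).
#' @param intron_lengths Integer vector, one per junction (each >= 4).
#' @param gc3_bias Probability of G/C at degenerate third positions.
#' @param motif_seeding Optional `list(set = <ese_set>, count = <k>)`:
#'   plant `k` motif matches within `vicinity_nt` of the junctions.
#' @param vicinity_nt Vicinity half-width used for seeding; default 70.
#' @param seed Integer seed; the record is fully determined by it.
#' @param id Record identifier.
#' @return A [gene_record()].
#' @export
make_toy_gene <- function(exon_lengths, intron_lengths = integer(0),
                          gc3_bias = 0.5, motif_seeding = NULL,
                          vicinity_nt = 70L, seed = 1L, id = "toy") {
  stopifnot(length(exon_lengths) == length(intron_lengths) + 1L,
            all(exon_lengths > 0L), all(intron_lengths >= 4L))
  total <- sum(exon_lengths)
  if (total %% 3L != 0L || total < 9L) {
    stop("exon lengths must sum to a multiple of 3 that is >= 9",
         call. = FALSE)
  }
  set.seed(seed)
  n_codons <- total %/% 3L
  aas <- setdiff(names(.FAMILIES), "*")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (k in seq(2L, n_codons - 1L)) {
    aa <- aas[sample.int(length(aas), 1L)]
    boxes <- .SUB_BOXES[[aa]]
    box_codons <- boxes[[sample.int(length(boxes), 1L)]]
    box <- .BOXES[[.box_id(box_codons)]]
    codons[k] <- paste0(box$prefix, .draw_third(box, gc3_bias))
  }
  codons[n_codons] <- .STOP_CODONS[sample.int(3L, 1L)]
  cds <- paste(codons, collapse = "")

  if (!is.null(motif_seeding)) {
    cds <- .plant_motifs(cds, exon_lengths, motif_seeding, vicinity_nt)
  }

  bounds <- cumsum(exon_lengths)
  exons <- substring(cds, c(1L, utils::head(bounds, -1L) + 1L), bounds)
  introns <- vapply(intron_lengths, function(L) {
    paste0("GT",
           paste(sample(c("A", "C", "G", "T"), L - 4L, replace = TRUE),
                 collapse = ""),
           "AG")
  }, character(1))
  gene_record(exons = exons, introns = introns, id = id,
              description = "synthetic toy gene")
}

.plant_motifs <- function(cds, exon_lengths, motif_seeding, vicinity_nt) {
  set <- motif_seeding$set
  k <- motif_seeding$count
  stopifnot(inherits(set, "ese_set"), k >= 1L)
  # motifs whose two codon-aligned codons are both sense codons
  ok <- vapply(set$motifs, function(m) {
    !substr(m, 1L, 3L) %in% .STOP_CODONS &&
      !substr(m, 4L, 6L) %in% .STOP_CODONS
  }, logical(1))
  if (!any(ok)) {
    stop("no motif in the set can be planted without creating a stop",
         call. = FALSE)
  }
  motifs <- set$motifs[ok]
  cds_len <- nchar(cds)
  junctions <- utils::head(cumsum(exon_lengths), -1L)  # 0-based offsets
  # candidate codon-aligned 0-based offsets inside vicinity windows,
  # avoiding the start and stop codons
  slots <- sort(unique(unlist(lapply(junctions, function(j) {
    from <- max(3L, j - vicinity_nt)
    to <- min(cds_len - 9L, j + vicinity_nt - 6L)
    if (to < from) return(integer(0))
    s <- seq.int(from, to)
    s[s %% 3L == 0L]
  }))))
  # keep slots 6 nt apart so planted matches never overlap
  picked <- integer(0)
  for (s in slots[sample.int(length(slots))]) {
    if (all(abs(s - picked) >= 6L)) picked <- c(picked, s)
    if (length(picked) == k) break
  }
  if (length(picked) < k) {
    stop("cannot plant ", k, " non-overlapping matches in the vicinity ",
         "windows (", length(picked), " slots available)", call. = FALSE)
  }
  for (s in picked) {
    m <- motifs[sample.int(length(motifs), 1L)]
    substr(cds, s + 1L, s + 6L) <- m
  }
  cds
}

#' Generate a training corpus with known position-dependent curves
#'
#' Each CDS starts with ATG, ends with a stop, and draws every internal
#' codon's box uniformly; the third nucleotide is G/C-class with
#' probability `floor + (ceiling - floor) * exp(-i / tau)` at 0-based
#' codon index `i` (uniform within the class), the generative model that
#' [fit_position_curves()] reconstructs.
#'
#' @param n Number of CDSs.
#' @param n_codons Codons per CDS (including start and stop).
#' @param floor,ceiling,tau Curve parameters of the GC-class probability.
#' @param seed Integer seed.
#' @return Character vector of `n` CDS strings.
#' @export
make_training_corpus <- function(n, n_codons = 300L, floor = 0.2,
                                 ceiling = 0.6, tau = 40, seed = 1L) {
  stopifnot(n >= 1L, n_codons >= 3L, tau > 0)
  set.seed(seed)
  box_ids <- names(.BOXES)
  gc_by_box <- lapply(.BOXES, function(b) intersect(b$nts, .GC_NUCS))
  at_by_box <- lapply(.BOXES, function(b) setdiff(b$nts, .GC_NUCS))
  prefix <- vapply(.BOXES, `[[`, character(1), "prefix")

  n_int <- n_codons - 2L
  total <- n * n_int
  idx <- rep(seq_len(n_int), n)                 # 0-based index is idx
  p_gc <- floor + (ceiling - floor) * exp(-idx / tau)
  bx <- sample(box_ids, total, replace = TRUE)
  third <- character(total)
  u <- stats::runif(total)
  for (id in box_ids) {
    sel <- bx == id
    if (!any(sel)) next
    gc <- gc_by_box[[id]]; at <- at_by_box[[id]]
    if (length(gc) == 0L) {
      third[sel] <- sample(at, sum(sel), replace = TRUE)
    } else if (length(at) == 0L) {
      third[sel] <- sample(gc, sum(sel), replace = TRUE)
    } else {
      use_gc <- u[sel] < p_gc[sel]
      pick <- character(sum(sel))
      pick[use_gc] <- sample(gc, sum(use_gc), replace = TRUE)
      pick[!use_gc] <- sample(at, sum(!use_gc), replace = TRUE)
      third[sel] <- pick
    }
  }
  codon <- paste0(prefix[bx], third)
  stops <- sample(.STOP_CODONS, n, replace = TRUE)
  vapply(seq_len(n), function(g) {
    paste0("ATG",
           paste(codon[((g - 1L) * n_int + 1L):(g * n_int)],
                 collapse = ""),
           stops[g])
  }, character(1))
}

#' Write a gene record as case-convention FASTA
#'
#' Exons uppercase, introns lowercase, 60-character lines; the format
#' [parse_fasta()] reads back. Flanks are not encoded.
#'
#' @param gene A [gene_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_fasta <- function(gene, path) {
  stopifnot(inherits(gene, "gene_record"))
  segs <- character(length(gene$exons) + length(gene$introns))
  segs[seq_along(gene$exons) * 2L - 1L] <- gene$exons
  if (length(gene$introns)) {
    segs[seq_along(gene$introns) * 2L] <- tolower(gene$introns)
  }
  .write_fasta(paste(segs, collapse = ""),
               paste(gene$id, gene$description), path)
}

#' Write a gene record as a minimal GenBank flat file
#'
#' Single LOCUS, one CDS feature with a `join()` over the exon intervals,
#' ORIGIN sequence; the dialect [parse_genbank()] reads back.
#'
#' @inheritParams write_gene_fasta
#' @return Invisibly, `path`.
#' @export
write_gene_genbank <- function(gene, path) {
  stopifnot(inherits(gene, "gene_record"))
  segs <- character(length(gene$exons) + length(gene$introns))
  segs[seq_along(gene$exons) * 2L - 1L] <- gene$exons
  if (length(gene$introns)) {
    segs[seq_along(gene$introns) * 2L] <- gene$introns
  }
  genome <- paste(segs, collapse = "")
  ex_len <- nchar(gene$exons)
  in_len <- nchar(gene$introns)
  starts <- integer(length(ex_len))
  pos <- 1L
  for (i in seq_along(ex_len)) {
    starts[i] <- pos
    pos <- pos + ex_len[i] + if (i <= length(in_len)) in_len[i] else 0L
  }
  ends <- starts + ex_len - 1L
  loc <- paste(sprintf("%d..%d", starts, ends), collapse = ",")
  if (length(ex_len) > 1L) loc <- paste0("join(", loc, ")")

  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", gene$id,
            nchar(genome)),
    sprintf("DEFINITION  %s", gene$description),
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             %s", loc),
    "ORIGIN"
  )
  seq_lines <- vapply(seq(1L, nchar(genome), 60L), function(s) {
    chunk <- substr(genome, s, min(s + 59L, nchar(genome)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L),
                             nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1))
  writeLines(c(lines, seq_lines, "//"), path)
  invisible(path)
}
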