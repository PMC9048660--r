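# Genetic-code bookkeeping: codon families, 6-fold sub-boxes, codon boxes.
#
# A "box" is a set of synonymous codons sharing their first two nucleotides;
# 6-fold families (Leu, Ser, Arg) split into a 4-fold and a 2-fold sub-box,
# every other family is a single box. Boxes are the unit over which
# third-position probability curves are defined.

.GENETIC_CODE <- c(Biostrings::GENETIC_CODE)

.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]

# amino acid -> codons
.FAMILIES <- split(names(.GENETIC_CODE), .GENETIC_CODE)

# sub-box partition per amino acid: 6-fold families split 4+2, all others
# are a single sub-box
.SUB_BOXES <- local({
  fams <- .FAMILIES
  sb <- lapply(fams, function(x) list(x))
  sb[["L"]] <- list(c("CTT", "CTC", "CTA", "CTG"), c("TTA", "TTG"))
  sb[["S"]] <- list(c("TCT", "TCC", "TCA", "TCG"), c("AGT", "AGC"))
  sb[["R"]] <- list(c("CGT", "CGC", "CGA", "CGG"), c("AGA", "AGG"))
  sb
})

.IUPAC_OF_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "AC" = "M", "GT" = "K", "CG" = "S", "AT" = "W",
  "ACT" = "H", "CGT" = "B", "ACG" = "V", "AGT" = "D", "ACGT" = "N"
)

.box_id <- function(codons) {
  third <- sort(unique(substr(codons, 3, 3)))
  paste0(substr(codons[1], 1, 2), .IUPAC_OF_SET[[paste(third, collapse = "")]])
}

# box tables: codon -> box id; box id -> list(prefix, nts, codons, aa)
.BOXES <- local({
  boxes <- list()
  for (aa in names(.SUB_BOXES)) {
    if (aa == "*") next
    for (codons in .SUB_BOXES[[aa]]) {
      id <- .box_id(codons)
      boxes[[id]] <- list(
        id = id, aa = aa, prefix = substr(codons[1], 1, 2),
        nts = sort(unique(substr(codons, 3, 3))), codons = codons
      )
    }
  }
  boxes
})

.CODON_BOX <- local({
  m <- character(0)
  for (b in .BOXES) {
    m[b$codons] <- b$id
  }
  m
})

.GC_NUCS <- c("G", "C")

#' Split a coding sequence into codons
#'
#' @param cds Nucleotide string whose length is a multiple of 3.
#' @return Character vector of codons, 5' to 3'.
#' @export
seq_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code; trailing stop translates to `*`.
#'
#' @param cds Nucleotide string, length a multiple of 3, alphabet ACGT.
#' @return Single amino-acid string.
#' @export
translate_cds <- function(cds) {
  codons <- seq_codons(toupper(cds))
  aa <- .GENETIC_CODE[codons]
  if (anyNA(aa)) {
    bad <- codons[is.na(aa)][1]
    stop("invalid codon '", bad, "' in CDS", call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Synonymous codon candidates for a site
#'
#' Returns the codons considered interchangeable at a site. Under the
#' default `full_box` policy all synonyms of the amino acid are candidates
#' (six for Leu/Ser/Arg); under `sub_box` only the 4-fold or 2-fold sub-box
#' containing the input codon is considered.
#'
#' @param codon A sense codon (uppercase ACGT).
#' @param policy `"full_box"` (default) or `"sub_box"`.
#' @return Character vector of candidate codons, always containing `codon`.
#' @export
synonymous_candidates <- function(codon, policy = c("full_box", "sub_box")) {
  policy <- match.arg(policy)
  codon <- toupper(codon)
  aa <- .GENETIC_CODE[codon]
  if (is.na(aa)) stop("'", codon, "' is not a codon", call. = FALSE)
  if (aa == "*") stop("stop codons are immutable", call. = FALSE)
  if (policy == "full_box") {
    unname(.FAMILIES[[aa]])
  } else {
    boxes <- .SUB_BOXES[[aa]]
    boxes[[which(vapply(boxes, function(b) codon %in% b, logical(1)))]]
  }
}

# positions (1..3) at which a candidate set is variable
.variable_positions <- function(candidates) {
  if (length(candidates) < 2L) return(integer(0))
  which(vapply(1:3, function(p) {
    length(unique(substr(candidates, p, p))) > 1L
  }, logical(1)))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
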