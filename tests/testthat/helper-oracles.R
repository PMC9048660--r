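# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately use naive enumeration (or Biostrings)
# rather than any code path they check.

# all 0-based hexamer window starts containing `position`, by enumeration
bf_windows <- function(position, seq_length) {
  if (seq_length < 6L) return(integer(0))
  starts <- 0:(seq_length - 6L)
  starts[starts <= position & position <= starts + 5L]
}

# count motif-set matches among all hexamer windows inside [start, end]
# (1-based inclusive), by direct comparison
bf_match_count <- function(seq, motifs, start = 1L, end = nchar(seq)) {
  n_match <- 0L
  for (s in seq_len(nchar(seq))) {
    if (s < start || s + 5L > end) next
    if (substr(seq, s, s + 5L) %in% motifs) n_match <- n_match + 1L
  }
  n_match
}

# both-strand IUPAC match intervals via Biostrings (0-based half-open)
oracle_matches <- function(seq, pattern) {
  subj <- Biostrings::DNAString(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  starts <- integer(0)
  for (p in unique(c(pattern, rc))) {
    v <- Biostrings::matchPattern(p, subj, fixed = FALSE)
    starts <- c(starts, BiocGenerics::start(v))
  }
  starts <- sort(unique(starts))
  data.frame(start = starts - 1L, end = starts - 1L + nchar(pattern))
}

# every synonymous recoding of a short CDS honoring the site plan's
# mutability, by exhaustive expansion
enumerate_synonymous <- function(processed, plan, config) {
  codons <- seq_codons(processed$cds)
  opts <- lapply(seq_along(codons), function(i) {
    if (!plan$mutable[i]) codons[i]
    else synonymous_candidates(codons[i], config$sixfold_policy)
  })
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a minimal two-exon gene record with chosen exon lengths
tiny_gene <- function(exon_lengths = c(30L, 30L), seed = 1L, ...) {
  make_toy_gene(exon_lengths,
                intron_lengths = rep(10L, length(exon_lengths) - 1L),
                seed = seed, ...)
}

toy_ese_set <- function(motifs = c("GAAGAA", "AAGAAG", "TTCTTC")) {
  load_ese_set(motifs = motifs)
}
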