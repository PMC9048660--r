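test_that("restriction matching covers both strands and IUPAC codes", {
  m <- find_restriction_matches("AAGAATTCAA", "GAATTC")
  expect_identical(m$start, 2L)
  expect_identical(m$end, 8L)
  # BsaI site present only as its reverse complement GAGACC
  m2 <- find_restriction_matches("AAGAGACCAA", "GGTCTC")
  expect_identical(m2$start, 2L)
  expect_identical(m2$end, 8L)
  m3 <- find_restriction_matches("AAGCTTGCAA", "GCNNGC")
  expect_true(any(m3$start == 2L & m3$end == 8L))
  expect_error(find_restriction_matches("ACGT", "GAAXTC"), "X")
})

test_that("restriction matching agrees with a Biostrings oracle", {
  set.seed(21)
  pats <- c("GAATTC", "GGTCTC", "GCNNGC", "RGGNCCY", "CCWGG")
  for (r in 1:30) {
    seq <- random_dna(sample(50:200, 1))
    p <- sample(pats, 1)
    got <- find_restriction_matches(seq, p)
    want <- oracle_matches(seq, p)
    expect_identical(got$start, want$start, info = paste(p, seq))
    expect_identical(got$end, want$end)
  }
})

test_that("site plans mark start, stop, no-synonym and protected codons", {
  g <- gene_record("ATGTGGAAACTGGAATTCTAA")  # M W K L E F *
  proc <- remove_introns(g)
  cfg <- design_config("max_gc", protect_enzymes = "GAATTC",
                       n_variants = 1)
  plan <- build_site_plan(proc, cfg)
  expect_identical(plan$reason[1], "start")
  expect_identical(plan$reason[2], "no_synonyms")       # Trp
  expect_identical(plan$reason[7], "stop")
  # GAATTC spans CDS offsets 12..17 -> codons 4 and 5 (0-based) protected
  expect_identical(plan$reason[plan$codon_index %in% c(4L, 5L)],
                   c("restriction", "restriction"))
  expect_true(plan$mutable[3])                          # Lys codon
  expect_false(any(plan$ese_eligible))                  # ese_mode off
})

test_that("ESE eligibility follows the vicinity window arithmetic", {
  set <- toy_ese_set()
  g <- make_toy_gene(c(300L, 300L), 20L, seed = 2)
  proc <- remove_introns(g, keep_first = FALSE)       # junction at 300
  cfg <- design_config("max_gc", ese_mode = "decrease", ese_set = set,
                       n_variants = 1)
  plan <- build_site_plan(proc, cfg)
  # codons with any nucleotide in [230, 370) are eligible
  eligible <- which(plan$ese_eligible) - 1L
  starts <- eligible * 3L
  expect_true(all(starts + 3L > 230L & starts < 370L))
  expect_identical(min(eligible), 230L %/% 3L)
  expect_identical(max(eligible), 369L %/% 3L)

  # a retained first intron suppresses its junction's vicinity
  g2 <- make_toy_gene(c(300L, 300L, 300L), c(20L, 20L), seed = 2)
  p_keep <- remove_introns(g2, keep_first = TRUE)
  expect_identical(p_keep$junctions, 600L)
  plan2 <- build_site_plan(p_keep, cfg)
  el2 <- (which(plan2$ese_eligible) - 1L) * 3L
  expect_true(all(el2 + 3L > 530L & el2 < 670L))

  # core expansion makes every sense codon eligible
  cfg3 <- design_config("max_gc", ese_mode = "decrease", ese_set = set,
                        ese_in_cores = TRUE, n_variants = 1)
  plan3 <- build_site_plan(proc, cfg3)
  expect_true(all(plan3$ese_eligible[-nrow(plan3)]))
})

test_that("a gene with no mutable sites returns itself", {
  g <- gene_record("ATGTGGTAA")
  proc <- remove_introns(g)
  cfg <- design_config("max_gc", n_variants = 1, seed = 1)
  plan <- build_site_plan(proc, cfg)
  set.seed(1)
  v <- generate_variant(proc, plan, gc_target_model("max_gc"), cfg)
  expect_identical(v$cds, "ATGTGGTAA")
  expect_identical(nrow(v$changes), 0L)
})

test_that("variants always translate to the input protein", {
  set.seed(30)
  for (r in 1:15) {
    g <- make_toy_gene(c(sample(30:90, 1) * 3L), gc3_bias = runif(1),
                       seed = r + 100)
    proc <- remove_introns(g)
    strat <- sample(c("max_gc", "one_two_exon", "human_usage"), 1)
    cfg <- design_config(strat, n_variants = 4, seed = r)
    plan <- build_site_plan(proc, cfg)
    cloud <- generate_cloud(proc, plan, gc_target_model(strat), cfg)
    for (v in cloud$variants) {
      expect_identical(translate_cds(v$cds), translate_cds(proc$cds))
    }
  }
})

test_that("protected restriction sites survive recoding verbatim", {
  set.seed(31)
  pats <- c("GAATTC", "GGATCC", "GGTCTC")
  for (r in 1:20) {
    g <- make_toy_gene(c(120L), gc3_bias = 0.3, seed = r + 300)
    proc <- remove_introns(g)
    p <- sample(pats, 2)
    cfg <- design_config("max_gc", protect_enzymes = p, n_variants = 3,
                         seed = r)
    plan <- build_site_plan(proc, cfg)
    before <- find_restriction_matches(proc$cds, p)
    cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
    for (v in cloud$variants) {
      for (h in seq_len(nrow(before))) {
        expect_identical(
          substr(v$cds, before$start[h] + 1L, before$end[h]),
          substr(proc$cds, before$start[h] + 1L, before$end[h])
        )
      }
    }
  }
})

test_that("blacklisted motifs are never newly introduced", {
  set.seed(32)
  for (r in 1:20) {
    g <- make_toy_gene(c(90L), gc3_bias = 0.5, seed = r + 500)
    proc <- remove_introns(g)
    motifs <- c("GAATTC", "GCGCGC", "CCSGG")
    cfg <- design_config("max_gc", avoid_motifs = motifs, n_variants = 3,
                         seed = r)
    plan <- build_site_plan(proc, cfg)
    cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
    for (m in motifs) {
      before <- find_restriction_matches(proc$cds, m)
      key0 <- paste(before$start, before$end)
      for (v in cloud$variants) {
        after <- find_restriction_matches(v$cds, m)
        new <- setdiff(paste(after$start, after$end), key0)
        expect_length(new, 0)
      }
    }
  }
})

test_that("a forced blacklist conflict leaves the site as is", {
  # Asn codon AAT: the only alternative AAC would complete GAATTC? No -
  # construct: context GA|AAT|TC.. -> alternative AAC gives GAACTC (no),
  # use Phe TTT -> TTC inside GAA_TTC: GAATTTC? Simpler direct case:
  # CDS ...GA ATT C...: Ile ATT, alternatives ATC/ATA; with avoid motif
  # GAATTC absent before, candidate ATC at GA|ATT|C -> GAATCC no.
  # Take Glu GAA followed by TTC (Phe): GAA TTC has GAATTC already; use
  # Lys AAA -> AAG creates no match. Instead test Glu GAG -> GAA before
  # TTC would create GAATTC:
  g <- gene_record("ATGGAGTTCTAA")  # M E F *
  proc <- remove_introns(g)
  cfg <- design_config("max_gc", avoid_motifs = "GAATTC",
                       ese_mode = "off", n_variants = 50, seed = 4)
  plan <- build_site_plan(proc, cfg)
  cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
  for (v in cloud$variants) {
    expect_length(find_restriction_matches(v$cds, "GAATTC")$start, 0)
  }
})

test_that("blacklist checks see flanks and the retained intron", {
  # 3' flank begins TTC: recoding a terminal Glu codon GAG -> GAA would
  # create GAATTC spanning the CDS/flank boundary (partial CDS so the
  # codon sits flush against the flank)
  g <- suppressWarnings(
    gene_record("ATGGAG", three_prime_flank = "TTCAAAAA",
                allow_partial = TRUE))
  proc <- remove_introns(g)
  cfg <- design_config("max_gc", avoid_motifs = "GAATTC",
                       n_variants = 40, seed = 6)
  plan <- build_site_plan(proc, cfg)
  cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
  for (v in cloud$variants) {
    construct <- paste0(v$cds, "TTCAAAAA")
    expect_length(find_restriction_matches(construct, "GAATTC")$start, 0)
  }
})

test_that("decrease mode lowers vicinity ESE matches", {
  set <- toy_ese_set(c("GAAGAA", "AAGAAG"))
  g <- make_toy_gene(c(150L, 150L), 20L, gc3_bias = 0.4,
                     motif_seeding = list(set = set, count = 4),
                     seed = 17)
  proc <- remove_introns(g, keep_first = FALSE)
  cfg <- design_config("ese_only", ese_mode = "decrease", ese_set = set,
                       lambda = 1, n_variants = 40, seed = 5)
  plan <- build_site_plan(proc, cfg)
  cloud <- generate_cloud(proc, plan, gc_target_model("ese_only"), cfg)
  best <- cloud$variants[[cloud$best_index]]
  expect_lte(best$ese_density_vicinity$density, cloud$input_ese_density)
})

test_that("the objective ranks fewer vicinity matches lower in decrease mode", {
  set <- toy_ese_set("GAAGAA")
  g <- make_toy_gene(c(90L, 90L), 20L, seed = 23,
                     motif_seeding = list(set = set, count = 2))
  proc <- remove_introns(g, keep_first = FALSE)
  cfg <- design_config("ese_only", ese_mode = "decrease", ese_set = set,
                       n_variants = 1)
  s_in <- score_variant(proc$cds, proc, gc_target_model("ese_only"), cfg)
  # degrade one seeded match by hand (synonymously irrelevant here: just
  # compare the stated objective on two sequences)
  hit <- regexpr("GAAGAA", proc$cds, fixed = TRUE)
  cds2 <- proc$cds
  substr(cds2, hit, hit) <- "T"
  s2 <- score_variant(cds2, proc, gc_target_model("ese_only"), cfg)
  expect_lt(s2$objective, s_in$objective)
})

test_that("identical seeds reproduce identical clouds", {
  g <- tiny_gene(c(60L, 60L), seed = 9)
  proc <- remove_introns(g)
  set <- toy_ese_set()
  cfg <- design_config("one_two_exon", ese_mode = "increase",
                       ese_set = set, n_variants = 8, seed = 42)
  plan <- build_site_plan(proc, cfg)
  m <- gc_target_model("one_two_exon")
  c1 <- generate_cloud(proc, plan, m, cfg)
  c2 <- generate_cloud(proc, plan, m, cfg)
  expect_identical(vapply(c1$variants, `[[`, character(1), "cds"),
                   vapply(c2$variants, `[[`, character(1), "cds"))
  expect_identical(c1$best_index, c2$best_index)
})

test_that("best-variant selection breaks ties by fewest changes", {
  g <- gene_record("ATGTGGTAA")  # nothing mutable: all variants identical
  proc <- remove_introns(g)
  cfg <- design_config("max_gc", n_variants = 5, seed = 1)
  plan <- build_site_plan(proc, cfg)
  cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
  expect_identical(cloud$best_index, 1L)
})
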