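test_that("candidate sets honor the 6-fold box policy", {
  expect_identical(synonymous_candidates("ATG"), "ATG")
  leu <- synonymous_candidates("CTG")
  expect_length(leu, 6)
  expect_setequal(leu, c("CTT", "CTC", "CTA", "CTG", "TTA", "TTG"))
  expect_setequal(synonymous_candidates("CTG", "sub_box"),
                  c("CTT", "CTC", "CTA", "CTG"))
  expect_setequal(synonymous_candidates("TTA", "sub_box"), c("TTA", "TTG"))
  expect_error(synonymous_candidates("TAA"), "immutable")
})

test_that("6-fold sub-boxes partition the full family", {
  for (codon in c("CTG", "TTA", "TCT", "AGC", "CGG", "AGA")) {
    full <- synonymous_candidates(codon, "full_box")
    subs <- unique(lapply(full, synonymous_candidates, policy = "sub_box"))
    expect_length(subs, 2)
    expect_length(intersect(subs[[1]], subs[[2]]), 0)
    expect_setequal(unlist(subs), full)
  }
})

test_that("max_gc scores count G/C at the variable positions", {
  m <- gc_target_model("max_gc")
  expect_equal(gc_score("GGC", 0, m), 1)
  expect_equal(gc_score("GGA", 0, m), 0)
  # Leu full box varies at positions 1 and 3
  leu <- synonymous_candidates("CTG")
  expect_equal(gc_score("CTG", 0, m, candidates = leu), 1)
  expect_equal(gc_score("TTA", 0, m, candidates = leu), 0)
  expect_equal(gc_score("CTA", 0, m, candidates = leu), 0.5)
  expect_equal(gc_score("ATG", 0, m, candidates = "ATG"), 1)
})

test_that("human_usage scores are within-family normalized frequencies", {
  usage <- c(GGC = 2, GGA = 2, GGG = 0, GGT = 0)
  m <- gc_target_model("human_usage", usage = usage)
  expect_equal(gc_score("GGC", 0, m), 0.5)
  expect_equal(gc_score("GGG", 0, m), 0)
  # bundled human table: within-family frequencies sum to 1
  mb <- gc_target_model("human_usage")
  gly <- c("GGT", "GGC", "GGA", "GGG")
  expect_equal(sum(vapply(gly, gc_score, numeric(1), codon_index = 0,
                          model = mb)), 1)
})

test_that("usage tables in Codon Usage Database layout parse", {
  f <- tempfile()
  writeLines(c("# comment", "UUU 17.6( 714298)  UUC 20.3(  824692)",
               "GGA 16.5 GGG 16.5"), f)
  u <- load_usage_table(f)
  expect_equal(unname(u["TTT"]), 17.6)
  expect_equal(unname(u["GGA"]), 16.5)
})

test_that("one_two_exon curve scores follow the parametric form", {
  curves <- list(GGN = list(
    C = list(floor = 0.25, ceiling = 0.55, tau = 50),
    G = list(floor = 0.25, ceiling = 0.25, tau = 50),
    A = list(floor = 0.25, ceiling = 0.10, tau = 50),
    T = list(floor = 0.25, ceiling = 0.10, tau = 50)
  ))
  m <- gc_target_model("one_two_exon", curves = curves)
  expect_equal(gc_score("GGC", 0, m), 0.55)
  expect_equal(gc_score("GGC", 1e6, m), 0.25, tolerance = 1e-9)
  i <- 30
  expect_equal(gc_score("GGC", i, m), 0.25 + 0.30 * exp(-i / 50))
  # probabilities over the box sum to 1 at any index
  for (idx in c(0, 7, 100)) {
    expect_equal(sum(vapply(c("GGA", "GGC", "GGG", "GGT"), gc_score,
                            numeric(1), codon_index = idx, model = m)), 1)
  }
})

test_that("default curve model is monotone non-increasing for GC", {
  m <- default_curve_model()
  idx <- c(0, 1, 5, 20, 50, 100, 300)
  for (codon in c("GGC", "GAG", "TTC", "CTG")) {
    s <- vapply(idx, gc_score, numeric(1), candidate = codon, model = m)
    expect_true(all(diff(s) <= 1e-12), info = codon)
  }
  # probabilities over each family sum to 1 at any index
  for (fam in list(c("GGA", "GGC", "GGG", "GGT"), c("GAA", "GAG"),
                   c("ATT", "ATC", "ATA"))) {
    for (idx in c(0, 12, 200)) {
      expect_equal(sum(vapply(fam, gc_score, numeric(1),
                              codon_index = idx, model = m)), 1)
    }
  }
})

test_that("ese_score is the matching-window fraction", {
  set <- load_ese_set(motifs = "GAAGAA")
  ctx <- "GAAGAAGAA"  # candidate set x = A at 0-based position 5
  expect_equal(ese_score(ctx, 5, set, "increase"), 0.5)
  expect_equal(ese_score(ctx, 5, set, "decrease"), 0.5)
  none <- "TTTTTTTTT"
  expect_equal(ese_score(none, 5, set, "increase"), 0)
  expect_equal(ese_score(none, 5, set, "decrease"), 1)
  # no window possible -> neutral
  expect_equal(ese_score("GAAG", 2, set, "increase"), 0.5)
})

test_that("scores convert to selection likelihoods per the convex blend", {
  expect_equal(selection_probabilities(c(1, 1)), c(0.5, 0.5))
  expect_equal(selection_probabilities(c(0.8, 0.2), c(0, 1), lambda = 0.5,
                                       ese_active = TRUE), c(0.4, 0.6))
  expect_equal(selection_probabilities(c(0.8, 0.2), c(0, 1), lambda = 0,
                                       ese_active = TRUE), c(0.8, 0.2))
  expect_equal(selection_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_error(selection_probabilities(c(1, 1), lambda = 1.5), "lambda")

  set.seed(5)
  for (r in 1:100) {
    k <- sample(1:6, 1)
    p <- selection_probabilities(runif(k), runif(k), lambda = runif(1),
                                 ese_active = sample(c(TRUE, FALSE), 1))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("under max_gc the GC-richest candidate is most likely", {
  m <- gc_target_model("max_gc")
  set.seed(8)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  for (codon in sample(sense, 25)) {
    cands <- synonymous_candidates(codon)
    if (length(cands) < 2) next
    gc <- vapply(cands, gc_score, numeric(1), codon_index = 0, model = m,
                 candidates = cands)
    p <- selection_probabilities(gc)
    expect_equal(which.max(p), which.max(gc))
    gc3 <- vapply(cands, function(x) {
      vp <- which(vapply(1:3, function(q)
        length(unique(substr(cands, q, q))) > 1, logical(1)))
      mean(substring(x, vp, vp) %in% c("G", "C"))
    }, numeric(1))
    expect_true(p[which.max(gc3)] >= max(p) - 1e-12)
  }
})

test_that("degenerate training collapses fitted curves correctly", {
  # every Phe codon ends in C -> fitted p(C | TTY) is 1 at all indices
  cds <- paste0("ATG", strrep("TTC", 40), "TAA")
  suppressWarnings(m <- fit_position_curves(rep(cds, 12)))
  for (idx in c(0, 10, 35)) {
    expect_equal(gc_score("TTC", idx, m), 1, tolerance = 1e-9)
  }
  expect_error(fit_position_curves(character(0)), "empty")
  expect_error(fit_position_curves(rep(cds, 5)), "at least 10")
})

test_that("flat generative curves are recovered as flat", {
  tr <- make_training_corpus(60, n_codons = 120, floor = 0.45,
                             ceiling = 0.45, tau = 40, seed = 3)
  suppressWarnings(m <- fit_position_curves(tr))
  # a 2-fold A/G box carries the GC-class probability directly
  s <- vapply(c(0, 30, 90), gc_score, numeric(1), candidate = "GAG",
              model = m)
  expect_true(all(abs(s - 0.45) < 0.05))
})
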