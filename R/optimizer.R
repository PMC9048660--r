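# Sliding-window stochastic recoding: site eligibility, restriction-site
# protection, blacklist enforcement, variant cloud generation and best-
# variant selection.

.IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

.iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- !chars %in% names(.IUPAC_CLASS)
  if (any(bad)) {
    stop("invalid IUPAC character '", chars[bad][1], "' in pattern '",
         pattern, "'", call. = FALSE)
  }
  paste(.IUPAC_CLASS[chars], collapse = "")
}

.iupac_revcomp <- function(pattern) {
  comp <- chartr("ACGTRYKMSWBDHVN", "TGCAYRMKSWVHDBN", toupper(pattern))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# all (possibly overlapping) 1-based match starts of a plain regex
.regex_starts <- function(regex, subject) {
  m <- gregexpr(paste0("(?=", regex, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find restriction-site (IUPAC pattern) matches on both strands
#'
#' Matches each IUPAC recognition pattern, and its reverse complement, on
#' the given strand, so minus-strand recognition sites are reported at
#' their plus-strand location. Overlapping matches all count.
#'
#' @param seq Nucleotide string.
#' @param patterns Character vector of IUPAC patterns.
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `pattern`, sorted by position; one row per distinct interval per
#'   pattern.
#' @export
find_restriction_matches <- function(seq, patterns) {
  seq <- toupper(seq)
  out <- list()
  for (p in patterns) {
    res <- unique(c(.iupac_regex(p), .iupac_regex(.iupac_revcomp(p))))
    starts <- sort(unique(unlist(lapply(res, .regex_starts, subject = seq))))
    if (length(starts)) {
      out[[length(out) + 1L]] <- data.frame(
        start = starts - 1L, end = starts - 1L + nchar(p),
        pattern = p, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$pattern), , drop = FALSE]
}

#' Design configuration
#'
#' All tunables of a recoding run.
#'
#' @param gc_strategy GC target strategy; see [gc_target_model()].
#' @param ese_mode `"off"`, `"increase"` or `"decrease"` ESE density.
#' @param ese_set An [load_ese_set()] object; required unless `ese_mode`
#'   is `"off"`.
#' @param lambda ESE/GC blend weight in `[0, 1]`; default 0.5.
#' @param vicinity_nt ESE vicinity half-width around each removed-intron
#'   junction, in nucleotides; default 70.
#' @param ese_in_cores Expand ESE scoring to all codons, including exon
#'   cores; default `FALSE`.
#' @param sixfold_policy `"full_box"` (all six synonyms at 6-fold sites,
#'   the default) or `"sub_box"` (stay within the 2- or 4-codon sub-box).
#' @param keep_first_intron Retain the first intron; default `TRUE`.
#' @param protect_enzymes IUPAC recognition patterns whose matches in the
#'   input must be retained (their codons are skipped).
#' @param avoid_motifs IUPAC patterns that must not be newly introduced.
#' @param n_variants Cloud size; default 1000.
#' @param seed Integer seed; the cloud is a deterministic function of
#'   (input, config, seed).
#' @return An object of class `design_config`.
#' @export
design_config <- function(gc_strategy = .GC_STRATEGIES,
                          ese_mode = c("off", "increase", "decrease"),
                          ese_set = NULL, lambda = 0.5, vicinity_nt = 70L,
                          ese_in_cores = FALSE,
                          sixfold_policy = c("full_box", "sub_box"),
                          keep_first_intron = TRUE,
                          protect_enzymes = character(0),
                          avoid_motifs = character(0),
                          n_variants = 1000L, seed = 1L) {
  gc_strategy <- match.arg(gc_strategy)
  ese_mode <- match.arg(ese_mode)
  sixfold_policy <- match.arg(sixfold_policy)
  if (ese_mode != "off" && is.null(ese_set)) {
    stop("ese set required when ese_mode is '", ese_mode, "'",
         call. = FALSE)
  }
  if (!is.null(ese_set)) stopifnot(inherits(ese_set, "ese_set"))
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]",
                                     call. = FALSE)
  if (vicinity_nt < 0) stop("vicinity_nt must be >= 0", call. = FALSE)
  if (n_variants < 1) stop("n_variants must be >= 1", call. = FALSE)
  for (p in c(protect_enzymes, avoid_motifs)) .iupac_regex(p)  # validate
  structure(
    list(gc_strategy = gc_strategy, ese_mode = ese_mode, ese_set = ese_set,
         lambda = lambda, vicinity_nt = as.integer(vicinity_nt),
         ese_in_cores = isTRUE(ese_in_cores),
         sixfold_policy = sixfold_policy,
         keep_first_intron = isTRUE(keep_first_intron),
         protect_enzymes = as.character(protect_enzymes),
         avoid_motifs = as.character(avoid_motifs),
         n_variants = as.integer(n_variants), seed = as.integer(seed)),
    class = "design_config"
  )
}

# working sequence (5' flank + CDS with retained intron + 3' flank) and the
# 1-based working position of every CDS nucleotide
.working_layout <- function(processed, cds = processed$cds) {
  work <- .assemble_construct(processed, cds, lower_intron = FALSE)
  n <- nchar(cds)
  off5 <- nchar(processed$five_prime_flank)
  map <- seq_len(n) + off5
  if (!is.null(processed$retained_intron)) {
    ri <- processed$retained_intron
    after <- seq_len(n) > ri$offset
    map[after] <- map[after] + nchar(ri$seq)
  }
  list(work = toupper(work), map = map)
}

# candidate lookup tables, computed once
.CANDIDATES <- local({
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  list(
    full_box = stats::setNames(
      lapply(sense, synonymous_candidates, policy = "full_box"), sense),
    sub_box = stats::setNames(
      lapply(sense, synonymous_candidates, policy = "sub_box"), sense)
  )
})

#' Build the per-codon site plan
#'
#' Decides, for every codon of the intronless CDS, whether it is mutable
#' and whether it is ESE-eligible. A codon is mutable when it has at least
#' two synonymous candidates under the 6-fold policy, is neither the start
#' nor the stop codon, and does not overlap any protected restriction-site
#' match (matches are located on the full working sequence, flanks and
#' retained intron included, so flank-spanning sites also protect). A codon
#' is ESE-eligible when any of its nucleotides lies within `vicinity_nt` of
#' a removed-intron junction (on either side), or everywhere with
#' `ese_in_cores`; never when `ese_mode` is `"off"`.
#'
#' @param processed A [remove_introns()] result.
#' @param config A [design_config()].
#' @return A data frame of class `site_plan` with columns `codon_index`
#'   (0-based), `codon`, `mutable`, `ese_eligible`, `reason`.
#' @export
build_site_plan <- function(processed, config) {
  stopifnot(inherits(processed, "processed_gene"),
            inherits(config, "design_config"))
  codons <- seq_codons(processed$cds)
  n <- length(codons)
  aa <- .GENETIC_CODE[codons]
  if (anyNA(aa)) stop("invalid codon in CDS", call. = FALSE)

  mutable <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  is_stop <- aa == "*"
  n_cand <- vapply(seq_len(n), function(i) {
    if (is_stop[i]) 1L else length(.CANDIDATES[[config$sixfold_policy]][[codons[i]]])
  }, integer(1))

  mark <- function(idx, why) {
    sel <- idx & mutable
    mutable[sel] <<- FALSE
    reason[sel] <<- why
  }
  mark(seq_len(n) == 1L, "start")
  mark(is_stop, "stop")
  mark(n_cand < 2L, "no_synonyms")

  if (length(config$protect_enzymes)) {
    lay <- .working_layout(processed)
    hits <- find_restriction_matches(lay$work, config$protect_enzymes)
    if (nrow(hits)) {
      # a working position (0-based) is covered if it falls in any match
      covered <- rep(FALSE, nchar(lay$work))
      for (h in seq_len(nrow(hits))) {
        covered[(hits$start[h] + 1L):hits$end[h]] <- TRUE
      }
      protected <- vapply(seq_len(n), function(i) {
        any(covered[lay$map[(3L * (i - 1L) + 1L):(3L * i)]])
      }, logical(1))
      mark(protected, "restriction")
    }
  }

  ese_eligible <- rep(FALSE, n)
  if (config$ese_mode != "off") {
    if (config$ese_in_cores) {
      ese_eligible <- rep(TRUE, n)
    } else if (length(processed$junctions)) {
      cds_len <- nchar(processed$cds)
      for (j in processed$junctions) {
        lo <- max(0L, j - config$vicinity_nt)        # 0-based half-open
        hi <- min(cds_len, j + config$vicinity_nt)
        first <- lo %/% 3L
        last <- (hi - 1L) %/% 3L
        ese_eligible[(first + 1L):(last + 1L)] <- TRUE
      }
    }
    ese_eligible[is_stop] <- FALSE
  }

  structure(
    data.frame(codon_index = seq_len(n) - 1L, codon = codons,
               mutable = mutable, ese_eligible = ese_eligible,
               reason = reason, stringsAsFactors = FALSE),
    class = c("site_plan", "data.frame")
  )
}

# merged ESE-eligible nucleotide regions (1-based inclusive) on the CDS
.ese_regions <- function(processed, config) {
  cds_len <- nchar(processed$cds)
  if (config$ese_in_cores) return(cbind(start = 1L, end = cds_len))
  if (length(processed$junctions) == 0L) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  v <- config$vicinity_nt
  lo <- pmax(1L, processed$junctions - v + 1L)
  hi <- pmin(cds_len, processed$junctions + v)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  ms <- lo[1]; me <- hi[1]; out <- NULL
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= me + 1L) me <- max(me, hi[k])
    else { out <- rbind(out, c(ms, me)); ms <- lo[k]; me <- hi[k] }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}

# Per-site work that is constant across a cloud: candidate set, GC scores
# and (for non-ESE sites) the fixed selection probabilities. NULL entries
# mark immutable sites.
.precompute_site_scores <- function(plan, model, config) {
  cands_tab <- .CANDIDATES[[config$sixfold_policy]]
  lapply(seq_len(nrow(plan)), function(i) {
    if (!plan$mutable[i]) return(NULL)
    cands <- cands_tab[[plan$codon[i]]]
    gc <- vapply(cands, gc_score, numeric(1),
                 codon_index = plan$codon_index[i], model = model,
                 candidates = cands)
    list(cands = cands, gc = gc,
         chars = vapply(cands, function(x) strsplit(x, "")[[1]],
                        character(3)),
         vp_codon = .variable_positions(cands),
         probs0 = selection_probabilities(gc))
  })
}

#' Generate one recoded variant
#'
#' Moves over the CDS 5' to 3', one synonymous site at a time. At each
#' mutable codon the synonymous candidates are scored (GC target fit, plus
#' ESE resemblance at ESE-eligible sites), scores are converted into a
#' selection likelihood, and one candidate is drawn. Before committing, a
#' draw that differs from the current codon is substituted into the working
#' sequence (flanks and retained intron included) and the surrounding
#' window is scanned for avoid-motif matches absent at the same offsets
#' before the substitution; if the change would introduce one, the site is
#' left as is. Later sites see earlier commitments. Uses the session RNG
#' stream; see [generate_cloud()] for seeding.
#'
#' @param processed A [remove_introns()] result.
#' @param plan A [build_site_plan()] result.
#' @param model A [gc_target_model()].
#' @param config A [design_config()].
#' @param .site_scores Precomputed [.precompute_site_scores()] result;
#'   internal, used by [generate_cloud()] to share work across variants.
#' @return An object of class `variant`: fields `cds`, `changes` (data
#'   frame `codon_index`, `from`, `to`, `reason`), `achieved_gc3`,
#'   `achieved_gc3_profile`, `ese_density_vicinity`, `objective`.
#' @export
generate_variant <- function(processed, plan, model, config,
                             .site_scores = NULL) {
  stopifnot(inherits(plan, "site_plan"))
  cds0 <- processed$cds
  lay <- .working_layout(processed)
  wvec <- strsplit(lay$work, "")[[1]]
  map <- lay$map
  if (is.null(.site_scores)) {
    .site_scores <- .precompute_site_scores(plan, model, config)
  }
  use_ese <- config$ese_mode != "off"
  avoid <- config$avoid_motifs
  if (length(avoid)) {
    avoid_re <- lapply(avoid, function(p) {
      unique(c(.iupac_regex(p), .iupac_regex(.iupac_revcomp(p))))
    })
    lmax <- max(nchar(avoid))
  }
  n <- nrow(plan)
  ch_idx <- integer(0); ch_from <- character(0); ch_to <- character(0)
  ch_why <- character(0)

  for (i in seq_len(n)) {
    ss <- .site_scores[[i]]
    if (is.null(ss)) next
    current <- plan$codon[i]
    cands <- ss$cands
    site_ese <- use_ese && plan$ese_eligible[i]
    if (site_ese) {
      vp_codon <- ss$vp_codon                              # 1..3 in codon
      vp <- 3L * (i - 1L) + vp_codon - 1L                  # 0-based in CDS
      cpos <- map[(3L * (i - 1L) + 1L):(3L * i)]           # working pos
      ese <- vapply(seq_along(cands), function(k) {
        ctx <- wvec
        ctx[cpos] <- ss$chars[, k]
        # score on the CDS view (mature mRNA): rebuild local CDS window
        lo <- max(1L, 3L * (i - 1L) + min(vp_codon) - 5L)
        hi <- min(nchar(cds0), 3L * (i - 1L) + max(vp_codon) + 5L)
        local_cds <- paste(ctx[map[lo:hi]], collapse = "")
        ese_score(local_cds,
                  var_positions = vp - (lo - 1L),
                  set = config$ese_set, mode = config$ese_mode)
      }, numeric(1))
      probs <- selection_probabilities(ss$gc, ese, lambda = config$lambda,
                                       ese_active = TRUE)
    } else {
      probs <- ss$probs0
    }
    ki <- sample.int(length(cands), 1L, prob = probs)
    draw <- cands[ki]
    if (draw == current) next

    cpos <- map[(3L * (i - 1L) + 1L):(3L * i)]
    if (length(avoid)) {
      wstart <- max(1L, min(cpos) - (lmax - 1L))
      wend <- min(length(wvec), max(cpos) + (lmax - 1L))
      before <- paste(wvec[wstart:wend], collapse = "")
      avec <- wvec
      avec[cpos] <- ss$chars[, ki]
      after <- paste(avec[wstart:wend], collapse = "")
      introduced <- FALSE
      for (res in avoid_re) {
        sb <- unlist(lapply(res, .regex_starts, subject = before))
        sa <- unlist(lapply(res, .regex_starts, subject = after))
        if (length(setdiff(sa, sb))) { introduced <- TRUE; break }
      }
      if (introduced) next  # the site is left as is
    }
    wvec[cpos] <- ss$chars[, ki]
    ch_idx <- c(ch_idx, plan$codon_index[i])
    ch_from <- c(ch_from, current)
    ch_to <- c(ch_to, draw)
    ch_why <- c(ch_why, if (site_ese) {
      if (config$gc_strategy == "ese_only") "ese" else "gc+ese"
    } else "gc")
  }

  cds <- paste(wvec[map], collapse = "")
  changes <- data.frame(codon_index = ch_idx, from = ch_from, to = ch_to,
                        reason = ch_why, stringsAsFactors = FALSE)
  stats <- score_variant(cds, processed, model, config)
  structure(
    c(list(cds = cds, changes = changes), stats),
    class = "variant"
  )
}

#' @export
print.variant <- function(x, ...) {
  cat("<variant> ", nrow(x$changes), " codon change(s), GC3 ",
      sprintf("%.3f", x$achieved_gc3), ", objective ",
      sprintf("%.4f", x$objective), "\n", sep = "")
  invisible(x)
}

#' Score a (candidate) variant CDS against the design targets
#'
#' The objective is the mean, over 10-codon bins, of the absolute deviation
#' between achieved and target GC3 (GC3 computed over degenerate third
#' positions; the target is the curve model's expected GC3 for
#' `one_two_exon`, 1 for `max_gc`, the usage-expected GC3 for
#' `human_usage`, and absent for `ese_only`), plus the absolute deviation
#' between the achieved ESE density over the vicinity regions and its
#' target (0 for `decrease`, 1 for `increase`) when ESE adjustment is on.
#' Lower is better; 0 is a perfect match.
#'
#' @param cds Variant CDS string (same protein as the input).
#' @param processed A [remove_introns()] result.
#' @param model A [gc_target_model()].
#' @param config A [design_config()].
#' @return List with `objective`, `achieved_gc3`, `achieved_gc3_profile`
#'   (per-bin), `ese_density_vicinity`.
#' @export
score_variant <- function(cds, processed, model, config) {
  if (inherits(cds, "variant")) cds <- cds$cds
  codons <- seq_codons(cds)
  n <- length(codons)
  aa <- .GENETIC_CODE[codons]
  deg <- aa != "*" & vapply(aa, function(a) length(.FAMILIES[[a]]) > 1L,
                            logical(1))
  third_gc <- substr(codons, 3L, 3L) %in% .GC_NUCS
  bin <- (seq_len(n) - 1L) %/% 10L

  gc_term <- 0
  profile <- numeric(0)
  if (any(deg)) {
    achieved_b <- tapply(third_gc[deg], bin[deg], mean)
    profile <- as.numeric(achieved_b)
    names(profile) <- names(achieved_b)
    if (model$strategy != "ese_only") {
      target_codon <- switch(model$strategy,
        max_gc = rep(1, sum(deg)),
        one_two_exon = {
          idx <- (which(deg) - 1L)
          vapply(seq_along(idx), function(k) {
            box_id <- .CODON_BOX[[codons[deg][k]]]
            p <- .curve_probs(model, box_id, idx[k])
            sum(p[names(p) %in% .GC_NUCS])
          }, numeric(1))
        },
        human_usage = {
          vapply(aa[deg], function(a) {
            fam <- .FAMILIES[[a]]
            sum(model$usage[fam][substr(fam, 3L, 3L) %in% .GC_NUCS])
          }, numeric(1))
        }
      )
      target_b <- tapply(target_codon, bin[deg], mean)
      gc_term <- mean(abs(achieved_b - target_b))
    }
  }

  ese_term <- 0
  dens <- .new_ese_density(0L, 0L)
  if (config$ese_mode != "off") {
    regions <- .ese_regions(processed, config)
    mc <- 0L; wc <- 0L
    for (r in seq_len(nrow(regions))) {
      d <- ese_match_count(cds, config$ese_set,
                           start = regions[r, "start"],
                           end = regions[r, "end"])
      mc <- mc + d$match_count
      wc <- wc + d$window_count
    }
    dens <- .new_ese_density(mc, wc)
    target <- if (config$ese_mode == "increase") 1 else 0
    ese_term <- abs(dens$density - target)
  }

  list(objective = gc_term + ese_term,
       achieved_gc3 = if (any(deg)) mean(third_gc[deg]) else NA_real_,
       achieved_gc3_profile = profile,
       ese_density_vicinity = dens)
}

# deterministic per-variant sub-stream seed, kept below 2^31
.variant_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483629 * 7919 + index * 104729 +
                1) %% 2147483629)
}

#' Generate the variant cloud and select the best variant
#'
#' Draws `config$n_variants` independent variants, each from its own
#' deterministic sub-stream derived from `(seed, variant index)`, so the
#' cloud is reproducible and order-independent. The best variant minimizes
#' the objective; ties break by fewest changes, then generation order.
#'
#' @inheritParams generate_variant
#' @return An object of class `variant_cloud`: `variants` (list),
#'   `best_index`, `input_gc3`, `input_ese_density`.
#' @export
generate_cloud <- function(processed, plan, model, config) {
  n <- config$n_variants
  site_scores <- .precompute_site_scores(plan, model, config)
  variants <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(.variant_seed(config$seed, k))
    variants[[k]] <- generate_variant(processed, plan, model, config,
                                      .site_scores = site_scores)
  }
  obj <- vapply(variants, `[[`, numeric(1), "objective")
  nch <- vapply(variants, function(v) nrow(v$changes), integer(1))
  best <- order(obj, nch, seq_len(n))[1]
  in_stats <- score_variant(processed$cds, processed, model, config)
  structure(
    list(variants = variants, best_index = best,
         input_gc3 = in_stats$achieved_gc3,
         input_ese_density = in_stats$ese_density_vicinity$density),
    class = "variant_cloud"
  )
}

#' @export
print.variant_cloud <- function(x, ...) {
  obj <- vapply(x$variants, `[[`, numeric(1), "objective")
  cat("<variant_cloud> ", length(x$variants), " variants (",
      length(unique(vapply(x$variants, `[[`, character(1), "cds"))),
      " distinct); best objective ",
      sprintf("%.4f", obj[x$best_index]), "\n", sep = "")
  invisible(x)
}
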