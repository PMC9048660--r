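# GC target models and codon scoring.
#
# Four strategies for the GC component of a codon's score:
#   one_two_exon - position-dependent third-nucleotide probability curves,
#                  emulating the favourability of synonymous sites in human
#                  1-2 exon genes (GC3-rich 5' end decaying downstream);
#   max_gc       - favour G/C at every degenerate position;
#   human_usage  - position-independent codon usage frequencies;
#   ese_only     - no GC component (ESE resemblance alone drives choice).

.GC_STRATEGIES <- c("one_two_exon", "max_gc", "human_usage", "ese_only")

#' Construct a GC target model
#'
#' @param strategy One of `"one_two_exon"`, `"max_gc"`, `"human_usage"`,
#'   `"ese_only"`.
#' @param curves For `one_two_exon`: a named list, box id ->
#'   third-nucleotide -> `list(floor, ceiling, tau)` describing the curve
#'   `p(i) = floor + (ceiling - floor) * exp(-i / tau)` over 0-based codon
#'   index `i`. Probabilities are renormalized over each box's nucleotides
#'   at every index. Defaults to [default_curve_model()]'s curves.
#' @param usage For `human_usage`: a named numeric vector, codon ->
#'   relative frequency (any positive scale; normalized within each codon
#'   family). Defaults to the bundled Codon Usage Database human table.
#' @return An object of class `gc_target_model`.
#' @export
gc_target_model <- function(strategy = .GC_STRATEGIES, curves = NULL,
                            usage = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "one_two_exon" && is.null(curves)) {
    curves <- default_curve_model()$curves
  }
  if (!is.null(curves)) .validate_curves(curves)
  if (strategy == "human_usage") {
    if (is.null(usage)) {
      usage <- load_usage_table(system.file(
        "extdata", "human_codon_usage.txt", package = "intronless"))
    }
    usage <- .normalize_usage(usage)
  }
  structure(list(strategy = strategy, curves = curves, usage = usage),
            class = "gc_target_model")
}

#' @export
print.gc_target_model <- function(x, ...) {
  cat("<gc_target_model> strategy:", x$strategy, "\n")
  invisible(x)
}

.validate_curves <- function(curves) {
  for (id in names(curves)) {
    if (!id %in% names(.BOXES)) {
      stop("unknown codon box '", id, "' in curve model", call. = FALSE)
    }
    for (nt in names(curves[[id]])) {
      p <- curves[[id]][[nt]]
      if (!all(c("floor", "ceiling", "tau") %in% names(p))) {
        stop("curve for box ", id, " nucleotide ", nt,
             " must have floor, ceiling, tau", call. = FALSE)
      }
      if (p$floor < 0 || p$ceiling < 0 || p$tau <= 0) {
        stop("invalid curve parameters for box ", id, " nucleotide ", nt,
             call. = FALSE)
      }
    }
  }
  invisible(curves)
}

#' Default position-dependent curve model
#'
#' A parametric stand-in for the third-nucleotide favourability of human
#' 1-2 exon genes: total GC3 probability starts at `ceiling` at the first
#' codon and decays exponentially with 0-based codon index `i` toward
#' `floor`, `p_GC(i) = floor + (ceiling - floor) * exp(-i / tau)`. Within
#' each codon box the GC mass is split equally over the box's G/C-ending
#' options and the AT mass over its A/T-ending options; boxes offering only
#' one class receive the full mass there.
#'
#' @param floor Asymptotic (3'-ward) GC3 probability. Default 0.55.
#' @param ceiling GC3 probability at codon 0. Default 0.80.
#' @param tau Decay length in codons. Default 50.
#' @return A `gc_target_model` with strategy `one_two_exon`.
#' @export
default_curve_model <- function(floor = 0.55, ceiling = 0.80, tau = 50) {
  stopifnot(floor >= 0, floor <= 1, ceiling >= 0, ceiling <= 1, tau > 0)
  curves <- lapply(.BOXES, function(b) {
    gc <- intersect(b$nts, .GC_NUCS)
    at <- setdiff(b$nts, .GC_NUCS)
    out <- list()
    for (nt in gc) {
      out[[nt]] <- if (length(at) == 0L) {
        list(floor = 1 / length(gc), ceiling = 1 / length(gc), tau = tau)
      } else {
        list(floor = floor / length(gc), ceiling = ceiling / length(gc),
             tau = tau)
      }
    }
    for (nt in at) {
      out[[nt]] <- if (length(gc) == 0L) {
        list(floor = 1 / length(at), ceiling = 1 / length(at), tau = tau)
      } else {
        list(floor = (1 - floor) / length(at),
             ceiling = (1 - ceiling) / length(at), tau = tau)
      }
    }
    out
  })
  structure(list(strategy = "one_two_exon", curves = curves, usage = NULL),
            class = "gc_target_model")
}

#' Load a curve model from a YAML config
#'
#' Layout: box id -> nucleotide -> `{floor, ceiling, tau}`. Boxes absent
#' from the file keep the package default curve.
#'
#' @param path YAML file path.
#' @return A `gc_target_model` with strategy `one_two_exon`.
#' @export
load_curve_model <- function(path) {
  user <- yaml::read_yaml(path)
  curves <- default_curve_model()$curves
  for (id in names(user)) curves[[id]] <- user[[id]]
  gc_target_model("one_two_exon", curves = curves)
}

#' Load a codon usage table
#'
#' Reads the Codon Usage Database tabular layout: whitespace-separated
#' `triplet frequency-per-thousand (count)` entries, several per line, RNA
#' or DNA alphabet.
#'
#' @param path Usage table file path.
#' @return Named numeric vector, codon -> per-thousand frequency.
#' @export
load_usage_table <- function(path) {
  lines <- sub("#.*$", "", readLines(path))
  txt <- paste(lines, collapse = " ")
  txt <- gsub("\\(\\s*[0-9.]+\\s*\\)", " ", txt)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  if (length(toks) %% 2L != 0L) {
    stop("cannot parse usage table '", path, "'", call. = FALSE)
  }
  codons <- toupper(chartr("Uu", "Tt", toks[c(TRUE, FALSE)]))
  freqs <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
  if (anyNA(freqs) || any(!codons %in% names(.GENETIC_CODE))) {
    stop("cannot parse usage table '", path, "'", call. = FALSE)
  }
  stats::setNames(freqs, codons)
}

# normalize usage to within-family relative frequencies
.normalize_usage <- function(usage) {
  out <- stats::setNames(numeric(length(.GENETIC_CODE)),
                         names(.GENETIC_CODE))
  out[names(usage)] <- usage
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    tot <- sum(out[fam])
    out[fam] <- if (tot > 0) out[fam] / tot else 1 / length(fam)
  }
  out
}

# raw curve value, then renormalized over the box's nucleotides at index i
.curve_probs <- function(model, box_id, codon_index) {
  box <- .BOXES[[box_id]]
  cv <- model$curves[[box_id]]
  if (is.null(cv)) {
    stop("curve model has no entry for codon box '", box_id, "'",
         call. = FALSE)
  }
  p <- vapply(box$nts, function(nt) {
    par <- cv[[nt]]
    if (is.null(par)) {
      stop("curve model box '", box_id, "' lacks nucleotide ", nt,
           call. = FALSE)
    }
    par$floor + (par$ceiling - par$floor) * exp(-codon_index / par$tau)
  }, numeric(1))
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) stats::setNames(rep(1 / length(p), length(p)), box$nts)
  else p / s
}

#' GC score of a candidate codon
#'
#' The GC component of a candidate's selection score, in `[0, 1]`:
#' * `one_two_exon` - the curve probability of the candidate's
#'   third-position nucleotide at `codon_index`, within the candidate's own
#'   box (6-fold families are always scored within their 4-fold/2-fold
#'   sub-box; joint renormalization across a full 6-fold candidate set
#'   happens in [selection_probabilities()]);
#' * `max_gc` - the fraction of the candidate set's variable positions at
#'   which the candidate carries G or C;
#' * `human_usage` - the candidate's within-family relative usage;
#' * `ese_only` - the uniform value `1 / length(candidates)` (no GC
#'   preference).
#'
#' @param candidate A sense codon.
#' @param codon_index 0-based codon position in the CDS.
#' @param model A [gc_target_model()].
#' @param candidates The candidate set the codon is drawn from; defaults to
#'   the candidate's full codon family.
#' @return Numeric score in `[0, 1]`.
#' @export
gc_score <- function(candidate, codon_index, model,
                     candidates = synonymous_candidates(candidate)) {
  stopifnot(inherits(model, "gc_target_model"), codon_index >= 0)
  candidate <- toupper(candidate)
  switch(model$strategy,
    one_two_exon = {
      box_id <- .CODON_BOX[[candidate]]
      probs <- .curve_probs(model, box_id, codon_index)
      unname(probs[substr(candidate, 3L, 3L)])
    },
    max_gc = {
      vp <- .variable_positions(candidates)
      if (length(vp) == 0L) return(1)
      mean(substring(candidate, vp, vp) %in% .GC_NUCS)
    },
    human_usage = unname(model$usage[candidate]),
    ese_only = 1 / length(candidates)
  )
}

#' ESE resemblance score of a candidate codon
#'
#' Operationalizes ESE resemblance as the fraction of hexamer windows
#' overlapping the candidate's variable position(s) that match the motif
#' set after the candidate is substituted into its context: `m / w` in
#' `increase` mode, `1 - m / w` in `decrease` mode, and the neutral 0.5
#' when no window exists.
#'
#' @param context Nucleotide string with the candidate already substituted.
#' @param var_positions 0-based offsets in `context` that the candidate
#'   set can alter.
#' @param set An [load_ese_set()] object.
#' @param mode `"increase"` or `"decrease"`.
#' @return Numeric score in `[0, 1]`.
#' @export
ese_score <- function(context, var_positions, set,
                      mode = c("increase", "decrease")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "ese_set"), length(var_positions) >= 1L)
  len <- nchar(context)
  lo <- max(0L, min(var_positions) - 5L)
  hi <- min(max(var_positions), len - 6L)
  if (hi < lo) return(0.5)
  starts <- seq.int(lo, hi)
  windows <- substring(context, starts + 1L, starts + 6L)
  frac <- mean(windows %in% set$motifs)
  if (mode == "increase") frac else 1 - frac
}

#' Convert codon scores into selection likelihoods
#'
#' Codon selection is non-deterministic: scores become a selection
#' likelihood. The GC and ESE components are blended convexly,
#' `combined = (1 - lambda) * gc + lambda * ese` when ESE scoring is active
#' at the site, else `combined = gc`, then normalized to sum to 1. An
#' all-zero combined vector falls back to the uniform distribution.
#'
#' @param gc_scores,ese_scores Equal-length numeric vectors in `[0, 1]`
#'   (`ese_scores` ignored when `ese_active` is `FALSE`).
#' @param lambda Blend weight in `[0, 1]`; default 0.5.
#' @param ese_active Whether the ESE component applies at this site.
#' @return Numeric probability vector summing to 1.
#' @export
selection_probabilities <- function(gc_scores, ese_scores = NULL,
                                    lambda = 0.5, ese_active = FALSE) {
  if (lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
  if (length(gc_scores) < 1L) stop("no candidates", call. = FALSE)
  combined <- if (ese_active) {
    stopifnot(length(ese_scores) == length(gc_scores))
    (1 - lambda) * gc_scores + lambda * ese_scores
  } else {
    gc_scores
  }
  if (any(combined < 0)) stop("negative scores", call. = FALSE)
  s <- sum(combined)
  if (s <= 0) rep(1 / length(combined), length(combined))
  else combined / s
}

#' Fit position-dependent third-nucleotide curves from training CDSs
#'
#' Reconstructs a `one_two_exon` model from data: per codon box and
#' third-position nucleotide, empirical frequencies are tabulated per
#' 0-based codon index pooled in bins of `bin_width` codons, then the
#' parametric curve `floor + (ceiling - floor) * exp(-i / tau)` is fitted
#' by bounded least squares. A box absent from the training data (or a
#' degenerate fit) falls back to its position-independent empirical
#' frequency, with a warning for absent boxes.
#'
#' @param training Character vector (or list) of valid CDS strings; at
#'   least 10.
#' @param bin_width Codons per position bin; default 10.
#' @return A `gc_target_model` with strategy `one_two_exon`.
#' @export
fit_position_curves <- function(training, bin_width = 10L) {
  training <- as.character(training)
  if (length(training) == 0L) stop("empty training set", call. = FALSE)
  if (length(training) < 10L) {
    stop("at least 10 training CDSs are required, got ", length(training),
         call. = FALSE)
  }
  codons <- unlist(lapply(training, seq_codons), use.names = FALSE)
  idx <- unlist(lapply(training, function(s) {
    seq_len(nchar(s) / 3L) - 1L
  }), use.names = FALSE)
  box <- .CODON_BOX[codons]
  keep <- !is.na(box)  # drops stop codons
  codons <- codons[keep]; idx <- idx[keep]; box <- box[keep]
  third <- substr(codons, 3L, 3L)
  bin <- idx %/% bin_width

  curves <- list()
  for (id in names(.BOXES)) {
    nts <- .BOXES[[id]]$nts
    sel <- box == id
    if (!any(sel)) {
      warning("codon box ", id, " absent from training data; ",
              "using a flat uniform curve", call. = FALSE)
      curves[[id]] <- stats::setNames(lapply(nts, function(nt) {
        list(floor = 1 / length(nts), ceiling = 1 / length(nts), tau = 1)
      }), nts)
      next
    }
    if (length(nts) == 1L) {
      curves[[id]] <- stats::setNames(
        list(list(floor = 1, ceiling = 1, tau = 1)), nts)
      next
    }
    tab <- table(bin = bin[sel], nt = factor(third[sel], levels = nts))
    tot <- rowSums(tab)
    x <- (as.numeric(rownames(tab)) + 0.5) * bin_width - 0.5  # bin centres
    curves[[id]] <- stats::setNames(lapply(nts, function(nt) {
      y <- tab[, nt] / tot
      .fit_one_curve(x[tot > 0], y[tot > 0],
                     fallback = sum(tab[, nt]) / sum(tot))
    }), nts)
  }
  gc_target_model("one_two_exon", curves = curves)
}

.fit_one_curve <- function(x, y, fallback) {
  flat <- list(floor = fallback, ceiling = fallback, tau = 1)
  if (length(x) < 3L || stats::sd(y) < 1e-6) return(flat)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fl + (ce - fl) * exp(-x / tau),
      data = data.frame(x = x, y = y),
      start = list(fl = unname(utils::tail(y, 1L)), ce = unname(y[1L]),
                   tau = 30),
      lower = c(0, 0, 0.5), upper = c(1, 1, 1e5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flat)
  cf <- stats::coef(fit)
  list(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
       tau = unname(cf["tau"]))
}
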