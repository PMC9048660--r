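# End-to-end pipeline: parse -> remove introns -> plan -> cloud -> select
# -> write, plus the run manifest. A thin command-line wrapper over
# run_design() ships in inst/scripts/design_transgene.R.

.read_flank <- function(path) {
  if (is.null(path)) return("")
  recs <- seqinr::read.fasta(path, forceDNAtolower = FALSE,
                             as.string = TRUE, seqtype = "DNA")
  if (length(recs) != 1L) {
    stop("flank file '", path, "' must contain exactly 1 record",
         call. = FALSE)
  }
  toupper(as.character(recs[[1]]))
}

#' Run the full transgene design pipeline
#'
#' Reads a gene, removes its introns (optionally keeping the first),
#' builds the site plan, generates the variant cloud, selects the best
#' variant and writes the outputs (best-variant FASTA, multi-FASTA of all
#' distinct variants, per-site change table, JSON summary) plus a JSON run
#' manifest sufficient to reproduce the run.
#'
#' @param input Path to a GenBank or FASTA gene file, or a `gene_record`.
#' @param out_prefix Output path prefix (4 output files + manifest).
#' @param input_format `"auto"`, `"genbank"` or `"fasta"`.
#' @param five_prime,three_prime Optional single-record FASTA paths with
#'   fixed flanking sequences (never recoded; scanned only for motif
#'   introductions spanning the flank/CDS boundary).
#' @param ese_set A set name from [list_ese_sets()], a motif file path, or
#'   an `ese_set` object; required unless `ese_mode` is `"off"`.
#' @param curve_model Optional YAML curve-config path for the
#'   `one_two_exon` strategy (see [load_curve_model()]).
#' @param usage_table Optional Codon Usage Database-layout file for the
#'   `human_usage` strategy.
#' @param allow_partial_cds Tolerate a CDS without ATG start / stop end.
#' @param quiet Suppress progress messages.
#' @inheritParams design_config
#' @return Invisibly, a list with `best`, `cloud`, `processed`, `files`,
#'   `manifest`.
#' @export
run_design <- function(input, out_prefix,
                       input_format = c("auto", "genbank", "fasta"),
                       five_prime = NULL, three_prime = NULL,
                       gc_strategy = .GC_STRATEGIES,
                       ese_mode = c("off", "increase", "decrease"),
                       ese_set = NULL, lambda = 0.5, vicinity_nt = 70L,
                       ese_in_cores = FALSE,
                       sixfold_policy = c("full_box", "sub_box"),
                       keep_first_intron = TRUE,
                       protect_enzymes = character(0),
                       avoid_motifs = character(0),
                       n_variants = 1000L, seed = 1L,
                       curve_model = NULL, usage_table = NULL,
                       allow_partial_cds = FALSE, quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[intronless] ", ...)
  gc_strategy <- match.arg(gc_strategy)
  ese_mode <- match.arg(ese_mode)
  sixfold_policy <- match.arg(sixfold_policy)

  if (!is.null(ese_set) && !inherits(ese_set, "ese_set")) {
    ese_set <- if (ese_set %in% .ESE_SET_NAMES) load_ese_set(name = ese_set)
    else load_ese_set(file = ese_set)
  }
  config <- design_config(
    gc_strategy = gc_strategy, ese_mode = ese_mode, ese_set = ese_set,
    lambda = lambda, vicinity_nt = vicinity_nt,
    ese_in_cores = ese_in_cores, sixfold_policy = sixfold_policy,
    keep_first_intron = keep_first_intron,
    protect_enzymes = protect_enzymes, avoid_motifs = avoid_motifs,
    n_variants = n_variants, seed = seed
  )

  input_path <- NULL
  if (inherits(input, "gene_record")) {
    gene <- input
  } else {
    input_path <- input
    say("reading gene from ", input)
    gene <- read_gene(input, format = match.arg(input_format),
                      allow_partial = allow_partial_cds)
  }
  gene$five_prime_flank <- .read_flank(five_prime)
  gene$three_prime_flank <- .read_flank(three_prime)

  say("removing introns (keep_first=", config$keep_first_intron, ")")
  processed <- remove_introns(gene, keep_first = config$keep_first_intron)

  model <- switch(gc_strategy,
    one_two_exon = if (is.null(curve_model)) default_curve_model()
                   else load_curve_model(curve_model),
    human_usage = gc_target_model("human_usage",
                                  usage = if (is.null(usage_table)) NULL
                                          else load_usage_table(usage_table)),
    gc_target_model(gc_strategy)
  )

  say("building site plan")
  plan <- build_site_plan(processed, config)
  say(sum(plan$mutable), "/", nrow(plan), " codons mutable, ",
      sum(plan$ese_eligible), " ESE-eligible")

  say("generating ", config$n_variants, " variants (seed ", config$seed,
      ")")
  cloud <- generate_cloud(processed, plan, model, config)
  best <- cloud$variants[[cloud$best_index]]
  say("best variant: objective ", sprintf("%.4f", best$objective), ", ",
      nrow(best$changes), " changes, GC3 ",
      sprintf("%.3f", best$achieved_gc3))

  files <- write_outputs(best, cloud, processed, out_prefix)

  manifest <- list(
    package = "intronless",
    version = as.character(utils::packageVersion("intronless")),
    seed = config$seed,
    input = list(
      path = input_path,
      md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path))
            else NULL,
      id = gene$id
    ),
    config = config[setdiff(names(config), "ese_set")],
    ese_set = if (!is.null(config$ese_set)) {
      list(name = config$ese_set$name,
           n_motifs = length(config$ese_set$motifs))
    } else NULL,
    outputs = as.list(files),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest_path <- paste0(out_prefix, "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, manifest = manifest_path)
  say("wrote ", length(files), " files under ", out_prefix)

  invisible(list(best = best, cloud = cloud, processed = processed,
                 plan = plan, files = files, manifest = manifest))
}
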