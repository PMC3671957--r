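#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_all()]. Input paths may
#' point at a bundle written by [write_bundle()] (or any files in the same
#' formats); leave `dir` as the bundle directory and the standard file
#' names are filled in.
#'
#' @param dir Bundle directory holding `promoters.tsv`, `clusters.tsv`,
#'   `expression.tsv`, `design.tsv`, `transcript.fa`, `mirs.fa`.
#' @param alpha DE significance cutoff.
#' @param universe Enrichment universe, `"gene"` or `"promoter"`.
#' @param n_shuffles Sponge null size.
#' @param seed Seed for the sponge null.
#' @param utr3 1-based inclusive 3'UTR interval, or `NULL` to use the
#'   final 40% of the transcript.
#' @param dialect Coordinate dialect of the interval files.
#' @param bh Apply Benjamini-Hochberg adjustment in the DE stage.
#' @param both_orientations Also score reverse-complement miRs in the
#'   sponge stage.
#' @param energy_params Energy parameter set (default
#'   [default_energy_params()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, alpha = 0.05,
                            universe = c("gene", "promoter"),
                            n_shuffles = 100L, seed = 1L, utr3 = NULL,
                            dialect = c("onebased", "bed0"), bh = FALSE,
                            both_orientations = FALSE,
                            energy_params = NULL) {
  universe <- match.arg(universe)
  dialect <- match.arg(dialect)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(
    promoters = file.path(dir, "promoters.tsv"),
    clusters = file.path(dir, "clusters.tsv"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    transcript = file.path(dir, "transcript.fa"),
    mirs = file.path(dir, "mirs.fa"),
    alpha = alpha, universe = universe,
    n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
    utr3 = utr3, dialect = dialect, bh = bh,
    both_orientations = both_orientations,
    energy_params = energy_params), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains the four stages — binding-site mapping, differential expression,
#' binding-vs-downregulation enrichment, and the sponge simulation — and
#' returns one machine-readable report. The enrichment stage joins the DE
#' stage's downregulated gene list with the binding summaries by gene
#' name; genes absent from the binding table count as unbound. Any stage
#' failure aborts with the stage name; if `out_json` was requested, a
#' `<out_json>.partial` marker is left behind.
#'
#' @param config A [pipeline_config()].
#' @param out_json Optional path for the JSON report.
#' @return The report: a list with `config` (audit trail), `binding`
#'   (classification counts), `de` (direction counts), `enrichment`
#'   (counts, analytic p, bound fraction) and `sponge` (per-region true
#'   score, null mean/sd, empirical p, z).
#' @export
run_all <- function(config, out_json = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("promoters", "clusters", "expression", "design",
              "transcript", "mirs")) {
    if (!file.exists(config[[f]]))
      stop("missing ", f, " input: ", config[[f]])
  }
  if (!is.null(out_json)) file.create(paste0(out_json, ".partial"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  binding <- stage("map-binding", {
    promoters <- read_promoters(config$promoters, config$dialect)
    clusters <- read_clusters(config$clusters, config$dialect)
    hits <- intersect_binding(promoters, clusters)
    summaries <- summarize_binding(promoters, hits, clusters)
    list(summaries = summaries, counts = classify_promoters(summaries))
  })
  de <- stage("de", {
    em <- read_expression(config$expression, config$design)
    res <- call_de(quantile_normalize(em), alpha = config$alpha,
                   bh = config$bh)
    list(results = res,
         counts = list(down = sum(res$direction == "down_in_kd"),
                       up = sum(res$direction == "up_in_kd"),
                       ns = sum(res$direction == "ns")))
  })
  enr <- stage("enrich", {
    inp <- enrichment_from_tables(binding$summaries, de$results,
                                  universe = config$universe)
    list(counts = unclass(inp), p_analytic = hypergeom_tail(inp),
         bound_fraction = if (inp$n_selected > 0) bound_fraction(inp)
         else NA_real_)
  })
  sponge <- stage("sponge", {
    tx <- read_rna_fasta(config$transcript, role = "transcript")[[1]]
    mirs <- read_rna_fasta(config$mirs, role = "mir")
    params <- if (is.null(config$energy_params)) default_energy_params()
      else config$energy_params
    utr3 <- if (is.null(config$utr3))
      c(floor(0.6 * nchar(tx$bases)) + 1L, nchar(tx$bases)) else
        config$utr3
    res <- run_sponge_null(tx, utr3 = utr3, mirs = mirs, params = params,
                           n_shuffles = config$n_shuffles,
                           seed = config$seed,
                           both_orientations = config$both_orientations)
    lapply(res, function(r) list(
      true_score = r$true_score, null_mean = mean(r$null_scores),
      null_sd = stats::sd(r$null_scores), empirical_p = r$empirical_p,
      z_score = r$z_score, n_shuffles = r$n_shuffles))
  })
  report <- list(
    config = config[setdiff(names(config), "energy_params")],
    binding = binding$counts, de = de$counts, enrichment = enr,
    sponge = sponge)
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    unlink(paste0(out_json, ".partial"))
  }
  report
}
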