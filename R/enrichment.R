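#' Counts feeding the binding-vs-downregulation enrichment test
#'
#' The 2x2 counts: `n_universe` miR promoters (or genes) considered,
#' `n_bound` of them carrying at least one TF binding site, `n_selected`
#' called downregulated, and `n_selected_bound` both bound and
#' downregulated. Containment constraints are validated.
#'
#' @param n_universe,n_bound,n_selected,n_selected_bound Non-negative
#'   integer counts with `n_bound <= n_universe`,
#'   `n_selected <= n_universe`,
#'   `n_selected_bound <= min(n_bound, n_selected)`.
#' @return A list of class `enrichment_input`.
#' @export
enrichment_input <- function(n_universe, n_bound, n_selected,
                             n_selected_bound) {
  x <- c(n_universe, n_bound, n_selected, n_selected_bound)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("all counts must be non-negative integers")
  if (n_bound > n_universe || n_selected > n_universe)
    stop("bound and selected counts cannot exceed the universe")
  if (n_selected_bound > min(n_bound, n_selected))
    stop("n_selected_bound cannot exceed min(n_bound, n_selected)")
  structure(list(n_universe = as.integer(n_universe),
                 n_bound = as.integer(n_bound),
                 n_selected = as.integer(n_selected),
                 n_selected_bound = as.integer(n_selected_bound)),
            class = "enrichment_input")
}

#' Exact hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing at least `n_selected_bound` bound items among
#' `n_selected` draws without replacement from a universe of `n_universe`
#' with `n_bound` bound: `P(X >= k)` for
#' `X ~ Hypergeometric(n_universe, n_bound, n_selected)`. One-sided upper
#' tail (over-representation). Computed through [stats::phyper()], which
#' works in log space internally and does not overflow for counts up to
#' 1e6.
#'
#' @param input An [enrichment_input()].
#' @return The upper-tail p-value.
#' @export
hypergeom_tail <- function(input) {
  stopifnot(inherits(input, "enrichment_input"))
  stats::phyper(input$n_selected_bound - 1L, input$n_bound,
                input$n_universe - input$n_bound, input$n_selected,
                lower.tail = FALSE)
}

#' Permutation cross-check of the enrichment p-value
#'
#' Draws `n_selected` labels without replacement from a universe with
#' `n_bound` marked items and counts draws at least as enriched as
#' observed. Empirical p uses the add-one rule
#' `(1 + #{draws >= observed}) / (1 + iters)`, so it is never exactly 0.
#' Reproducible under a fixed seed; independent of the analytic tail.
#'
#' @param input An [enrichment_input()].
#' @param iters Number of permutations (>= 1000).
#' @param seed Integer RNG seed.
#' @return A list with `p_empirical`, `iters`, `seed`.
#' @export
permutation_enrichment <- function(input, iters = 10000L, seed = 1L) {
  stopifnot(inherits(input, "enrichment_input"))
  if (iters < 1000L) stop("iters must be at least 1000")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  marked <- c(rep(TRUE, input$n_bound),
              rep(FALSE, input$n_universe - input$n_bound))
  n <- input$n_selected
  N <- input$n_universe
  k <- input$n_selected_bound
  hits <- 0L
  chunk <- 10000L
  done <- 0L
  while (done < iters) {
    m <- min(chunk, iters - done)
    cnt <- vapply(seq_len(m),
                  function(i) sum(marked[sample.int(N, n)]), integer(1))
    hits <- hits + sum(cnt >= k)
    done <- done + m
  }
  list(p_empirical = (1 + hits) / (1 + iters), iters = as.integer(iters),
       seed = as.integer(seed))
}

#' Percentage of selected items that are bound
#'
#' `100 * n_selected_bound / n_selected`, at full precision; round for
#' display.
#'
#' @param input An [enrichment_input()].
#' @return Percentage in \[0, 100\].
#' @export
bound_fraction <- function(input) {
  stopifnot(inherits(input, "enrichment_input"))
  if (input$n_selected == 0L)
    stop("bound_fraction undefined for n_selected = 0")
  100 * input$n_selected_bound / input$n_selected
}

#' Build enrichment counts from binding summaries and DE results
#'
#' Joins the differential-expression calls to the binding table by gene
#' name. At gene level the universe is every gene tested for differential
#' expression; a gene is bound when it appears in the gene list of any
#' bound promoter (genes absent from the binding table count as unbound).
#' At promoter level the universe is the promoter table; a promoter is
#' selected when at least one of its genes is downregulated.
#'
#' @param summaries Output of [summarize_binding()].
#' @param de Output of [call_de()].
#' @param universe `"gene"` (default) or `"promoter"`.
#' @return An [enrichment_input()].
#' @export
enrichment_from_tables <- function(summaries, de,
                                   universe = c("gene", "promoter")) {
  universe <- match.arg(universe)
  bound_genes <- unique(unlist(strsplit(
    summaries$genes[summaries$n_sites >= 1L], ",", fixed = TRUE)))
  down <- de$gene_id[de$direction == "down_in_kd"]
  if (universe == "gene") {
    genes <- unique(de$gene_id)
    enrichment_input(length(genes), sum(genes %in% bound_genes),
                     length(down), sum(down %in% bound_genes))
  } else {
    gene_lists <- strsplit(summaries$genes, ",", fixed = TRUE)
    selected <- vapply(gene_lists, function(g) any(g %in% down), logical(1))
    bound <- summaries$n_sites >= 1L
    enrichment_input(nrow(summaries), sum(bound), sum(selected),
                     sum(selected & bound))
  }
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
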