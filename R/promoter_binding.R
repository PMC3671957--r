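#' Read a table of putative miR promoters
#'
#' Ingests a tab-separated promoter table with columns `chrom`, `start`,
#' `end` and `genes` (a cell may hold several comma-separated miR gene
#' names, in which case the row describes the shared promoter of a pre-miR
#' cluster). Coordinates are normalised to the package-internal convention:
#' 0-based, half-open `[start, end)`.
#'
#' Genome-browser style tables print 1-based inclusive coordinates; true
#' BED files are 0-based half-open. Both dialects are accepted via
#' `dialect`; the default is 1-based inclusive, matching how such tables
#' are usually published.
#'
#' @param path Path to a tab-separated file (gzip transparent) with a
#'   header naming at least `chrom`, `start`, `end`, `genes`. An optional
#'   `strand` column is carried through; an optional `promoter_id` column
#'   overrides the generated ids.
#' @param dialect `"onebased"` (1-based inclusive, default) or `"bed0"`
#'   (0-based half-open).
#' @return A `data.frame` with columns `promoter_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, and `genes` (comma-separated gene
#'   names).
#' @seealso [write_binding_table()] for the inverse conversion on output.
#' @export
read_promoters <- function(path, dialect = c("onebased", "bed0")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  required <- c("chrom", "start", "end", "genes")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("promoter table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(data.frame(promoter_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(!is.finite(start) | !is.finite(end) | df$chrom == "" |
                 is.na(df$chrom) | df$genes == "" | is.na(df$genes))
  if (length(bad) > 0L) {
    stop("malformed promoter row at line ", bad[1L] + 1L, " of ", path)
  }
  bad <- which(end <= start)  # degenerate in either dialect
  if (length(bad) > 0L) {
    stop("empty or inverted interval (end <= start) at line ",
         bad[1L] + 1L, " of ", path)
  }
  if (dialect == "onebased") start <- start - 1
  strand <- if ("strand" %in% names(df)) as.character(df$strand) else
    rep("*", nrow(df))
  strand[!strand %in% c("+", "-")] <- "*"
  promoter_id <- if ("promoter_id" %in% names(df))
    as.character(df$promoter_id) else sprintf("prom_%04d", seq_len(nrow(df)))
  genes <- gsub("\\s+", "", as.character(df$genes))
  data.frame(promoter_id = promoter_id, chrom = as.character(df$chrom),
             start = as.integer(start), end = as.integer(end),
             strand = strand, genes = genes, stringsAsFactors = FALSE)
}

#' Read scored TF binding clusters
#'
#' Ingests a BED-like table of ChIP-seq binding clusters, each carrying an
#' integer cluster score in \[0, 1000\] summarising binding-signal strength
#' (the ENCODE cluster-score convention). Scores outside that range are an
#' error.
#'
#' @param path Tab-separated file (gzip transparent) with header columns
#'   `chrom`, `start`, `end`, `score`.
#' @inheritParams read_promoters
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and integer `score`.
#' @export
read_clusters <- function(path, dialect = c("onebased", "bed0")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  required <- c("chrom", "start", "end", "score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("cluster table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(score))
  if (length(bad) > 0L) {
    stop("malformed cluster row at line ", bad[1L] + 1L, " of ", path)
  }
  if (any(score < 0 | score > 1000)) {
    stop("cluster score outside [0, 1000] at line ",
         which(score < 0 | score > 1000)[1L] + 1L, " of ", path)
  }
  if (any(end <= start)) {
    stop("empty or inverted interval (end <= start) at line ",
         which(end <= start)[1L] + 1L, " of ", path)
  }
  if (dialect == "onebased") start <- start - 1
  data.frame(chrom = as.character(df$chrom), start = as.integer(start),
             end = as.integer(end), score = as.integer(round(score)),
             stringsAsFactors = FALSE)
}

#' Assign binding clusters to promoters by interval overlap
#'
#' A cluster is assigned to a promoter iff their half-open intervals on the
#' same chromosome share at least `min_overlap_bp` bases. A cluster
#' overlapping two promoters is counted for both; strand is ignored
#' (ChIP-seq clusters are unstranded).
#'
#' @param promoters Promoter table as returned by [read_promoters()].
#' @param clusters Cluster table as returned by [read_clusters()].
#' @param min_overlap_bp Minimum shared bases to count as binding
#'   (default 1).
#' @return A named list, one entry per promoter (named by `promoter_id`, in
#'   input order), each an integer vector of row indices into `clusters`
#'   (possibly empty).
#' @export
intersect_binding <- function(promoters, clusters, min_overlap_bp = 1L) {
  hits <- stats::setNames(
    rep(list(integer(0)), nrow(promoters)), promoters$promoter_id)
  if (nrow(promoters) == 0L || nrow(clusters) == 0L) return(hits)
  # internal 0-based half-open -> IRanges 1-based inclusive
  prom_gr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(promoters$start + 1L, promoters$end))
  clus_gr <- GenomicRanges::GRanges(
    clusters$chrom,
    IRanges::IRanges(clusters$start + 1L, clusters$end))
  ov <- GenomicRanges::findOverlaps(prom_gr, clus_gr,
                                    minoverlap = as.integer(min_overlap_bp))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  for (i in unique(qh)) hits[[i]] <- sort(sh[qh == i])
  hits
}

#' Summarise per-promoter binding
#'
#' Aggregates the clusters assigned to each promoter into the per-promoter
#' summary used in published binding tables: the number of sites and the
#' median and range of their scores. The median of an even number of
#' scores is the arithmetic mean of the two central values. Promoters with
#' no assigned cluster get `n_sites = 0` and `NA` scores.
#'
#' @param promoters Promoter table ([read_promoters()]).
#' @param hits Assignment as returned by [intersect_binding()].
#' @param clusters Cluster table the indices in `hits` refer to.
#' @return A `data.frame` with one row per promoter: `promoter_id`,
#'   `genes`, `chrom`, `start`, `end`, `n_sites`, `median_score`,
#'   `min_score`, `max_score`.
#' @export
summarize_binding <- function(promoters, hits, clusters) {
  stopifnot(length(hits) == nrow(promoters))
  n_sites <- vapply(hits, length, integer(1))
  med <- min_s <- max_s <- rep(NA_real_, nrow(promoters))
  for (i in which(n_sites > 0L)) {
    sc <- clusters$score[hits[[i]]]
    med[i] <- stats::median(sc)
    min_s[i] <- min(sc)
    max_s[i] <- max(sc)
  }
  data.frame(promoter_id = promoters$promoter_id, genes = promoters$genes,
             chrom = promoters$chrom, start = promoters$start,
             end = promoters$end, n_sites = n_sites, median_score = med,
             min_score = min_s, max_score = max_s, stringsAsFactors = FALSE)
}

#' Count bound single-gene promoters, bound cluster promoters, and unbound
#' promoters
#'
#' A promoter is bound when at least one cluster overlaps it; a "cluster
#' promoter" drives 2 or more pre-miR genes (comma-separated names in its
#' `genes` field).
#'
#' @param summaries Output of [summarize_binding()].
#' @return A list with integer elements `bound_single`, `bound_cluster`,
#'   `unbound`.
#' @export
classify_promoters <- function(summaries) {
  n_genes <- vapply(strsplit(summaries$genes, ",", fixed = TRUE), length,
                    integer(1))
  bound <- summaries$n_sites >= 1L
  list(bound_single = sum(bound & n_genes == 1L),
       bound_cluster = sum(bound & n_genes >= 2L),
       unbound = sum(!bound))
}

#' Write the per-promoter binding table
#'
#' Writes a tab-separated table with 1-based inclusive coordinates and a
#' rendered `"median (min-max)"` score column, sorted by descending median
#' score and then gene name (unbound promoters last). The written file can
#' be re-read with [read_promoters()]; the coordinate round-trip is the
#' identity.
#'
#' @param summaries Output of [summarize_binding()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binding_table <- function(summaries, path) {
  out <- summaries
  out$start <- out$start + 1L  # internal 0-based half-open -> 1-based incl.
  out$score_display <- ifelse(
    out$n_sites == 0L, "",
    sprintf("%s (%s-%s)", format_score(out$median_score),
            format_score(out$min_score), format_score(out$max_score)))
  ord <- order(-ifelse(is.na(out$median_score), -Inf, out$median_score),
               out$genes)
  out <- out[ord, c("genes", "chrom", "start", "end", "n_sites",
                    "median_score", "min_score", "max_score",
                    "score_display")]
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write binding table to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

format_score <- function(x) {
  ifelse(is.na(x), "", ifelse(x == round(x),
                              format(round(x), trim = TRUE, scientific = FALSE),
                              format(x, trim = TRUE, scientific = FALSE)))
}
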