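# Attention-ranked genomic regions: top-k window selection, gene
# annotation by interval overlap, and hypergeometric over-representation
# analysis with Benjamini-Hochberg correction.

#' Rank windows by attention weight
#'
#' Stable descending sort of per-window weights (ties broken by genome
#' order) and selection of the `top_k` highest-weight windows.
#'
#' @param weights Numeric weight per window. Either length = total windows
#'   in `ws`, or length = `length(window_indices)` when `window_indices`
#'   names the (0-based) windows the weights belong to (e.g. the retained
#'   columns of a pruned matrix).
#' @param ws A `window_set` supplying coordinates.
#' @param top_k Number of windows to keep. Default 5000 (truncated with a
#'   warning when it exceeds the number of ranked windows).
#' @param window_indices Optional 0-based indices aligned with `weights`.
#' @return A `ranked_regions` object: data.frame `regions` with columns
#'   `window_index`, `chrom`, `start`, `end`, `weight` in non-increasing
#'   weight order, plus `top_k`.
#' @export
rank_windows <- function(weights, ws, top_k = 5000, window_indices = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(window_indices)) {
    if (length(weights) != nrow(ws$windows))
      stop2("weights length != number of windows; pass window_indices for a subset")
    window_indices <- ws$windows$index
  }
  if (length(weights) != length(window_indices))
    stop2("weights and window_indices lengths differ")
  if (top_k > length(weights)) {
    warning("top_k (", top_k, ") exceeds ranked windows (", length(weights),
            "); truncated")
    top_k <- length(weights)
  }
  ord <- order(-weights, window_indices)
  sel <- ord[seq_len(top_k)]
  w <- ws$windows[match(window_indices[sel], ws$windows$index), ]
  structure(list(
    regions = data.frame(window_index = window_indices[sel],
                         chrom = w$chrom, start = w$start, end = w$end,
                         weight = weights[sel], stringsAsFactors = FALSE),
    top_k = top_k
  ), class = "ranked_regions")
}

#' @export
print.ranked_regions <- function(x, ...) {
  cat(sprintf("ranked_regions: top %d windows, weight range [%.3g, %.3g]\n",
              x$top_k, min(x$regions$weight), max(x$regions$weight)))
  invisible(x)
}

#' Export ranked regions as BED
#'
#' Writes `chrom start end window_index weight` in rank order.
#' @param rr A `ranked_regions`.
#' @param path Output path.
#' @export
write_regions_bed <- function(rr, path) {
  utils::write.table(
    rr$regions[, c("chrom", "start", "end", "window_index", "weight")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotate ranked regions with overlapping genes
#'
#' A gene is reported when it overlaps any selected window by at least 1 bp
#' (0-based half-open, so abutting intervals do not overlap). Genes are
#' de-duplicated and returned in a stable order: by the rank of the first
#' window they overlap.
#'
#' @param rr A `ranked_regions`.
#' @param genes data.frame with columns `chrom`, `start`, `end`, `name`, or
#'   a path to a BED-like file with those four columns.
#' @return Character vector of gene names.
#' @export
annotate_genes <- function(rr, genes) {
  stopifnot(inherits(rr, "ranked_regions"))
  if (is.character(genes) && length(genes) == 1L)
    genes <- read_intervals(genes, c("chrom", "start", "end", "name"))
  if (nrow(genes) == 0) return(character(0))
  bad <- genes$end <= genes$start | is.na(genes$start) | is.na(genes$end)
  if (any(bad)) {
    warning(sum(bad), " malformed gene interval(s) skipped")
    genes <- genes[!bad, , drop = FALSE]
  }
  reg <- rr$regions
  hits_list <- lapply(unique(reg$chrom), function(ch) {
    qi <- which(reg$chrom == ch)
    si <- which(genes$chrom == ch)
    if (length(si) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = reg$start[qi] + 1, end = reg$end[qi]),
      IRanges::IRanges(start = genes$start[si] + 1, end = genes$end[si]))
    if (length(ov) == 0) return(NULL)
    data.frame(rank = qi[S4Vectors::queryHits(ov)],
               gene = genes$name[si[S4Vectors::subjectHits(ov)]],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits_list)
  if (is.null(hits) || nrow(hits) == 0) return(character(0))
  hits <- hits[order(hits$rank), , drop = FALSE]
  unique(hits$gene)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the selected genes overlap it more than
#' expected under hypergeometric sampling from the universe: upper-tail
#' p = P(X >= k) with universe size N, set size K (after intersection with
#' the universe) and selection size n. P-values are Benjamini-Hochberg
#' adjusted across all tested sets; `p_adjusted < 0.05` marks significance.
#'
#' @param selected Character vector of selected gene names. Names outside
#'   the universe are dropped (reported in the `dropped` attribute).
#' @param gene_sets Named list of character vectors, or a path to a GMT
#'   file (`term<TAB>description<TAB>gene...`).
#' @param universe Character vector of all eligible gene names.
#' @return An `enrichment_result` data.frame: `term_id`, `k`, `K`, `n`,
#'   `N`, `p_value`, `p_adjusted`, `genes` (overlap, comma-separated),
#'   ordered by `p_adjusted` then `p_value`.
#' @export
ora_enrich <- function(selected, gene_sets, universe) {
  if (is.character(gene_sets) && length(gene_sets) == 1L &&
      file.exists(gene_sets))
    gene_sets <- read_gmt(gene_sets)
  universe <- unique(universe)
  if (length(universe) == 0) stop2("empty universe")
  selected <- unique(selected)
  dropped <- setdiff(selected, universe)
  if (length(dropped) > 0)
    warning(length(dropped), " selected gene(s) outside the universe dropped")
  selected <- intersect(selected, universe)
  if (length(selected) == 0) stop2("no selected genes inside the universe")
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(set)
    hit <- intersect(selected, set)
    k <- length(hit)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(hit, collapse = ","), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_adjusted, res$p_value, res$term_id),
             c("term_id", "k", "K", "n", "N", "p_value", "p_adjusted",
               "genes")]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Read a GMT gene-set file
#' @param path GMT path: `term<TAB>description<TAB>gene1<TAB>gene2...`
#' @return Named list of gene name vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  short <- lengths(parts) < 3
  if (any(short)) {
    warning(sum(short), " malformed GMT line(s) skipped")
    parts <- parts[!short]
  }
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[`, "", 1L))
}
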