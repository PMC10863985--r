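#' @title Score-distribution statistics and interactome graph assembly
#' @name stats_and_network
#' @description
#' Distribution comparisons between selected and randomly paired complexes
#' (ECDF, two-sample Kolmogorov-Smirnov, per-bin chi-square), category
#' summaries with printed-precision percentages, and assembly/export of the
#' undirected interactome graph with ipTM edge attributes.
NULL

#' Empirical cumulative distribution function
#'
#' Right-continuous step function with F(max) = 1.
#'
#' @param values Non-empty numeric vector.
#' @return A function of class `ecdf`.
#' @export
ecdf_fun <- function(values) {
  if (length(values) == 0) stop("empty sample")
  stats::ecdf(values)
}

# exhaustive permutation p-value for the two-sample KS statistic; feasible
# for small n + m, used as the exact route when ties invalidate the
# classical exact distribution
.ks_perm_exact <- function(a, b) {
  pooled <- c(a, b); n <- length(a)
  ksd <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
  }
  obs <- ksd(a, b)
  idx <- combn(length(pooled), n)
  cnt <- sum(apply(idx, 2, function(i)
    ksd(pooled[i], pooled[-i]) >= obs - 1e-12))
  cnt / ncol(idx)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |F_a - F_b|. The p-value is exact (conditional enumeration) when
#' n * m <= 10^4; with ties and a small pooled sample the exact route is an
#' exhaustive permutation enumeration, otherwise the asymptotic two-sample
#' KS distribution is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List `statistic` (D), `p_value`, `method`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  grid <- sort(unique(c(a, b)))
  D <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  small <- length(a) * length(b) <= 1e4
  ties <- any(duplicated(c(a, b)))
  if (small && !ties) {
    p <- suppressWarnings(ks.test(a, b, exact = TRUE)$p.value)
    method <- "exact"
  } else if (small && ties && length(a) + length(b) <= 14) {
    p <- .ks_perm_exact(a, b)
    method <- "exact-permutation"
  } else {
    p <- suppressWarnings(ks.test(a, b, exact = FALSE)$p.value)
    method <- "asymptotic"
  }
  list(statistic = D, p_value = p, method = method)
}

#' Per-bin chi-square comparison of binned score counts
#'
#' For each score bin, a 2 x 2 chi-square (without continuity correction)
#' contrasts the bin's selected/random counts against the remainder of each
#' sample; an overall chi-square of homogeneity across all bins is also
#' returned. Bins with any expected count below 5 are flagged.
#'
#' @param counts_selected,counts_random Equal-length integer vectors of
#'   per-bin counts.
#' @return List `per_bin` (data frame `bin`, `statistic`, `p_value`,
#'   `low_expected`), `overall_statistic`, `overall_p`, `df`.
#' @export
chisq_bins <- function(counts_selected, counts_random) {
  stopifnot(length(counts_selected) == length(counts_random))
  ns <- sum(counts_selected); nr <- sum(counts_random)
  if (ns == 0 || nr == 0) stop("zero total count in one sample")
  k <- length(counts_selected)
  per <- lapply(seq_len(k), function(i) {
    tab <- matrix(c(counts_selected[i], ns - counts_selected[i],
                    counts_random[i], nr - counts_random[i]), 2, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    data.frame(bin = i, statistic = stat,
               p_value = pchisq(stat, df = 1, lower.tail = FALSE),
               low_expected = any(E < 5))
  })
  per <- do.call(rbind, per)
  if (any(per$low_expected))
    warning("bin(s) with expected count < 5: ",
            paste(per$bin[per$low_expected], collapse = ", "))
  tab <- rbind(counts_selected, counts_random)
  nz <- colSums(tab) > 0
  E <- outer(rowSums(tab[, nz, drop = FALSE]),
             colSums(tab[, nz, drop = FALSE])) / sum(tab)
  overall <- sum((tab[, nz, drop = FALSE] - E)^2 / E)
  df <- sum(nz) - 1
  list(per_bin = per, overall_statistic = overall,
       overall_p = pchisq(overall, df = df, lower.tail = FALSE), df = df)
}

#' Bin scores on \[0, 1\] into equal-width bins
#' @param scores Numeric vector in \[0, 1\].
#' @param n_bins Number of bins (default 10).
#' @return Integer vector of per-bin counts.
#' @export
bin_scores <- function(scores, n_bins = 10L) {
  stopifnot(all(scores >= 0 & scores <= 1))
  idx <- pmin(floor(scores * n_bins) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

# round half-up to `digits` decimals (printed-value convention)
.round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Category counts and percentages for an ipTM column
#'
#' Counts of unlikely / plausible / high-confidence models under the triage
#' thresholds, with percentages reported to 2 decimals (half-up rounding, as
#' printed in tabulated results).
#'
#' @param scores Numeric vector of ipTM values in \[0, 1\].
#' @param th [classification_thresholds()].
#' @return List `counts` (named integer vector summing to `n`),
#'   `percentages` (named, 2-decimal), `n`.
#' @export
summarize_categories <- function(scores, th = classification_thresholds()) {
  lev <- c("unlikely", "plausible", "high_confidence")
  if (length(scores) == 0) {
    cnt <- setNames(integer(3), lev)
    return(list(counts = cnt, percentages = setNames(rep(NA_real_, 3), lev),
                n = 0L))
  }
  cat <- factor(classify_iptm(scores, th), levels = lev)
  cnt <- table(cat)
  counts <- setNames(as.integer(cnt), lev)
  list(counts = counts,
       percentages = setNames(.round_half_up(100 * counts / length(scores)),
                              lev),
       n = length(scores))
}

#' Assemble the interactome graph
#'
#' Simple undirected graph over ortholog groups with `iptm`, `pdockq`,
#' `pdockq2`, `category` and `gram_group` edge attributes. Self-loops are
#' rejected; duplicated pairs collapse to a single edge keeping the
#' maximum-ipTM record (mirroring best-model selection).
#'
#' @param edges Data frame with `group_a`, `group_b`, `iptm` and optionally
#'   `pdockq`, `pdockq2`, `category`, `gram_group`.
#' @return An `igraph` object.
#' @export
build_graph <- function(edges) {
  stopifnot(all(c("group_a", "group_b", "iptm") %in% names(edges)))
  if (any(edges$group_a == edges$group_b)) stop("self-loops are not allowed")
  e <- canonicalize_edges(edges)
  e <- e[order(-e$iptm), , drop = FALSE]
  e <- e[!duplicated(paste(e$group_a, e$group_b)), , drop = FALSE]
  keep <- intersect(c("group_a", "group_b", "iptm", "pdockq", "pdockq2",
                      "category", "gram_group"), names(e))
  igraph::graph_from_data_frame(e[, keep], directed = FALSE)
}

#' Export / import an interactome graph
#'
#' `export_graph` writes GraphML or a Cytoscape-compatible edge TSV
#' (`source`, `target`, then edge attributes); `import_graph` reads GraphML
#' back. The GraphML round-trip preserves nodes, edges and numeric
#' attributes.
#'
#' @param graph An `igraph` object.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path` invisibly (`export_graph`); an `igraph`
#'   (`import_graph`).
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     stringsAsFactors = FALSE)
    for (at in igraph::edge_attr_names(graph))
      df[[at]] <- igraph::edge_attr(graph, at)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path) igraph::read_graph(path, format = "graphml")

#' Node degree table of a graph (hub inspection)
#' @param graph An `igraph` object.
#' @return Data frame `node`, `degree`, sorted by decreasing degree.
#' @export
degree_table <- function(graph) {
  d <- igraph::degree(graph)
  out <- data.frame(node = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  out
}
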