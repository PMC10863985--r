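#' @title Candidate-edge construction and filtering for essential interactomes
#' @name interactome_build
#' @description
#' Functions that turn per-species essentiality tables, an ortholog-group map
#' and STRING-format edge lists into a filtered candidate interactome at the
#' ortholog-group level, plus seeded random negative pairs. Edges are plain
#' data frames of class `candidate_edges`; ortholog maps are named character
#' vectors (accession -> group id).
NULL

.edge_cols <- c("group_a", "group_b", "combined_score", "experimental_score",
                "species_support", "origin", "gram_group")

#' Construct a candidate-edge table
#'
#' Builds the canonical edge container used across the package. Pairs are
#' canonicalized so that `group_a < group_b` lexicographically, mirroring an
#' edge list that keeps only one-way (undirected) edges. `species_support` is
#' stored as a `;`-separated string so the table round-trips through TSV.
#'
#' @param group_a,group_b Character vectors of ortholog-group ids.
#' @param combined_score,experimental_score Numeric scores in \[0, 1\].
#' @param species_support Character vector (";"-separated species ids) or list
#'   of character vectors.
#' @param origin One of `"string_evidence"`, `"synthetic_lethal"`,
#'   `"random_negative"` (recycled).
#' @param gram_group `"negative"` or `"positive"` (recycled), or `NA`.
#' @return A `candidate_edges` data frame.
#' @export
candidate_edges <- function(group_a, group_b,
                            combined_score = 0, experimental_score = 0,
                            species_support = "", origin = "string_evidence",
                            gram_group = NA_character_) {
  n <- length(group_a)
  stopifnot(length(group_b) == n)
  if (is.list(species_support)) {
    species_support <- vapply(species_support, function(s)
      paste(sort(unique(s)), collapse = ";"), character(1))
  }
  df <- data.frame(group_a = as.character(group_a),
                   group_b = as.character(group_b),
                   combined_score = rep_len(as.numeric(combined_score), n),
                   experimental_score = rep_len(as.numeric(experimental_score), n),
                   species_support = rep_len(as.character(species_support), n),
                   origin = rep_len(as.character(origin), n),
                   gram_group = rep_len(as.character(gram_group), n),
                   stringsAsFactors = FALSE)
  bad <- df$combined_score < 0 | df$combined_score > 1 |
    df$experimental_score < 0 | df$experimental_score > 1
  if (any(bad, na.rm = TRUE)) stop("scores must lie in [0, 1]")
  if (!all(df$origin %in% c("string_evidence", "synthetic_lethal",
                            "random_negative")))
    stop("unknown edge origin")
  df <- canonicalize_edges(df)
  if (any(df$group_a == df$group_b)) stop("self-pairs are not allowed")
  class(df) <- c("candidate_edges", "data.frame")
  df
}

#' Canonicalize edge endpoint order
#'
#' Swaps endpoints where needed so `group_a` sorts before `group_b`; results
#' are therefore invariant to the endpoint order of the input.
#'
#' @param edges Edge data frame with `group_a`/`group_b` columns.
#' @return The same table with canonically ordered endpoints.
#' @export
canonicalize_edges <- function(edges) {
  swap <- edges$group_a > edges$group_b
  if (any(swap)) {
    tmp <- edges$group_a[swap]
    edges$group_a[swap] <- edges$group_b[swap]
    edges$group_b[swap] <- tmp
  }
  edges
}

.pair_key <- function(edges) paste(edges$group_a, edges$group_b, sep = "\t")

.merge_support <- function(...) {
  s <- unlist(strsplit(c(...), ";", fixed = TRUE))
  paste(sort(unique(s[nzchar(s)])), collapse = ";")
}

#' Deduplicate edges to one record per unordered pair
#'
#' Species support is unioned; scores keep the per-pair maximum; origins are
#' merged (a pair seen both as STRING evidence and as a synthetic-lethal pair
#' is recorded with both labels, `;`-joined).
#'
#' @param edges A `candidate_edges` table.
#' @return Deduplicated `candidate_edges`.
#' @export
dedup_edges <- function(edges) {
  edges <- canonicalize_edges(edges)
  key <- .pair_key(edges)
  if (!anyDuplicated(key)) return(edges[order(key), , drop = FALSE])
  out <- lapply(split(seq_len(nrow(edges)), key), function(i) {
    e <- edges[i, , drop = FALSE]
    data.frame(group_a = e$group_a[1], group_b = e$group_b[1],
               combined_score = max(e$combined_score),
               experimental_score = max(e$experimental_score),
               species_support = .merge_support(e$species_support),
               origin = paste(sort(unique(unlist(
                 strsplit(e$origin, ";", fixed = TRUE)))), collapse = ";"),
               gram_group = e$gram_group[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("candidate_edges", "data.frame")
  out
}

#' Edge-filter configuration
#'
#' Thresholds follow the source-selection rules used to assemble the
#' interactome: STRING combined score strictly above `combined_min` and/or
#' experimental sub-score strictly above `experimental_min`; an interaction
#' is essential only when both partners are essential; pairs touching
#' excluded families (ribosomal proteins, tRNA ligases by default) are
#' discarded; and consensus requires support in at least
#' `min_species_support` species.
#'
#' @param combined_min,experimental_min Score thresholds in \[0, 1\]
#'   (defaults 0.7 and 0.15; applied strictly, `>` not `>=`).
#' @param min_species_support,min_essential_species Minimum species counts
#'   (defaults 2).
#' @param excluded_families Character vector of family labels to discard.
#' @param seed Integer seed used by downstream random sampling.
#' @return A list of class `edge_filter_config`.
#' @export
edge_filter_config <- function(combined_min = 0.7, experimental_min = 0.15,
                               min_species_support = 2L,
                               min_essential_species = 2L,
                               excluded_families = c("ribosomal", "tRNA_ligase"),
                               seed = 1L) {
  stopifnot(combined_min >= 0, combined_min <= 1,
            experimental_min >= 0, experimental_min <= 1,
            min_species_support >= 1, min_essential_species >= 1)
  structure(list(combined_min = combined_min,
                 experimental_min = experimental_min,
                 min_species_support = as.integer(min_species_support),
                 min_essential_species = as.integer(min_essential_species),
                 excluded_families = excluded_families,
                 seed = as.integer(seed)),
            class = "edge_filter_config")
}

#' Compile the consensus essential set
#'
#' Maps per-species essentiality records onto ortholog groups and keeps the
#' groups flagged essential in at least `min_essential_species` distinct
#' species. Accessions absent from the ortholog map are collected, reported
#' via a warning, and skipped; duplicated (species, accession) rows are
#' deduplicated silently.
#'
#' @param records Data frame with columns `species_id`, `accession` (extra
#'   columns such as `locus_tag`, `gene_name`, `source` are carried but not
#'   used).
#' @param orthologs Named character vector mapping accession -> ortholog
#'   group id.
#' @param min_essential_species Minimum number of distinct species (default 2).
#' @return Character vector of essential ortholog-group ids (sorted).
#' @export
compile_essential_set <- function(records, orthologs,
                                  min_essential_species = 2L) {
  if (is.null(records) || nrow(records) == 0) {
    warning("no essentiality records supplied; essential set is empty")
    return(character(0))
  }
  stopifnot(all(c("species_id", "accession") %in% names(records)))
  if (any(!nzchar(records$accession))) stop("empty accession in records")
  records <- records[!duplicated(records[c("species_id", "accession")]), ]
  hit <- records$accession %in% names(orthologs)
  if (!all(hit)) {
    miss <- unique(records$accession[!hit])
    warning(sprintf("%d accession(s) not resolvable in ortholog map, skipped: %s",
                    length(miss), paste(head(miss, 5), collapse = ", ")))
    records <- records[hit, , drop = FALSE]
  }
  grp <- unname(orthologs[records$accession])
  tab <- tapply(records$species_id, grp, function(s) length(unique(s)))
  sort(names(tab)[tab >= min_essential_species])
}

#' Filter STRING-format edges into candidate essential interactions
#'
#' Keeps an edge iff (combined score strictly above the combined threshold OR
#' experimental score strictly above the experimental threshold) AND both
#' endpoints belong to the essential set AND neither endpoint is annotated
#' with an excluded family. Output is deduplicated to one record per
#' unordered pair. Synthetic-lethal edges, when present in the input, bypass
#' the both-essential requirement (they capture pairs that are only essential
#' in combination) but still face the family exclusion.
#'
#' @param edges `candidate_edges` table (endpoints at ortholog-group level).
#' @param essential Character vector of essential group ids.
#' @param config An [edge_filter_config()].
#' @param family_annotation Named character vector, group id -> family label.
#'   Endpoints absent from the annotation are treated as not excluded.
#' @return Filtered, deduplicated `candidate_edges`.
#' @export
filter_string_edges <- function(edges, essential, config = edge_filter_config(),
                                family_annotation = NULL) {
  if (nrow(edges) == 0) return(edges)
  edges <- canonicalize_edges(edges)
  score_ok <- edges$combined_score > config$combined_min |
    edges$experimental_score > config$experimental_min
  ess_ok <- edges$group_a %in% essential & edges$group_b %in% essential
  sl <- grepl("synthetic_lethal", edges$origin, fixed = TRUE)
  keep <- (score_ok & ess_ok) | sl
  if (!is.null(family_annotation)) {
    fam_a <- family_annotation[edges$group_a]
    fam_b <- family_annotation[edges$group_b]
    excl <- (!is.na(fam_a) & fam_a %in% config$excluded_families) |
      (!is.na(fam_b) & fam_b %in% config$excluded_families)
    keep <- keep & !excl
  }
  dedup_edges(edges[keep, , drop = FALSE])
}

#' Consensus across species edge lists
#'
#' Combines per-species filtered edge lists and keeps unordered pairs seen in
#' at least `min_species_support` species; `species_support` on the output is
#' the union of contributing species. Synthetic-lethal edges are exempt from
#' the multi-species rule (their source is a single-species screen).
#'
#' @param per_species_edges Named list, species id -> `candidate_edges`.
#' @param min_species_support Minimum number of supporting species.
#' @return Consensus `candidate_edges`.
#' @export
consensus_edges <- function(per_species_edges, min_species_support = 2L) {
  stopifnot(is.list(per_species_edges))
  tagged <- Map(function(sp, e) {
    if (nrow(e) > 0 && any(!nzchar(e$species_support)))
      e$species_support[!nzchar(e$species_support)] <- sp
    e
  }, names(per_species_edges), per_species_edges)
  all_e <- do.call(rbind, unname(tagged))
  if (is.null(all_e) || nrow(all_e) == 0) {
    return(candidate_edges(character(0), character(0)))
  }
  class(all_e) <- c("candidate_edges", "data.frame")
  merged <- dedup_edges(all_e)
  nsup <- vapply(strsplit(merged$species_support, ";", fixed = TRUE),
                 function(s) length(unique(s[nzchar(s)])), integer(1))
  sl <- grepl("synthetic_lethal", merged$origin, fixed = TRUE)
  merged[nsup >= min_species_support | sl, , drop = FALSE]
}

#' Merge synthetic-lethal pairs into an edge table
#'
#' Maps accession pairs to ortholog groups and appends them with origin
#' `synthetic_lethal`. Pairs duplicating an existing edge are merged into a
#' single record whose origin carries both labels. Self-pairs (both
#' accessions in the same group) are an error; unmappable accessions are an
#' error, since downstream modeling needs group-level identities.
#'
#' @param edges Existing `candidate_edges`.
#' @param sl_pairs Two-column data frame (or matrix) of accessions.
#' @param orthologs Named character vector, accession -> group id.
#' @return Augmented `candidate_edges`.
#' @export
merge_synthetic_lethal <- function(edges, sl_pairs, orthologs) {
  if (is.null(sl_pairs) || NROW(sl_pairs) == 0) return(edges)
  a <- as.character(sl_pairs[[1]]); b <- as.character(sl_pairs[[2]])
  if (any(!(a %in% names(orthologs))) || any(!(b %in% names(orthologs))))
    stop("synthetic-lethal accession not present in ortholog map")
  ga <- unname(orthologs[a]); gb <- unname(orthologs[b])
  if (any(ga == gb)) stop("synthetic-lethal self-pair after ortholog mapping")
  sl <- candidate_edges(ga, gb, origin = "synthetic_lethal",
                        gram_group = if (nrow(edges)) edges$gram_group[1] else NA)
  out <- rbind(edges, sl)
  class(out) <- c("candidate_edges", "data.frame")
  dedup_edges(out)
}

#' Generate seeded random negative pairs
#'
#' Rejection-samples `n` distinct unordered pairs from the given proteins,
#' excluding self-pairs and any pair present in `positives`. Identical seeds
#' give identical output.
#'
#' @param proteins Character vector of ortholog-group ids.
#' @param n Number of negative pairs.
#' @param positives `candidate_edges` table or 2-column data frame of pairs
#'   to exclude.
#' @param seed Integer seed.
#' @return `candidate_edges` with origin `random_negative`.
#' @export
generate_random_negatives <- function(proteins, n, positives = NULL, seed = 1L) {
  proteins <- sort(unique(as.character(proteins)))
  p <- length(proteins)
  pos_keys <- character(0)
  if (!is.null(positives) && NROW(positives) > 0) {
    pa <- as.character(positives[[1]]); pb <- as.character(positives[[2]])
    swap <- pa > pb
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
    pos_keys <- unique(paste(pa, pb, sep = "\t"))
    pos_keys <- pos_keys[vapply(strsplit(pos_keys, "\t"), function(x)
      all(x %in% proteins) && x[1] != x[2], logical(1))]
  }
  avail <- choose(p, 2) - length(pos_keys)
  if (n > avail)
    stop(sprintf("requested %d negatives but only %d non-positive pairs exist",
                 n, avail))
  if (n == 0) return(candidate_edges(character(0), character(0)))
  out <- character(0)
  set.seed(seed)
  while (length(out) < n) {
    k <- max(2 * (n - length(out)), 16L)
    i <- sample.int(p, k, replace = TRUE)
    j <- sample.int(p, k, replace = TRUE)
    ok <- i != j
    a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
    key <- paste(proteins[a], proteins[b], sep = "\t")
    key <- setdiff(unique(key), c(pos_keys, out))
    out <- c(out, key)
  }
  out <- out[seq_len(n)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  candidate_edges(vapply(parts, `[`, character(1), 1),
                  vapply(parts, `[`, character(1), 2),
                  origin = "random_negative")
}

#' Run the full interactome construction pipeline
#'
#' Per-species threshold filtering, multi-species consensus, synthetic-lethal
#' merge, and optional random-negative generation, in the order the analysis
#' applies them: thresholds and the both-essential rule are applied to each
#' species edge list before consensus.
#'
#' @param essentiality Data frame of essentiality records (all species).
#' @param orthologs Named character vector, accession -> group id.
#' @param string_edges Named list, species id -> `candidate_edges` at group
#'   level (see [read_string_edges()]).
#' @param config [edge_filter_config()].
#' @param family_annotation Named vector group id -> family, or `NULL`.
#' @param sl_pairs Optional synthetic-lethal accession pairs.
#' @param n_negatives Number of random negatives to draw (0 for none).
#' @param gram_group Label stamped on the output edges.
#' @return List with `positives`, `negatives`, `essential` (group ids).
#' @export
build_interactome <- function(essentiality, orthologs, string_edges,
                              config = edge_filter_config(),
                              family_annotation = NULL, sl_pairs = NULL,
                              n_negatives = 0L, gram_group = NA_character_) {
  essential <- compile_essential_set(essentiality, orthologs,
                                     config$min_essential_species)
  per_sp <- lapply(string_edges, filter_string_edges, essential = essential,
                   config = config, family_annotation = family_annotation)
  pos <- consensus_edges(per_sp, config$min_species_support)
  if (!is.null(sl_pairs)) pos <- merge_synthetic_lethal(pos, sl_pairs, orthologs)
  if (nrow(pos)) pos$gram_group <- gram_group
  neg <- NULL
  if (n_negatives > 0) {
    prots <- sort(unique(c(pos$group_a, pos$group_b, essential)))
    neg <- generate_random_negatives(prots, n_negatives, pos, config$seed)
    if (nrow(neg)) neg$gram_group <- gram_group
  }
  list(positives = pos, negatives = neg, essential = essential)
}

# ---- tabular IO ------------------------------------------------------------

#' Read a STRING-dialect edge TSV
#'
#' Expects columns `protein1`, `protein2`, `experimental`, `combined` (extra
#' columns ignored). Scores given as 0-1000 integers (STRING's native export
#' scale) are auto-detected and normalized to \[0, 1\]. Accessions are mapped
#' to ortholog groups when a map is supplied; unmapped rows are dropped with
#' a warning.
#'
#' @param path TSV path.
#' @param species_id Species label stamped into `species_support`.
#' @param orthologs Optional named vector accession -> group id.
#' @param gram_group Optional gram label.
#' @return `candidate_edges`.
#' @export
read_string_edges <- function(path, species_id, orthologs = NULL,
                              gram_group = NA_character_) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein1", "protein2", "experimental", "combined")
  if (!all(need %in% names(df)))
    stop("STRING edge file must have columns protein1, protein2, experimental, combined")
  norm <- function(x) {
    x <- as.numeric(x)
    if (length(x) && max(x, na.rm = TRUE) > 1) x / 1000 else x
  }
  a <- df$protein1; b <- df$protein2
  if (!is.null(orthologs)) {
    ok <- a %in% names(orthologs) & b %in% names(orthologs)
    if (!all(ok))
      warning(sprintf("%d edge row(s) with unmapped accessions dropped", sum(!ok)))
    df <- df[ok, , drop = FALSE]
    a <- unname(orthologs[df$protein1]); b <- unname(orthologs[df$protein2])
  }
  keep <- a != b
  candidate_edges(a[keep], b[keep],
                  combined_score = norm(df$combined)[keep],
                  experimental_score = norm(df$experimental)[keep],
                  species_support = species_id, gram_group = gram_group)
}

#' Read an essentiality TSV
#'
#' Columns: `species_id`, `accession`, optional `locus_tag`, `gene_name`,
#' `source`.
#' @param path TSV path.
#' @return Data frame of essentiality records.
#' @export
read_essentiality_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species_id", "accession") %in% names(df)))
  df
}

#' Read an ortholog map TSV (columns `accession`, `group_id`)
#' @param path TSV path.
#' @return Named character vector accession -> group id.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "group_id") %in% names(df)))
  if (anyDuplicated(df$accession)) stop("accession maps to more than one group")
  setNames(as.character(df$group_id), df$accession)
}

#' Write / read the canonical edge TSV
#' @param edges `candidate_edges`.
#' @param path TSV path.
#' @return `write_edges_tsv` returns `path` invisibly; `read_edges_tsv`
#'   returns `candidate_edges`.
#' @export
write_edges_tsv <- function(edges, path) {
  write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(species_support = "character",
                                  origin = "character",
                                  gram_group = "character"))
  df$species_support[is.na(df$species_support)] <- ""
  class(df) <- c("candidate_edges", "data.frame")
  df
}
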