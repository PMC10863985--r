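#' @title Interface, surface and conservation analysis of binary complexes
#' @name interface_analysis
#' @description
#' Contact/interface/surface residue extraction with the analysis cutoffs
#' (4.5 A contacts, 10 A interface, 6.5 A^2 exposed-atom surface criterion),
#' a Shrake-Rupley solvent-accessible surface area implementation, buried
#' interface area, interface-versus-surface conservation contrasts
#' (Wilcoxon rank-sum), and residue-type contact networks aggregated over
#' high-confidence models.
NULL

#' Interface analysis configuration
#'
#' @param contact_cutoff Heavy-atom contact distance, Angstrom (default 4.5).
#' @param interface_cutoff Interface distance, Angstrom (default 10).
#' @param surface_atom_sasa_min Exposed-area threshold per atom, Angstrom^2,
#'   above which an atom (and its residue) counts as surface (default 6.5).
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4).
#' @param sphere_points Number of test points per atom sphere (default 960).
#' @return List of class `interface_config`.
#' @export
interface_config <- function(contact_cutoff = 4.5, interface_cutoff = 10,
                             surface_atom_sasa_min = 6.5, probe_radius = 1.4,
                             sphere_points = 960L) {
  stopifnot(contact_cutoff > 0, contact_cutoff <= interface_cutoff,
            probe_radius > 0, sphere_points >= 16)
  structure(list(contact_cutoff = contact_cutoff,
                 interface_cutoff = interface_cutoff,
                 surface_atom_sasa_min = surface_atom_sasa_min,
                 probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points)),
            class = "interface_config")
}

#' Interchain contact residue pairs (heavy-atom criterion)
#'
#' Residue pairs across the two chains with any heavy-atom pair within
#' `contact_cutoff` (inclusive).
#'
#' @param model Two-chain `structure_model`.
#' @param config [interface_config()].
#' @return Data frame `chain_a`, `resno_a`, `chain_b`, `resno_b`,
#'   `min_dist`.
#' @export
find_contact_residues <- function(model, config = interface_config()) {
  ab <- .two_chains(model)
  A <- .heavy(ab$a); B <- .heavy(ab$b)
  d <- .crossdist(.xyz(A), .xyz(B))
  ka <- paste(A$chain, A$resno); kb <- paste(B$chain, B$resno)
  hit <- which(d <= config$contact_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      min_dist = numeric(0)))
  pair <- paste(ka[hit[, 1]], kb[hit[, 2]], sep = "|")
  md <- tapply(d[hit], pair, min)
  parts <- strsplit(names(md), "[| ]")
  data.frame(chain_a = vapply(parts, `[`, "", 1),
             resno_a = as.integer(vapply(parts, `[`, "", 2)),
             chain_b = vapply(parts, `[`, "", 3),
             resno_b = as.integer(vapply(parts, `[`, "", 4)),
             min_dist = as.numeric(md), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Interface residues of a two-chain model
#'
#' Residues with any heavy atom within `interface_cutoff` of any heavy atom
#' of the other chain. Contact residues (4.5 A) are always a subset.
#'
#' @param model Two-chain `structure_model`.
#' @param config [interface_config()].
#' @return Data frame `chain`, `resno`.
#' @export
find_interface_residues <- function(model, config = interface_config()) {
  ab <- .two_chains(model)
  A <- .heavy(ab$a); B <- .heavy(ab$b)
  d <- .crossdist(.xyz(A), .xyz(B))
  near_a <- apply(d, 1, min) <= config$interface_cutoff
  near_b <- apply(d, 2, min) <= config$interface_cutoff
  out <- rbind(data.frame(chain = A$chain[near_a], resno = A$resno[near_a]),
               data.frame(chain = B$chain[near_b], resno = B$resno[near_b]))
  out <- unique(out)
  rownames(out) <- NULL
  out
}

.sphere_points <- function(n) {
  # golden-spiral (Fibonacci) lattice: near-uniform points on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(elements, radii = score_constants()$vdw_radii) {
  r <- unlist(radii[elements])
  unknown <- !(elements %in% names(radii))
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s assigned default vdW radius %.2f",
                    paste(unique(elements[unknown]), collapse = ", "),
                    radii$default))
  }
  out <- numeric(length(elements))
  out[!unknown] <- unlist(radii[elements[!unknown]])
  out[unknown] <- radii$default
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic test-point algorithm: each heavy atom's van der Waals sphere is
#' inflated by the probe radius and covered with a near-uniform point
#' lattice; the atom's SASA is the sphere area times the fraction of points
#' not buried inside any neighbouring inflated sphere. Hydrogens are
#' ignored (predicted models do not carry them).
#'
#' @param model A `structure_model` (any number of chains).
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param sphere_points Test points per atom (default 960).
#' @param radii Named list of element van der Waals radii with a `default`
#'   entry (default: the shipped published set).
#' @return Numeric vector of per-atom SASA (Angstrom^2) for the heavy atoms,
#'   with attribute `atoms` giving their `chain`, `resno`, `elety` table.
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4,
                               sphere_points = 960L,
                               radii = score_constants()$vdw_radii) {
  atoms <- .heavy(model$atoms)
  n <- nrow(atoms)
  xyz <- .xyz(atoms)
  r <- .atom_radii(atoms$element, radii) + probe_radius
  pts <- .sphere_points(sphere_points)
  out <- numeric(n)
  # neighbour search via cell-free cutoff: atoms within r_i + max(r) can bury
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r[i] + rmax)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (length(nb) == 0) {
      out[i] <- 4 * pi * r[i]^2
      next
    }
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    # a point is buried if inside any neighbour's inflated sphere
    free <- rep(TRUE, sphere_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- colSums((t(sp[free, , drop = FALSE]) - xyz[j, ])^2)
      free[free] <- dj2 >= r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * sum(free) / sphere_points
  }
  attr(out, "atoms") <- atoms[, c("chain", "resno", "resid", "elety")]
  out
}

#' Buried interface area of a two-chain complex
#'
#' SASA(chain A alone) + SASA(chain B alone) - SASA(complex); non-negative
#' up to quadrature tolerance. Also returns the per-chain split
#' (delta-SASA of each chain), since either convention can be reported.
#'
#' @param model Two-chain `structure_model`.
#' @param config [interface_config()] (probe radius and sphere points).
#' @return List `buried_area`, `delta_chain` (named per-chain delta-SASA),
#'   `sasa_complex`.
#' @export
buried_interface_area <- function(model, config = interface_config()) {
  ab <- .two_chains(model)
  sasa_all <- shrake_rupley_sasa(model, config$probe_radius,
                                 config$sphere_points)
  ch <- attr(sasa_all, "atoms")$chain
  iso <- lapply(list(ab$a, ab$b), function(at)
    sum(shrake_rupley_sasa(structure_model(at, "chain"),
                           config$probe_radius, config$sphere_points)))
  in_complex <- vapply(ab$ids, function(c) sum(sasa_all[ch == c]), numeric(1))
  delta <- unlist(iso) - in_complex
  names(delta) <- ab$ids
  list(buried_area = sum(delta), delta_chain = delta,
       sasa_complex = sum(sasa_all))
}

#' Surface residues of a chain
#'
#' Computes per-atom SASA on each isolated chain and returns residues owning
#' at least one atom with exposed area >= `surface_atom_sasa_min`.
#'
#' @param model A `structure_model`.
#' @param config [interface_config()].
#' @return Data frame `chain`, `resno`.
#' @export
find_surface_residues <- function(model, config = interface_config()) {
  out <- lapply(chain_ids(model), function(ch) {
    at <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    s <- shrake_rupley_sasa(structure_model(at, "chain"),
                            config$probe_radius, config$sphere_points)
    tab <- attr(s, "atoms")
    keep <- s >= config$surface_atom_sasa_min
    unique(data.frame(chain = tab$chain[keep], resno = tab$resno[keep]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interface-versus-surface conservation contrast
#'
#' Two-sided Wilcoxon rank-sum test with tie correction between the
#' conservation scores of interface residues and of (non-interface) surface
#' residues, plus the one-sided p-value for interface more conserved than
#' surface and both medians.
#'
#' @param interface_scores,surface_scores Numeric vectors (each n >= 2) of
#'   1-9 conservation scores.
#' @return List `statistic`, `p_two_sided`, `p_greater`,
#'   `median_interface`, `median_surface`.
#' @export
conservation_contrast <- function(interface_scores, surface_scores) {
  if (length(interface_scores) < 2 || length(surface_scores) < 2)
    stop("each sample needs at least 2 values")
  two <- suppressWarnings(wilcox.test(interface_scores, surface_scores,
                                      alternative = "two.sided",
                                      exact = FALSE, correct = TRUE))
  gr <- suppressWarnings(wilcox.test(interface_scores, surface_scores,
                                     alternative = "greater",
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(two$statistic),
       p_two_sided = two$p.value, p_greater = gr$p.value,
       median_interface = median(interface_scores),
       median_surface = median(surface_scores))
}

#' Full interface report for one complex
#'
#' Bundles contact/interface/surface residue sets, per-atom SASA, buried
#' area and (when a conservation track is given) the interface-vs-surface
#' conservation contrast. The surface contrast set excludes interface
#' residues.
#'
#' @param model Two-chain `structure_model`.
#' @param conservation Optional data frame `chain`, `resno`, `score`.
#' @param config [interface_config()].
#' @return List of class `interface_report`.
#' @export
interface_report <- function(model, conservation = NULL,
                             config = interface_config()) {
  contacts <- find_contact_residues(model, config)
  iface <- find_interface_residues(model, config)
  surf <- find_surface_residues(model, config)
  ikey <- paste(iface$chain, iface$resno)
  surf_only <- surf[!(paste(surf$chain, surf$resno) %in% ikey), , drop = FALSE]
  sasa <- shrake_rupley_sasa(model, config$probe_radius, config$sphere_points)
  buried <- buried_interface_area(model, config)
  cons <- NULL
  if (!is.null(conservation)) {
    ck <- paste(conservation$chain, conservation$resno)
    a <- conservation$score[ck %in% ikey]
    b <- conservation$score[ck %in% paste(surf_only$chain, surf_only$resno)]
    if (length(a) >= 2 && length(b) >= 2) {
      cons <- conservation_contrast(a, b)
    } else {
      warning("too few interface or surface residues for a conservation contrast")
    }
  }
  structure(list(contact_pairs = contacts, interface_residues = iface,
                 surface_residues = surf_only, per_atom_sasa = sasa,
                 buried_area = buried$buried_area,
                 delta_chain = buried$delta_chain,
                 conservation_stats = cons),
            class = "interface_report")
}

.sidechain_atoms <- function(atoms) {
  sc <- .heavy(atoms)
  gly <- sc$resid == "GLY"
  keep <- (!(sc$elety %in% .backbone_atoms)) | (gly & sc$elety == "CA")
  sc[keep, , drop = FALSE]
}

#' Residue-type contact network over a model set
#'
#' For each model (intended: the high-confidence category), every interchain
#' residue pair whose side-chain heavy atoms come within `contact_cutoff`
#' adds 1 to the weight of the undirected edge between the two residue
#' types (self-edges such as LEU-LEU allowed). Glycine's side chain is its
#' C-alpha.
#'
#' @param models List of two-chain `structure_model`s.
#' @param config [interface_config()].
#' @return `igraph` undirected weighted graph over residue types present.
#' @export
residue_type_network <- function(models, config = interface_config()) {
  tally <- new.env(parent = emptyenv())
  for (m in models) {
    ab <- .two_chains(m)
    A <- .sidechain_atoms(ab$a); B <- .sidechain_atoms(ab$b)
    if (nrow(A) == 0 || nrow(B) == 0) next
    d <- .crossdist(.xyz(A), .xyz(B))
    hit <- which(d <= config$contact_cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    pair <- unique(data.frame(ra = paste(A$chain[hit[, 1]], A$resno[hit[, 1]]),
                              ta = A$resid[hit[, 1]],
                              rb = paste(B$chain[hit[, 2]], B$resno[hit[, 2]]),
                              tb = B$resid[hit[, 2]]))
    key <- ifelse(pair$ta <= pair$tb, paste(pair$ta, pair$tb),
                  paste(pair$tb, pair$ta))
    for (k in key) assign(k, (tally[[k]] %||% 0) + 1, envir = tally)
  }
  keys <- ls(tally)
  if (length(keys) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(keys, " ")
  el <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2),
                   weight = vapply(keys, function(k) tally[[k]], numeric(1)))
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Edge-list table of a residue-type network
#' @param graph Result of [residue_type_network()].
#' @return Data frame `type_a`, `type_b`, `weight`.
#' @export
residue_type_edges <- function(graph) {
  if (igraph::ecount(graph) == 0)
    return(data.frame(type_a = character(0), type_b = character(0),
                      weight = numeric(0)))
  el <- igraph::as_edgelist(graph)
  data.frame(type_a = el[, 1], type_b = el[, 2],
             weight = igraph::E(graph)$weight, stringsAsFactors = FALSE)
}

#' Read a per-residue conservation TSV
#'
#' Columns `chain`, `resno`, `score`; scores must be integers 1 (most
#' variable) to 9 (most conserved).
#'
#' @param path TSV path.
#' @return Data frame `chain`, `resno`, `score`.
#' @export
read_conservation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chain = "character"))
  stopifnot(all(c("chain", "resno", "score") %in% names(df)))
  if (any(df$score < 1 | df$score > 9 | df$score != round(df$score)))
    stop("conservation scores must be integers in 1..9")
  df
}
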