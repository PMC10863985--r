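#' @title Seeded synthetic-data generators
#' @name synthetic_data
#' @description
#' Pure-function generators (byte-identical reruns for a fixed seed) for
#' every input class the pipeline consumes: multi-species essentiality and
#' STRING-dialect edge tables with known ground truth, two-chain coordinate
#' models built from ideal polyalanine helices with controllable interface
#' separation and perturbation, confidence bundles (per-model ipTM, pLDDT,
#' PAE) with controllable quality, and 1-9 conservation tracks with a
#' controllable interface shift. These are geometric/statistical surrogates
#' for structure-prediction output: their contract is the orderings and
#' ground-truth sets asserted in tests, not physical realism.
NULL

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: four species
#' per Gram group with consensus at two species, STRING-style scores on
#' \[0, 1\], and small helix dimers whose interface size is set by the
#' helix-axis separation.
#'
#' @param seed Integer seed.
#' @param n_species Species per Gram group (default 4).
#' @param n_proteins Ortholog groups in the simulated universe (default 60).
#' @param essential_fraction Per-species probability that a group is
#'   essential (default 0.6).
#' @param n_true_edges Planted high-evidence edges (default 40).
#' @param score_noise_sd SD of Gaussian noise added to planted scores
#'   (default 0.05).
#' @param dimer_length Residues per helix chain (default 24, >= 8).
#' @param interface_separation Helix-axis separation in Angstrom
#'   (default 9).
#' @param axial_offset Offset of chain B along the helix axis, Angstrom
#'   (default 0); a non-zero value localizes the interface to the
#'   overlapping segment so that surface-only residues exist.
#' @param perturbation_sd SD of Gaussian coordinate noise for the perturbed
#'   dimer copy (default 0.5).
#' @param rigid_offset Rigid x-offset (Angstrom) applied to the second chain
#'   of the perturbed copy (default 0).
#' @param confidence_quality `"high"`, `"medium"` or `"low"`.
#' @param conservation_shift Added to interface conservation scores,
#'   clipped to 1..9 (default 2).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 4L, n_proteins = 60L,
                       essential_fraction = 0.6, n_true_edges = 40L,
                       score_noise_sd = 0.05, dimer_length = 24L,
                       interface_separation = 9, axial_offset = 0,
                       perturbation_sd = 0.5, rigid_offset = 0,
                       confidence_quality = c("high", "medium", "low"),
                       conservation_shift = 2) {
  confidence_quality <- match.arg(confidence_quality)
  stopifnot(n_species >= 1, n_proteins >= 4, n_true_edges >= 0,
            essential_fraction >= 0, essential_fraction <= 1,
            dimer_length >= 8, score_noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# ---- interactome inputs ----------------------------------------------------

.quantize <- function(x) round(pmin(pmax(x, 0), 1) * 1000) / 1000

#' Generate a synthetic interactome input set with ground truth
#'
#' Emits per-species essentiality tables, an ortholog map, a family
#' annotation, STRING-dialect edge tables per species (scores written on
#' STRING's 0-1000 integer scale), a small synthetic-lethal pair list, and a
#' ground-truth record of exactly which planted edges survive the filter
#' rules (score thresholds, both-endpoints-essential, family exclusion,
#' multi-species consensus). Planted edges carry high evidence in a random
#' subset of species; an equal number of decoy edges carries sub-threshold
#' scores; additional edges touch non-essential or excluded-family proteins.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, all tables are written as TSVs
#'   and their paths returned alongside the in-memory objects.
#' @return List with `essentiality`, `orthologs`, `families`,
#'   `string_edges` (named list per species), `sl_pairs`, `ground_truth`
#'   (list `essential_groups`, `kept_edges`, `sl_groups`) and, with `dir`,
#'   `paths`.
#' @export
synth_interactome <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  ns <- cfg$n_species; np <- cfg$n_proteins
  if (cfg$n_true_edges > choose(np, 2) / 3)
    stop("n_true_edges infeasible for n_proteins")
  groups <- sprintf("G%03d", seq_len(np))
  species <- sprintf("sp%d", seq_len(ns))
  # family annotation: a handful of excluded-family groups
  fam <- rep("other", np)
  fam[sample.int(np, max(2, np %/% 20))] <- "ribosomal"
  fam[sample(which(fam == "other"), max(1, np %/% 30))] <- "tRNA_ligase"
  names(fam) <- groups
  # per-species essentiality
  ess <- matrix(runif(np * ns) < cfg$essential_fraction, np, ns,
                dimnames = list(groups, species))
  essential_groups <- groups[rowSums(ess) >= 2]
  acc <- function(sp, g) paste(sp, g, sep = "_")
  ess_rows <- do.call(rbind, lapply(species, function(sp) {
    g <- groups[ess[, sp]]
    if (length(g) == 0) return(NULL)
    data.frame(species_id = sp, accession = acc(sp, g),
               locus_tag = paste0("lt_", g), gene_name = tolower(g),
               source = "synthetic_screen", stringsAsFactors = FALSE)
  }))
  orthologs <- setNames(rep(groups, each = ns),
                        as.vector(vapply(groups, function(g)
                          acc(species, g), character(ns))))
  # planted edge universe: true (high evidence), decoy (low evidence)
  all_pairs <- t(combn(np, 2))
  pick <- sample.int(nrow(all_pairs), 2 * cfg$n_true_edges)
  true_idx <- pick[seq_len(cfg$n_true_edges)]
  decoy_idx <- pick[-seq_len(cfg$n_true_edges)]
  mk_edges <- function(idx, high) {
    do.call(rbind, lapply(idx, function(k) {
      ga <- groups[all_pairs[k, 1]]; gb <- groups[all_pairs[k, 2]]
      in_sp <- sample(species, sample(ns, 1))
      do.call(rbind, lapply(in_sp, function(sp) {
        if (high) {
          comb <- runif(1, 0.78, 0.99); expm <- runif(1, 0.2, 0.9)
        } else {
          comb <- runif(1, 0, 0.6); expm <- runif(1, 0, 0.1)
        }
        data.frame(species = sp, group_a = ga, group_b = gb,
                   combined = .quantize(comb + rnorm(1, 0, cfg$score_noise_sd)),
                   experimental = .quantize(expm + rnorm(1, 0, cfg$score_noise_sd)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  planted <- rbind(mk_edges(true_idx, TRUE), mk_edges(decoy_idx, FALSE))
  # ground truth from the emitted (quantized) scores: per-species pass,
  # consensus >= 2 species, both endpoints essential, no excluded family
  planted$pass <- planted$combined > 0.7 | planted$experimental > 0.15
  key <- paste(planted$group_a, planted$group_b)
  nsup <- tapply(planted$species[planted$pass], key[planted$pass],
                 function(s) length(unique(s)))
  ok_support <- names(nsup)[nsup >= 2]
  kept <- unique(planted[key %in% ok_support, c("group_a", "group_b")])
  kept <- kept[kept$group_a %in% essential_groups &
                 kept$group_b %in% essential_groups &
                 !(fam[kept$group_a] %in% c("ribosomal", "tRNA_ligase")) &
                 !(fam[kept$group_b] %in% c("ribosomal", "tRNA_ligase")), ]
  kept <- kept[order(kept$group_a, kept$group_b), ]
  rownames(kept) <- NULL
  # synthetic-lethal pairs: accessions of species 1, avoiding planted pairs
  non_planted <- setdiff(seq_len(nrow(all_pairs)), pick)
  sl_idx <- sample(non_planted, 2)
  sl_pairs <- data.frame(
    accession_a = acc(species[1], groups[all_pairs[sl_idx, 1]]),
    accession_b = acc(species[1], groups[all_pairs[sl_idx, 2]]),
    stringsAsFactors = FALSE)
  sl_groups <- data.frame(group_a = groups[all_pairs[sl_idx, 1]],
                          group_b = groups[all_pairs[sl_idx, 2]],
                          stringsAsFactors = FALSE)
  # STRING-dialect tables per species (accession space, 0-1000 scores)
  string_edges <- lapply(species, function(sp) {
    e <- planted[planted$species == sp, , drop = FALSE]
    data.frame(protein1 = acc(sp, e$group_a), protein2 = acc(sp, e$group_b),
               experimental = as.integer(round(e$experimental * 1000)),
               combined = as.integer(round(e$combined * 1000)),
               stringsAsFactors = FALSE)
  })
  names(string_edges) <- species
  out <- list(essentiality = ess_rows, orthologs = orthologs, families = fam,
              string_edges = string_edges, sl_pairs = sl_pairs,
              ground_truth = list(essential_groups = essential_groups,
                                  kept_edges = kept, sl_groups = sl_groups))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(essentiality = file.path(dir, "essentiality.tsv"),
                  orthologs = file.path(dir, "orthologs.tsv"),
                  families = file.path(dir, "families.tsv"),
                  sl_pairs = file.path(dir, "sl_pairs.tsv"))
    write.table(ess_rows, paths$essentiality, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(accession = names(orthologs),
                           group_id = unname(orthologs)),
                paths$orthologs, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(group_id = names(fam), family = unname(fam)),
                paths$families, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sl_pairs, paths$sl_pairs, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$string_edges <- vapply(species, function(sp) {
      p <- file.path(dir, sprintf("string_edges_%s.tsv", sp))
      write.table(string_edges[[sp]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      p
    }, character(1))
    out$paths <- paths
  }
  out
}

# ---- coordinate fixtures ---------------------------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D given A-B-C, bond length r (C-D), bond angle theta (B-C-D,
# degrees) and torsion phi (A-B-C-D, degrees); natural extension reference
# frame construction
.place_atom <- function(A, B, C, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# ideal polyalanine helix (N, CA, C, O, CB) with standard geometry
.ideal_helix <- function(n_res, phi = -57, psi = -47, chain = "A") {
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_CNCa <- 121.7; a_NCaC <- 111.2; a_CaCN <- 116.2
  rows <- list()
  # seed residue in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(b_NCa, 0, 0)
  ang <- a_NCaC * pi / 180
  C <- CA + b_CaC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    rows[[length(rows) + 1]] <- list(i, "N", "N", N)
    rows[[length(rows) + 1]] <- list(i, "CA", "C", CA)
    CB <- .place_atom(C, N, CA, 1.521, 110.5, -122.6)
    rows[[length(rows) + 1]] <- list(i, "CB", "C", CB)
    rows[[length(rows) + 1]] <- list(i, "C", "C", C)
    if (i < n_res) {
      Nn <- .place_atom(N, CA, C, b_CN, a_CaCN, psi)
      CAn <- .place_atom(CA, C, Nn, b_NCa, a_CNCa, 180)
      Cn <- .place_atom(C, Nn, CAn, b_CaC, a_NCaC, phi)
      O <- .place_atom(Nn, CA, C, 1.231, 120.8, 180)  # trans to next N
      rows[[length(rows) + 1]] <- list(i, "O", "O", O)
      N <- Nn; CA <- CAn; C <- Cn
    } else {
      O <- .place_atom(N, CA, C, 1.231, 120.8, psi + 180)
      rows[[length(rows) + 1]] <- list(i, "O", "O", O)
    }
  }
  xyz <- t(vapply(rows, function(r) r[[4]], numeric(3)))
  atoms <- data.frame(chain = chain,
                      resno = vapply(rows, function(r) r[[1]], numeric(1)),
                      resid = "ALA",
                      elety = vapply(rows, function(r) r[[2]], character(1)),
                      element = vapply(rows, function(r) r[[3]], character(1)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0,
                      stringsAsFactors = FALSE)
  # align the helix axis (first principal component of CA) to +z, centered
  ca <- as.matrix(atoms[atoms$elety == "CA", c("x", "y", "z")])
  ctr <- colMeans(ca)
  ax <- prcomp(ca)$rotation[, 1]
  z <- c(0, 0, 1)
  v <- .cross3(ax, z); s <- sqrt(sum(v^2)); cc <- sum(ax * z)
  R <- if (s < 1e-12) diag(3) * sign(cc) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
  }
  m <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, ctr) %*% t(R)
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

#' Generate a native and a perturbed two-chain helix dimer
#'
#' Chain A is an ideal polyalanine alpha-helix (phi = -57, psi = -47,
#' standard bond geometry) with its axis on z; chain B is a copy rotated
#' 180 degrees about z and offset along x by `interface_separation`, giving
#' a parallel helix pair whose interface size is controlled by the
#' separation. The perturbed copy adds seeded Gaussian coordinate noise
#' (`perturbation_sd`) to all atoms and a rigid x-offset (`rigid_offset`)
#' to chain B.
#'
#' @param cfg A [sim_config()].
#' @return List `native`, `perturbed` (both `structure_model`s).
#' @export
synth_dimer <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  A <- .ideal_helix(cfg$dimer_length, chain = "A")
  B <- A
  B$chain <- "B"
  B$x <- -B$x + cfg$interface_separation
  B$y <- -B$y
  B$z <- B$z + cfg$axial_offset
  native <- structure_model(rbind(A, B), "synthetic_dimer_native")
  pert <- native
  pert$model_id <- "synthetic_dimer_perturbed"
  n <- nrow(pert$atoms)
  if (cfg$perturbation_sd > 0) {
    pert$atoms$x <- pert$atoms$x + rnorm(n, 0, cfg$perturbation_sd)
    pert$atoms$y <- pert$atoms$y + rnorm(n, 0, cfg$perturbation_sd)
    pert$atoms$z <- pert$atoms$z + rnorm(n, 0, cfg$perturbation_sd)
  }
  if (cfg$rigid_offset != 0) {
    bb <- pert$atoms$chain == "B"
    pert$atoms$x[bb] <- pert$atoms$x[bb] + cfg$rigid_offset
  }
  list(native = native, perturbed = pert)
}

# ---- confidence surrogates -------------------------------------------------

.quality_params <- list(
  high   = list(plddt = c(90, 3),  pae_inter = c(3, 1),  pae_intra = c(2, 0.5),
                iptm = c(0.60, 0.95)),
  medium = list(plddt = c(70, 5),  pae_inter = c(12, 3), pae_intra = c(5, 2),
                iptm = c(0.40, 0.60)),
  low    = list(plddt = c(50, 10), pae_inter = c(25, 4), pae_intra = c(10, 3),
                iptm = c(0.05, 0.40)))

#' Generate a synthetic confidence bundle for a model
#'
#' Stamps per-residue pLDDT into the B-factor column and fabricates a PAE
#' matrix and five per-model ipTM values whose distributions depend on the
#' requested quality tier (high: pLDDT ~ N(90, 3), interchain PAE ~ N(3, 1)
#' clipped at 0.2; low: pLDDT ~ N(50, 10), interchain PAE ~ N(25, 4)).
#' These are statistical surrogates; only their orderings are contractual.
#'
#' @param model A `structure_model`.
#' @param quality `"high"`, `"medium"` or `"low"`.
#' @param seed Integer seed.
#' @param symmetric_pae Symmetrize the PAE matrix (default TRUE).
#' @return List `model` (pLDDT-stamped), `bundle` (a `confidence_bundle`
#'   whose PAE belongs to the top-ranked model), `best_model`.
#' @export
synth_confidence <- function(model, quality = c("high", "medium", "low"),
                             seed = 1L, symmetric_pae = TRUE) {
  quality <- match.arg(quality)
  qp <- .quality_params[[quality]]
  set.seed(seed)
  rt <- residue_table(model)
  nres <- nrow(rt)
  plddt <- pmin(pmax(rnorm(nres, qp$plddt[1], qp$plddt[2]), 0), 100)
  key <- paste(model$atoms$chain, model$atoms$resno)
  model$atoms$b <- plddt[match(key, paste(rt$chain, rt$resno))]
  inter <- outer(rt$chain, rt$chain, "!=")
  pae <- matrix(0, nres, nres)
  pae[inter] <- rnorm(sum(inter), qp$pae_inter[1], qp$pae_inter[2])
  pae[!inter] <- rnorm(sum(!inter), qp$pae_intra[1], qp$pae_intra[2])
  diag(pae) <- 0.2
  pae <- pmin(pmax(pae, 0.2), 31.75)
  diag(pae) <- 0.2
  if (symmetric_pae) pae <- (pae + t(pae)) / 2
  iptm <- sort(runif(5, qp$iptm[1], qp$iptm[2]), decreasing = TRUE)
  names(iptm) <- sprintf("model_%d", 1:5)
  bundle <- confidence_bundle(iptm, pae = pae, n_residues = nres)
  list(model = model, bundle = bundle, best_model = select_best_model(bundle))
}

#' Write a confidence bundle as predictor-dialect JSON files
#'
#' Emits `ranking_debug.json` (with both an `iptm` and an `iptm+ptm` map and
#' the descending `order`) and `pae.json` (with the
#' `predicted_aligned_error` key).
#'
#' @param bundle A `confidence_bundle`.
#' @param dir Output directory.
#' @return Named list of the two paths.
#' @export
write_confidence <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rank_path <- file.path(dir, "ranking_debug.json")
  iptm <- as.list(bundle$iptm_by_model)
  jsonlite::write_json(list(iptm = iptm, `iptm+ptm` = iptm,
                            order = bundle$ranking),
                       rank_path, auto_unbox = TRUE, digits = NA)
  pae_path <- NULL
  if (!is.null(bundle$pae)) {
    pae_path <- file.path(dir, "pae.json")
    jsonlite::write_json(list(predicted_aligned_error = bundle$pae),
                         pae_path, digits = NA, matrix = "rowmajor")
  }
  list(ranking = rank_path, pae = pae_path)
}

#' Generate a synthetic conservation track
#'
#' Baseline per-residue scores are uniform on 1..9; residues of the model's
#' interface (10 A criterion) are shifted by `+shift` and clipped back to
#' the 1..9 scale.
#'
#' @param model Two-chain `structure_model`.
#' @param shift Shift added to interface residues (default from the
#'   config's `conservation_shift`).
#' @param seed Integer seed.
#' @param config [interface_config()] used to define the interface.
#' @return Data frame `chain`, `resno`, `score` plus attribute
#'   `interface` (logical vector).
#' @export
synth_conservation <- function(model, shift = 2, seed = 1L,
                               config = interface_config()) {
  set.seed(seed)
  rt <- residue_table(model)
  score <- sample(1:9, nrow(rt), replace = TRUE)
  iface <- find_interface_residues(model, config)
  is_if <- paste(rt$chain, rt$resno) %in% paste(iface$chain, iface$resno)
  score[is_if] <- pmin(pmax(round(score[is_if] + shift), 1L), 9L)
  out <- data.frame(chain = rt$chain, resno = rt$resno, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "interface") <- is_if
  out
}
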