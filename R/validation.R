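#' @title Model-versus-native validation metrics
#' @name validation_metrics
#' @description
#' Rigid superposition (Kabsch), interface RMSD, fraction of native contacts
#' (Fnat), ligand RMSD, the composite DockQ score, TM-score over the
#' concatenated complex, crosslink distance-restraint checking, and the
#' metadata filter used to assemble a non-redundant reference benchmark.
#' Residue correspondence between model and native is established by chain
#' mapping plus author sequence index; no alignment search is performed.
NULL

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid-body fit of point set `P` onto `Q` via singular value
#' decomposition, with reflection correction so the returned rotation is
#' proper (det = +1).
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3.
#' @return List `rotation` (3 x 3, applied as `P %*% rotation`),
#'   `translation` (length 3), `rmsd`. The fitted coordinates are
#'   `P %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || nrow(P) < 3 || ncol(P) != 3 || ncol(Q) != 3)
    stop("P and Q must be n x 3 matrices with equal n >= 3")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  C <- t(Pc) %*% Qc
  s <- svd(C)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate (collinear) point set: superposition not unique")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - cp %*% R), rmsd = rmsd)
}

# residue correspondence: shared (chain, resno) pairs after chain mapping
# chain_map: named character vector model chain -> native chain (default:
# positional pairing in file order)
.map_chains <- function(model, native, chain_map = NULL) {
  mc <- chain_ids(model); nc <- chain_ids(native)
  if (is.null(chain_map)) {
    if (length(mc) != length(nc))
      stop("chain counts differ; supply an explicit chain_map")
    chain_map <- setNames(nc, mc)
  }
  chain_map
}

# matched coordinate matrices for a set of atom names over given native
# residues (data.frame chain, resno in native labelling)
.matched_coords <- function(model, native, chain_map, residues = NULL,
                            atom_names = .backbone_atoms) {
  ma <- model$atoms; na <- native$atoms
  ma$native_chain <- unname(chain_map[ma$chain])
  keym <- paste(ma$native_chain, ma$resno, ma$elety)
  keyn <- paste(na$chain, na$resno, na$elety)
  if (!is.null(atom_names)) {
    selm <- ma$elety %in% atom_names
    seln <- na$elety %in% atom_names
  } else {
    selm <- rep(TRUE, nrow(ma)); seln <- rep(TRUE, nrow(na))
  }
  if (!is.null(residues)) {
    rk <- paste(residues$chain, residues$resno)
    selm <- selm & paste(ma$native_chain, ma$resno) %in% rk
    seln <- seln & paste(na$chain, na$resno) %in% rk
  }
  common <- intersect(keym[selm], keyn[seln])
  if (length(common) == 0) stop("no matched atoms between model and native")
  im <- match(common, keym); inn <- match(common, keyn)
  list(P = .xyz(ma)[im, , drop = FALSE], Q = .xyz(na)[inn, , drop = FALSE],
       keys = common)
}

# native interface residues in native labelling (any heavy atom within
# cutoff of the other chain)
.native_interface <- function(native, cutoff) {
  cfg <- interface_config(contact_cutoff = min(4.5, cutoff),
                          interface_cutoff = cutoff)
  find_interface_residues(native, cfg)
}

#' Interface RMSD against a native structure
#'
#' Backbone RMSD over the native-defined interface residues (any heavy atom
#' within `cutoff` of the other chain) after least-squares superposition on
#' those same residues.
#'
#' @param model,native Two-chain `structure_model`s.
#' @param cutoff Interface definition cutoff, Angstrom (default 10).
#' @param chain_map Optional named vector, model chain -> native chain.
#' @param atoms `"backbone"` (N, CA, C, O; default) or `"heavy"`.
#' @return i-RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, native, cutoff = 10, chain_map = NULL,
                           atoms = c("backbone", "heavy")) {
  atoms <- match.arg(atoms)
  chain_map <- .map_chains(model, native, chain_map)
  iface <- .native_interface(native, cutoff)
  if (nrow(iface) == 0) stop("native structure has no interface residues")
  mc <- .matched_coords(model, native, chain_map, residues = iface,
                        atom_names = if (atoms == "backbone")
                          .backbone_atoms else NULL)
  kabsch_superpose(mc$P, mc$Q)$rmsd
}

# native-contact keys (residue pairs across chains, heavy atoms <= cutoff)
.contact_keys <- function(model, cutoff) {
  cc <- find_contact_residues(model, interface_config(contact_cutoff = cutoff,
                                                      interface_cutoff = max(10, cutoff)))
  # canonicalize so the key is independent of chain file order
  ifelse(cc$chain_a <= cc$chain_b,
         paste(cc$chain_a, cc$resno_a, cc$chain_b, cc$resno_b),
         paste(cc$chain_b, cc$resno_b, cc$chain_a, cc$resno_a))
}

#' Fraction of native contacts preserved in the model
#'
#' Native interchain residue contacts are heavy-atom pairs within
#' `contact_cutoff`; Fnat is the fraction of those residue pairs still in
#' contact (same criterion) in the model, after mapping model chains onto
#' native chains.
#'
#' @param model,native Two-chain `structure_model`s.
#' @param contact_cutoff Angstrom (default 5, the CAPRI convention).
#' @param chain_map Optional named vector, model chain -> native chain.
#' @return Fnat in \[0, 1\].
#' @export
fnat <- function(model, native, contact_cutoff = 5, chain_map = NULL) {
  chain_map <- .map_chains(model, native, chain_map)
  nat <- .contact_keys(native, contact_cutoff)
  if (length(nat) == 0) stop("native structure has no interchain contacts")
  m2 <- model
  m2$atoms$chain <- unname(chain_map[m2$atoms$chain])
  mod <- .contact_keys(m2, contact_cutoff)
  mean(nat %in% mod)
}

#' Ligand RMSD after receptor superposition
#'
#' The receptor is the native chain with more residues (ties: first chain in
#' file order). Model and native are superposed on the receptor backbone;
#' the RMSD is over the ligand backbone.
#'
#' @inheritParams fnat
#' @return L-RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, native, chain_map = NULL) {
  chain_map <- .map_chains(model, native, chain_map)
  nc <- chain_ids(native)
  nres <- vapply(nc, function(c)
    length(unique(native$atoms$resno[native$atoms$chain == c])), integer(1))
  receptor <- nc[which.max(nres)]
  ligand <- setdiff(nc, receptor)
  rec <- .matched_coords(model, native, chain_map,
                         residues = data.frame(
                           chain = receptor,
                           resno = unique(native$atoms$resno[
                             native$atoms$chain == receptor])))
  fit <- kabsch_superpose(rec$P, rec$Q)
  lig <- .matched_coords(model, native, chain_map,
                         residues = data.frame(
                           chain = ligand,
                           resno = unique(native$atoms$resno[
                             native$atoms$chain == ligand])))
  moved <- sweep(lig$P %*% fit$rotation, 2, fit$translation, "+")
  sqrt(mean(rowSums((moved - lig$Q)^2)))
}

#' DockQ score of a model against its native structure
#'
#' DockQ = (Fnat + 1/(1+(iRMS/d1)^2) + 1/(1+(LRMS/d2)^2)) / 3 with the
#' published scaling constants (d1 = 1.5 A for the interface RMSD term,
#' d2 = 8.5 A for the ligand RMSD term) held in [score_constants()].
#'
#' @inheritParams fnat
#' @param constants Constant set (default [score_constants()]`$dockq`).
#' @return List `dockq`, `fnat`, `irms`, `lrms`.
#' @export
dockq <- function(model, native, chain_map = NULL,
                  constants = score_constants()$dockq) {
  fn <- fnat(model, native, constants$fnat_cutoff, chain_map)
  ir <- interface_rmsd(model, native, constants$interface_cutoff, chain_map)
  lr <- ligand_rmsd(model, native, chain_map)
  q <- (fn + 1 / (1 + (ir / constants$d1)^2) +
          1 / (1 + (lr / constants$d2)^2)) / 3
  list(dockq = q, fnat = fn, irms = ir, lrms = lr)
}

#' TM-score of a model against its native structure
#'
#' Length-normalized structural similarity over the concatenated chains,
#' scored on C-alpha atoms with fixed sequence correspondence:
#' TM = max over superpositions of (1/L_native) * sum 1/(1 + (d_i/d0)^2),
#' d0 = 1.24 (L-15)^(1/3) - 1.8 floored at 0.5. The maximization follows
#' the standard iterative scheme: superpositions seeded from contiguous
#' fragments (full length, halves, quarters), each refined by repeatedly
#' superposing on the residues currently within a distance shell and
#' keeping the best score seen.
#'
#' @inheritParams fnat
#' @param constants Constant set (default [score_constants()]`$tm_score`).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, native, chain_map = NULL,
                     constants = score_constants()$tm_score) {
  chain_map <- .map_chains(model, native, chain_map)
  mc <- .matched_coords(model, native, chain_map, atom_names = "CA")
  L_native <- length(unique(paste(native$atoms$chain,
                                  native$atoms$resno)))
  if (L_native < 3) stop("native has fewer than 3 residues")
  d0 <- max(constants$d0_coef * sign(L_native - constants$d0_sub) *
              abs(L_native - constants$d0_sub)^(1/3) - constants$d0_shift,
            constants$d0_min)
  P <- mc$P; Q <- mc$Q; n <- nrow(P)
  score_of <- function(fit) {
    moved <- sweep(P %*% fit$rotation, 2, fit$translation, "+")
    d <- sqrt(rowSums((moved - Q)^2))
    list(tm = sum(1 / (1 + (d / d0)^2)) / L_native, d = d)
  }
  best <- 0
  frag_lens <- unique(pmax(4, c(n, n %/% 2, n %/% 4)))
  for (fl in frag_lens) {
    starts <- unique(pmax(1, seq(1, n - fl + 1, by = max(fl %/% 2, 1))))
    for (s0 in starts) {
      idx <- s0:(s0 + fl - 1)
      fit <- tryCatch(kabsch_superpose(P[idx, , drop = FALSE],
                                       Q[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      for (iter in 1:20) {
        sc <- score_of(fit)
        best <- max(best, sc$tm)
        shell <- which(sc$d < max(d0, 4.5))
        if (length(shell) < 3) break
        fit2 <- tryCatch(kabsch_superpose(P[shell, , drop = FALSE],
                                          Q[shell, , drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(fit2)) break
        sc2 <- score_of(fit2)
        if (sc2$tm <= sc$tm + 1e-12) { best <- max(best, sc2$tm); break }
        fit <- fit2
      }
    }
  }
  min(best, 1)
}

#' Check crosslink distance restraints on a model
#'
#' A restraint is satisfied when the C-alpha--C-alpha distance between the
#' two crosslinked lysines is at most its `max_distance` (default 20 A,
#' reflecting typical lysine-reactive crosslinker spacers). Restraints whose
#' residues are missing from the model, or are not lysines, are skipped and
#' reported.
#'
#' @param model A `structure_model`.
#' @param restraints Data frame `chain_a`, `resno_a`, `chain_b`, `resno_b`,
#'   optional `max_distance`.
#' @param max_distance Default maximum distance (Angstrom) for restraints
#'   without their own.
#' @return List `satisfied`, `total`, `fraction` (NA when total is 0),
#'   `skipped`.
#' @export
crosslink_check <- function(model, restraints, max_distance = 20) {
  if (is.null(restraints) || nrow(restraints) == 0)
    return(list(satisfied = 0L, total = 0L, fraction = NA_real_,
                skipped = 0L))
  if (is.null(restraints$max_distance))
    restraints$max_distance <- max_distance
  a <- model$atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$resno)
  sat <- 0L; tot <- 0L; skip <- 0L
  for (i in seq_len(nrow(restraints))) {
    ia <- match(paste(restraints$chain_a[i], restraints$resno_a[i]), key)
    ib <- match(paste(restraints$chain_b[i], restraints$resno_b[i]), key)
    if (is.na(ia) || is.na(ib) ||
        ca$resid[ia] != "LYS" || ca$resid[ib] != "LYS") {
      skip <- skip + 1L
      next
    }
    d <- sqrt(sum((.xyz(ca[ia, ]) - .xyz(ca[ib, ]))^2))
    tot <- tot + 1L
    if (d <= restraints$max_distance[i]) sat <- sat + 1L
  }
  if (skip > 0) warning(skip, " restraint(s) skipped (missing or non-lysine)")
  list(satisfied = sat, total = tot,
       fraction = if (tot > 0) sat / tot else NA_real_, skipped = skip)
}

#' Filter benchmark metadata to the reference set
#'
#' Keeps heterodimer entries released after the training cutoff, solved by
#' X-ray crystallography or cryo-EM at resolution <= `resolution_max`,
#' marked as their structural cluster's representative, and with maximum
#' sequence identity to the predictor's training set strictly below
#' `identity_max`. Order-invariant and idempotent.
#'
#' @param entries Data frame with columns `pdb_id`, `release_date`,
#'   `method` (`xray` / `cryoem` / `other`), `resolution`,
#'   `n_distinct_chains`, `cluster_representative`,
#'   `max_identity_to_training`.
#' @param date_cutoff Release-date cutoff (default `"2021-09-30"`).
#' @param resolution_max Maximum resolution in Angstrom (default 2.0).
#' @param identity_max Strict upper bound on training-set identity
#'   (default 0.30).
#' @return Filtered data frame.
#' @export
benchmark_filter <- function(entries, date_cutoff = "2021-09-30",
                             resolution_max = 2.0, identity_max = 0.30) {
  stopifnot(all(c("pdb_id", "release_date", "method", "resolution",
                  "n_distinct_chains", "cluster_representative",
                  "max_identity_to_training") %in% names(entries)))
  keep <- as.Date(entries$release_date) > as.Date(date_cutoff) &
    entries$method %in% c("xray", "cryoem") &
    entries$resolution <= resolution_max &
    entries$n_distinct_chains == 2 &
    entries$cluster_representative &
    entries$max_identity_to_training < identity_max
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full validation report for a model against a native structure
#'
#' @inheritParams fnat
#' @param restraints Optional crosslink restraint table (see
#'   [crosslink_check()]).
#' @return List of class `validation_report` with `tm_score`, `i_rmsd`,
#'   `l_rmsd`, `fnat`, `dockq`, `crosslink_satisfied`, `crosslink_total`.
#' @export
validation_report <- function(model, native, chain_map = NULL,
                              restraints = NULL) {
  dq <- dockq(model, native, chain_map)
  xl <- crosslink_check(model, restraints %||% data.frame())
  structure(list(tm_score = tm_score(model, native, chain_map),
                 i_rmsd = dq$irms, l_rmsd = dq$lrms, fnat = dq$fnat,
                 dockq = dq$dockq,
                 crosslink_satisfied = xl$satisfied,
                 crosslink_total = xl$total),
            class = "validation_report")
}
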