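#' @title Structure and confidence-artifact input/output
#' @name structure_io
#' @description
#' Readers and writers for predicted and reference structures (PDB / mmCIF)
#' and for the confidence artifacts emitted by multimer structure predictors
#' (ranking-score JSON with per-model ipTM, PAE JSON). A structure is held as
#' a `structure_model`: a flat atom table plus a model id. In predicted
#' models the B-factor column carries per-residue pLDDT (0-100).
NULL

#' Construct a structure model
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid` (3-letter),
#'   `elety` (atom name), `element`, `x`, `y`, `z`, `b`.
#' @param model_id Identifier string.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model") {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z", "b")
  stopifnot(all(need %in% names(atoms)))
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms) == 0 || length(unique(atoms$chain)) < 1)
    stop("structure has zero chains")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    r <- r[!duplicated(r)]
    if (any(diff(r) <= 0))
      stop(sprintf("residue numbering not strictly increasing in chain %s", ch))
  }
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nres <- vapply(ch, function(c)
    length(unique(x$atoms$resno[x$atoms$chain == c])), integer(1))
  cat(sprintf("structure_model '%s': %d chain(s) [%s], %d atoms\n",
              x$model_id, length(ch),
              paste(sprintf("%s:%d", ch, nres), collapse = ", "),
              nrow(x$atoms)))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model A `structure_model`.
#' @return Character vector of chain ids in file order.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Per-residue table of a model
#'
#' One row per residue in chain-concatenation (file) order, with the
#' pLDDT/B-factor taken from the C-alpha atom (first atom when no C-alpha
#' exists). This order is the indexing convention for PAE matrices.
#'
#' @param model A `structure_model`.
#' @return Data frame with `chain`, `resno`, `resid`, `plddt`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  plddt <- a$b[first]
  ca_rows <- which(a$elety == "CA")
  m <- match(paste(out$chain, out$resno), key[ca_rows])
  plddt[!is.na(m)] <- a$b[ca_rows[m[!is.na(m)]]]
  out$plddt <- plddt
  out
}

.guess_element <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", elety))
  two <- substr(e, 1, 2)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(e) > 1 & !grepl("^C[ABGDEZ]", e) & !grepl("^N[ABGDEZH]", e) &
           !grepl("^O[ABGDEZXH]", e) & !grepl("^S[GD]", e),
         two, substr(e, 1, 1))
}

.water_resids <- c("HOH", "WAT", "DOD", "H2O")

.postprocess_atoms <- function(atoms) {
  atoms <- atoms[!(atoms$resid %in% .water_resids), , drop = FALSE]
  if (nrow(atoms) == 0) stop("structure has zero chains after removing waters")
  # altloc: keep the highest-occupancy copy of each atom
  if (!is.null(atoms$alt) && any(!is.na(atoms$alt) & atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    occ <- if (is.null(atoms$o)) rep(1, nrow(atoms)) else
      ifelse(is.na(atoms$o), 1, atoms$o)
    atoms <- atoms[order(key, -occ), , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$elety)), ,
                   drop = FALSE]
    atoms <- atoms[order(match(paste(atoms$chain, atoms$resno),
                               unique(paste(atoms$chain, atoms$resno)))), ,
                   drop = FALSE]
  }
  # insertion codes: renumber sequentially per chain, with a message
  if (!is.null(atoms$insert) && any(!is.na(atoms$insert) & atoms$insert != "")) {
    message("insertion codes present; residues renumbered sequentially per chain")
    for (ch in unique(atoms$chain)) {
      i <- atoms$chain == ch
      rk <- paste(atoms$resno[i], ifelse(is.na(atoms$insert[i]), "",
                                         atoms$insert[i]))
      atoms$resno[i] <- as.integer(factor(rk, levels = unique(rk)))
    }
  }
  atoms
}

#' Read a structure from PDB or mmCIF
#'
#' Waters are dropped; alternate locations are collapsed to the
#' highest-occupancy copy; only the first model of multi-model (NMR-style)
#' files is kept, with a message. Author residue numbering is preserved
#' except when insertion codes are present, in which case residues are
#' renumbered sequentially per chain (logged).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("unparseable structure file: ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- .guess_element(a$elety)
  elem[is.na(elem) | elem == ""] <- .guess_element(a$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(chain = as.character(a$chain), resno = as.integer(a$resno),
                      resid = as.character(a$resid), elety = as.character(a$elety),
                      element = toupper(elem),
                      x = a$x, y = a$y, z = a$z,
                      b = ifelse(is.na(a$b), 0, a$b),
                      alt = if (is.null(a$alt)) NA_character_ else a$alt,
                      o = if (is.null(a$o)) 1 else a$o,
                      insert = if (is.null(a$insert)) NA_character_ else a$insert,
                      stringsAsFactors = FALSE)
  atoms <- .postprocess_atoms(atoms)
  atoms <- atoms[, c("chain", "resno", "resid", "elety", "element",
                     "x", "y", "z", "b")]
  structure_model(atoms, model_id = sub("\\.[^.]+$", "", basename(path)))
}

#' Write a structure to PDB or mmCIF
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                    paste0(" ", formatC(a$elety, width = -3)))
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1.00, a$b, a$element)
    writeLines(c(lines, "END"), path)
  } else {
    # standard PDBx/mmCIF atom_site field order (RCSB layout)
    hdr <- c(paste0("data_", model$model_id), "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
             "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
             "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1.00, a$b, a$resno, a$resid, a$chain, a$elety)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

# ---- confidence artifacts --------------------------------------------------

#' Construct a confidence bundle
#'
#' Holds per-model ipTM scores, a ranking (descending ipTM, ties broken by
#' lexicographically smallest model id) and an optional PAE matrix for the
#' top-ranked model.
#'
#' @param iptm_by_model Named numeric vector, model id -> ipTM in \[0, 1\].
#' @param pae Optional square PAE matrix (Angstrom), indexed over the
#'   concatenated residues of all chains.
#' @param n_residues Optional residue count to validate `pae` against.
#' @return Object of class `confidence_bundle`.
#' @export
confidence_bundle <- function(iptm_by_model, pae = NULL, n_residues = NULL) {
  if (length(iptm_by_model) == 0) stop("empty confidence bundle")
  stopifnot(!is.null(names(iptm_by_model)),
            all(iptm_by_model >= 0 & iptm_by_model <= 1))
  ord <- order(-iptm_by_model, names(iptm_by_model))
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae)) stop("PAE matrix must be square")
    if (any(pae < 0)) stop("PAE entries must be non-negative")
    if (!is.null(n_residues) && nrow(pae) != n_residues)
      stop("PAE dimension does not match residue count")
  }
  structure(list(iptm_by_model = iptm_by_model,
                 ranking = names(iptm_by_model)[ord], pae = pae),
            class = "confidence_bundle")
}

#' Select the representative model of a prediction job
#'
#' Returns the model with the highest ipTM; ties go to the lexicographically
#' smallest model id.
#'
#' @param bundle A `confidence_bundle`.
#' @return Model id string.
#' @export
select_best_model <- function(bundle) {
  if (length(bundle$iptm_by_model) == 0) stop("empty confidence bundle")
  bundle$ranking[1]
}

#' Read a ranking-score JSON
#'
#' Accepts the multimer predictor dialect: an object with an `"iptm"` and/or
#' `"iptm+ptm"` map of model id to score. By default the raw ipTM is used;
#' set `use = "ranking_confidence"` to read the weighted
#' 0.8*ipTM + 0.2*pTM ranking score instead.
#'
#' @param path JSON path.
#' @param use `"iptm"` (default) or `"ranking_confidence"`.
#' @return A `confidence_bundle` (without PAE).
#' @export
read_ranking <- function(path, use = c("iptm", "ranking_confidence")) {
  use <- match.arg(use)
  j <- jsonlite::fromJSON(path)
  key <- if (use == "iptm" && !is.null(j$iptm)) "iptm" else "iptm+ptm"
  if (is.null(j[[key]])) stop("ranking JSON lacks an ipTM score map")
  confidence_bundle(unlist(j[[key]]))
}

#' Read a PAE JSON
#'
#' Accepts both the `"pae"` and the `"predicted_aligned_error"` key dialects,
#' optionally wrapped in a one-element array.
#'
#' @param path JSON path.
#' @return Square numeric matrix of non-negative aligned errors (Angstrom).
#' @export
read_pae <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (is.data.frame(j)) j <- as.list(j)
  if (is.list(j) && is.null(j$pae) && is.null(j$predicted_aligned_error) &&
      length(j) == 1 && is.list(j[[1]]))
    j <- j[[1]]
  m <- if (!is.null(j$pae)) j$pae else j$predicted_aligned_error
  if (is.null(m)) stop("PAE JSON lacks a 'pae' or 'predicted_aligned_error' key")
  if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, m)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("PAE matrix must be square")
  if (any(m < 0)) stop("PAE entries must be non-negative")
  unname(m)
}
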