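#' @title Structure-aware confidence scores for predicted binary complexes
#' @name confidence_scores
#' @description
#' pDockQ and pDockQ2 estimators for two-chain predicted models, ipTM triage
#' into unlikely / plausible / high-confidence categories, and score-column
#' correlation. Sigmoid constants come from the versioned table returned by
#' [score_constants()], transcribed from the scores' primary publications.
NULL

#' Interchain residue contacts from C-beta positions
#'
#' Contact convention of the pDockQ family: residue pairs across the two
#' chains whose C-beta atoms (C-alpha for glycine) lie within `cutoff`
#' Angstrom (inclusive).
#'
#' @param model Two-chain `structure_model`.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return Data frame with `chain_a`, `resno_a`, `chain_b`, `resno_b`,
#'   `dist`.
#' @export
interface_contacts_cb <- function(model, cutoff = 8) {
  ab <- .two_chains(model)
  ta <- .cb_table(ab$a); tb <- .cb_table(ab$b)
  if (nrow(ta) == 0 || nrow(tb) == 0)
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      dist = numeric(0)))
  d <- .crossdist(.xyz(ta), .xyz(tb))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  data.frame(chain_a = ta$chain[hit[, 1]], resno_a = ta$resno[hit[, 1]],
             chain_b = tb$chain[hit[, 2]], resno_b = tb$resno[hit[, 2]],
             dist = d[hit], stringsAsFactors = FALSE)
}

.check_plddt <- function(model) {
  b <- model$atoms$b
  if (all(is.na(b)) || all(b == 0))
    stop("model carries no pLDDT values in its B-factor column")
}

#' Compute pDockQ for a two-chain model
#'
#' pDockQ = L / (1 + exp(-k (x - x0))) + b with
#' x = (mean pLDDT over interface residues) * ln(number of interface
#' contacts). Interface residues are those participating in at least one
#' interchain C-beta contact at the configured cutoff. A model with no
#' interface contacts scores 0.
#'
#' @param model Two-chain `structure_model` with pLDDT in B-factors.
#' @param constants Constant set (default [score_constants()]`$pdockq`).
#' @return pDockQ in \[0, 1\].
#' @export
compute_pdockq <- function(model, constants = score_constants()$pdockq) {
  .check_plddt(model)
  contacts <- interface_contacts_cb(model, constants$cb_cutoff)
  if (nrow(contacts) == 0) return(0)
  rt <- residue_table(model)
  iface <- unique(rbind(
    data.frame(chain = contacts$chain_a, resno = contacts$resno_a),
    data.frame(chain = contacts$chain_b, resno = contacts$resno_b)))
  plddt <- rt$plddt[match(paste(iface$chain, iface$resno),
                          paste(rt$chain, rt$resno))]
  if (anyNA(plddt)) stop("interface residue without pLDDT")
  x <- mean(plddt) * log(nrow(contacts))
  constants$L / (1 + exp(-constants$k * (x - constants$x0))) + constants$b
}

#' Compute pDockQ2 for a two-chain model
#'
#' Per chain i, X_i = (mean pLDDT over the chain's interface residues) *
#' (mean over interchain contact pairs of 1 / (1 + (PAE_ij / d0)^2)); the
#' chain score is the published sigmoid of X_i and the complex score is the
#' mean over the two chains. PAE is indexed over the concatenated residues
#' in file order. A model with no interface contacts scores 0.
#'
#' @param model Two-chain `structure_model` with pLDDT in B-factors.
#' @param pae Square PAE matrix matching the model's residue count.
#' @param constants Constant set (default [score_constants()]`$pdockq2`).
#' @return pDockQ2 in \[0, 1\].
#' @export
compute_pdockq2 <- function(model, pae,
                            constants = score_constants()$pdockq2) {
  .check_plddt(model)
  rt <- residue_table(model)
  pae <- as.matrix(pae)
  if (nrow(pae) != nrow(rt) || ncol(pae) != nrow(rt))
    stop("PAE dimension does not match model residue count")
  contacts <- interface_contacts_cb(model, constants$cb_cutoff)
  if (nrow(contacts) == 0) return(0)
  reskey <- paste(rt$chain, rt$resno)
  ia <- match(paste(contacts$chain_a, contacts$resno_a), reskey)
  ib <- match(paste(contacts$chain_b, contacts$resno_b), reskey)
  chains <- unique(rt$chain)
  per_chain <- vapply(chains, function(ch) {
    if (ch == chains[1]) { own <- ia; pae_vals <- pae[cbind(ia, ib)] }
    else { own <- ib; pae_vals <- pae[cbind(ib, ia)] }
    plddt <- rt$plddt[unique(own)]
    ptm_term <- mean(1 / (1 + (pae_vals / constants$d0)^2))
    x <- mean(plddt) * ptm_term
    constants$L / (1 + exp(-constants$k * (x - constants$x0))) + constants$b
  }, numeric(1))
  min(max(mean(per_chain), 0), 1)
}

#' Classification thresholds for ipTM triage
#' @param low,high Boundaries of the plausible band (defaults 0.4 and 0.6).
#' @return List of class `classification_thresholds`.
#' @export
classification_thresholds <- function(low = 0.4, high = 0.6) {
  stopifnot(low > 0, high < 1, low < high)
  structure(list(low = low, high = high), class = "classification_thresholds")
}

#' Classify models by ipTM
#'
#' Scores strictly below `low` are `unlikely`; scores strictly above `high`
#' are `high_confidence`; both boundaries belong to `plausible`.
#'
#' @param score Numeric vector of ipTM scores in \[0, 1\].
#' @param th A [classification_thresholds()].
#' @return Character vector of categories.
#' @export
classify_iptm <- function(score, th = classification_thresholds()) {
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("ipTM scores must lie in [0, 1]")
  ifelse(score < th$low, "unlikely",
         ifelse(score > th$high, "high_confidence", "plausible"))
}

#' Pearson correlation between two score columns
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-constant).
#' @return Pearson product-moment coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need two equal-length vectors of at least 3 values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant column: correlation undefined")
  cor(x, y, method = "pearson")
}

#' Score a set of predicted complexes
#'
#' Convenience wrapper producing one row per model: ipTM (from its
#' confidence bundle), pDockQ, pDockQ2 (when PAE is present) and the ipTM
#' category.
#'
#' @param models Named list of two-chain `structure_model`s (pLDDT in
#'   B-factors).
#' @param bundles Named list of `confidence_bundle`s parallel to `models`.
#' @param th [classification_thresholds()].
#' @return Data frame with `edge_id`, `model_id`, `iptm`, `pdockq`,
#'   `pdockq2`, `category`.
#' @export
score_models <- function(models, bundles, th = classification_thresholds()) {
  stopifnot(length(models) == length(bundles))
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]; bdl <- bundles[[i]]
    best <- select_best_model(bdl)
    iptm <- unname(bdl$iptm_by_model[best])
    pd2 <- if (!is.null(bdl$pae)) compute_pdockq2(m, bdl$pae) else NA_real_
    data.frame(edge_id = names(models)[i] %||% m$model_id,
               model_id = best, iptm = iptm,
               pdockq = compute_pdockq(m), pdockq2 = pd2,
               category = classify_iptm(iptm, th),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
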