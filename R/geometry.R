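# Internal geometry helpers shared by the interface, confidence and
# validation modules.

.backbone_atoms <- c("N", "CA", "C", "O")

# coordinate matrix (n x 3) for a subset of atoms
.xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

.heavy <- function(atoms) atoms[atoms$element != "H", , drop = FALSE]

# all pairwise Euclidean distances between rows of A and rows of B
.crossdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# split a two-chain model into its two atom tables (error otherwise)
.two_chains <- function(model) {
  ch <- chain_ids(model)
  if (length(ch) != 2) stop("operation requires a model with exactly 2 chains")
  list(a = model$atoms[model$atoms$chain == ch[1], , drop = FALSE],
       b = model$atoms[model$atoms$chain == ch[2], , drop = FALSE],
       ids = ch)
}

# Apply a rigid-body transform (rotation matrix R, translation t) to a model.
.transform_model <- function(model, R, t = c(0, 0, 0)) {
  xyz <- .xyz(model$atoms) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# random proper rotation matrix (for property tests and fixtures)
.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# representative C-beta coordinates per residue (C-alpha for glycine or when
# C-beta is absent); residues with neither atom are dropped with a message
.cb_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  res_keys <- unique(key)
  cb <- atoms[atoms$elety == "CB", , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  use_cb <- match(res_keys, paste(cb$chain, cb$resno))
  use_ca <- match(res_keys, paste(ca$chain, ca$resno))
  pick <- ifelse(!is.na(use_cb), "cb", ifelse(!is.na(use_ca), "ca", NA))
  if (any(is.na(pick)))
    message(sum(is.na(pick)), " residue(s) without CB/CA skipped")
  keep <- !is.na(pick)
  rows <- ifelse(pick[keep] == "cb",
                 which(atoms$elety == "CB")[use_cb[keep]],
                 which(atoms$elety == "CA")[use_ca[keep]])
  out <- atoms[rows, c("chain", "resno", "resid", "x", "y", "z", "b")]
  rownames(out) <- NULL
  out
}
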