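# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (double loops, eigen-decompositions,
# Monte-Carlo) and share no code with the implementation paths they check.

# a minimal atom row
atom_row <- function(chain, resno, elety, element, x, y, z,
                     resid = "ALA", b = 0) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             element = element, x = x, y = y, z = z, b = b,
             stringsAsFactors = FALSE)
}

# two single-residue chains with one atom each, a given distance apart
two_res_model <- function(d, elety = "CB", element = "C", b = 100) {
  structure_model(rbind(
    atom_row("A", 1, elety, element, 0, 0, 0, b = b),
    atom_row("B", 1, elety, element, d, 0, 0, b = b)), "two_res")
}

# "ladder": n residue pairs, partners dx apart in x, rungs dz apart in z,
# so each A residue contacts exactly its own B partner
ladder_model <- function(n, dx = 4, dz = 10, b = 90) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
    atom_row("A", i, "CA", "C", 0, 0, i * dz, b = b),
    atom_row("B", i, "CA", "C", dx, 0, i * dz, b = b))))
  rows <- rows[order(rows$chain, rows$resno), ]
  structure_model(rows, "ladder")
}

# rigid-body transform applied directly to the atom table
apply_rigid <- function(model, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# O(n^2) brute-force interchain residue contact pairs over heavy atoms
bf_contact_pairs <- function(model, cutoff) {
  a <- model$atoms[model$atoms$element != "H", ]
  ch <- unique(a$chain)
  A <- a[a$chain == ch[1], ]; B <- a[a$chain == ch[2], ]
  hits <- character(0)
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    if (d <= cutoff)
      hits <- c(hits, paste(A$chain[i], A$resno[i], B$chain[j], B$resno[j]))
  }
  sort(unique(hits))
}

# Monte-Carlo per-atom SASA oracle: random directions on each inflated
# sphere, fraction not buried in any neighbour sphere
mc_sasa <- function(model, n_points = 1e5, probe = 1.4, seed = 99) {
  set.seed(seed)
  cst <- score_constants()$vdw_radii
  a <- model$atoms[model$atoms$element != "H", ]
  r <- vapply(a$element, function(e)
    if (!is.null(cst[[e]])) cst[[e]] else cst$default, numeric(1)) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    u <- matrix(rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      d2 <- colSums((t(pts) - xyz[j, ])^2)
      free <- free & d2 >= r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  out
}

# Horn's closed-form quaternion superposition (independent of the SVD path)
quat_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- t(Pc) %*% Qc
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
                2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
                2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
              3, 3, byrow = TRUE)
  # Horn's R maps column vectors P -> Q; row convention needs the transpose
  R <- t(R)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, rmsd = rmsd)
}

# backbone coordinate selection by (chain, resno) in native labelling
select_bb <- function(model, residues, chain_map = NULL) {
  a <- model$atoms
  if (!is.null(chain_map)) a$chain <- unname(chain_map[a$chain])
  a <- a[a$elety %in% c("N", "CA", "C", "O") &
           paste(a$chain, a$resno) %in% paste(residues$chain, residues$resno), ]
  a <- a[order(a$chain, a$resno, a$elety), ]
  as.matrix(a[, c("x", "y", "z")])
}

# brute-force native interface residues (any heavy atom within cutoff)
bf_interface_res <- function(model, cutoff = 10) {
  a <- model$atoms[model$atoms$element != "H", ]
  ch <- unique(a$chain)
  A <- a[a$chain == ch[1], ]; B <- a[a$chain == ch[2], ]
  res <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    if (d <= cutoff) {
      res[[length(res) + 1]] <- data.frame(chain = A$chain[i], resno = A$resno[i])
      res[[length(res) + 1]] <- data.frame(chain = B$chain[j], resno = B$resno[j])
    }
  }
  unique(do.call(rbind, res))
}

# independent i-RMSD oracle: brute-force interface + quaternion fit
oracle_irmsd <- function(model, native, cutoff = 10, chain_map = NULL) {
  iface <- bf_interface_res(native, cutoff)
  P <- select_bb(model, iface, chain_map)
  Q <- select_bb(native, iface)
  quat_superpose(P, Q)$rmsd
}

# independent Fnat oracle
oracle_fnat <- function(model, native, cutoff = 5, chain_map = NULL) {
  nat <- bf_contact_pairs(native, cutoff)
  m <- model
  if (!is.null(chain_map)) m$atoms$chain <- unname(chain_map[m$atoms$chain])
  mod <- bf_contact_pairs(m, cutoff)
  mean(nat %in% mod)
}

# independent L-RMSD oracle (fit on larger native chain's backbone)
oracle_lrmsd <- function(model, native, chain_map = NULL) {
  a <- native$atoms
  ch <- unique(a$chain)
  nres <- vapply(ch, function(c) length(unique(a$resno[a$chain == c])),
                 integer(1))
  receptor <- ch[which.max(nres)]
  ligand <- setdiff(ch, receptor)
  rec_res <- data.frame(chain = receptor,
                        resno = unique(a$resno[a$chain == receptor]))
  lig_res <- data.frame(chain = ligand,
                        resno = unique(a$resno[a$chain == ligand]))
  P <- select_bb(model, rec_res, chain_map); Q <- select_bb(native, rec_res)
  cp <- colMeans(P); cq <- colMeans(Q)
  fit <- quat_superpose(P, Q)
  Pl <- select_bb(model, lig_res, chain_map); Ql <- select_bb(native, lig_res)
  moved <- sweep(sweep(Pl, 2, cp) %*% fit$rotation, 2, cq, "+")
  sqrt(mean(rowSums((moved - Ql)^2)))
}

# exhaustive seed-fragment TM-score oracle with quaternion refinement
oracle_tm <- function(model, native, chain_map = NULL) {
  cm <- if (is.null(chain_map)) {
    mc <- unique(model$atoms$chain); nc <- unique(native$atoms$chain)
    setNames(nc, mc)
  } else chain_map
  am <- model$atoms; am$chain <- unname(cm[am$chain])
  an <- native$atoms
  km <- paste(am$chain, am$resno, am$elety)
  kn <- paste(an$chain, an$resno, an$elety)
  ca <- intersect(km[am$elety == "CA"], kn[an$elety == "CA"])
  P <- as.matrix(am[match(ca, km), c("x", "y", "z")])
  Q <- as.matrix(an[match(ca, kn), c("x", "y", "z")])
  L <- length(unique(paste(an$chain, an$resno)))
  d0 <- max(1.24 * (L - 15)^(1/3) - 1.8, 0.5)
  n <- nrow(P)
  tm_of <- function(idx) {
    fit <- quat_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    cp <- colMeans(P[idx, , drop = FALSE]); cq <- colMeans(Q[idx, , drop = FALSE])
    best_here <- 0
    for (k in 1:20) {
      moved <- sweep(sweep(P, 2, cp) %*% fit$rotation, 2, cq, "+")
      d <- sqrt(rowSums((moved - Q)^2))
      tm <- sum(1 / (1 + (d / d0)^2)) / L
      best_here <- max(best_here, tm)
      sel <- which(d < max(d0, 4.5))
      if (length(sel) < 3) break
      fit <- quat_superpose(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      cp <- colMeans(P[sel, , drop = FALSE]); cq <- colMeans(Q[sel, , drop = FALSE])
    }
    best_here
  }
  best <- 0
  for (len in unique(pmax(4, c(n, n %/% 2, n %/% 4, n %/% 8)))) {
    for (s in seq(1, n - len + 1)) best <- max(best, tm_of(s:(s + len - 1)))
  }
  min(best, 1)
}

# exhaustive two-sample KS permutation p-value (independent of the package)
oracle_ks_perm <- function(a, b) {
  ksd <- function(x, y) {
    g <- sort(unique(c(x, y)))
    Fx <- vapply(g, function(v) mean(x <= v), numeric(1))
    Fy <- vapply(g, function(v) mean(y <= v), numeric(1))
    max(abs(Fx - Fy))
  }
  pooled <- c(a, b); n <- length(a)
  obs <- ksd(a, b)
  idx <- combn(length(pooled), n)
  mean(apply(idx, 2, function(i) ksd(pooled[i], pooled[-i]) >= obs - 1e-12))
}

# Mann-Whitney statistic by direct pair counting
oracle_rank_sum <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# run the full interactome pipeline on a synth_interactome result
run_pipeline <- function(si, n_negatives = 0, seed = 1) {
  edges <- lapply(names(si$string_edges), function(sp) {
    f <- tempfile(fileext = ".tsv")
    write.table(si$string_edges[[sp]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    read_string_edges(f, sp, si$orthologs)
  })
  names(edges) <- names(si$string_edges)
  build_interactome(si$essentiality, si$orthologs, edges,
                    config = edge_filter_config(seed = seed),
                    family_annotation = si$families,
                    sl_pairs = si$sl_pairs, n_negatives = n_negatives)
}
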