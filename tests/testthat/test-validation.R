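test_that("Kabsch superposition matches the quaternion oracle", {
  set.seed(5)
  P <- matrix(rnorm(12), 4, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_superpose(P, P)$rotation, diag(3), tolerance = 1e-8)
  Q <- sweep(P, 2, c(5, 0, 0), "+")
  expect_equal(kabsch_superpose(P, Q)$rmsd, 0, tolerance = 1e-10)
  # random perturbed sets: agreement with an independent closed-form method
  for (i in 1:10) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- P %*% random_rotation() + matrix(rnorm(30, 0, 0.3), 10, 3)
    k <- kabsch_superpose(P, Q)
    q <- quat_superpose(P, Q)
    expect_equal(k$rmsd, q$rmsd, tolerance = 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
  # collinear sets are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("interface RMSD is zero for the native and rigid copies, else matches oracle", {
  d <- synth_dimer(sim_config(seed = 31, perturbation_sd = 0.4))
  expect_equal(interface_rmsd(d$native, d$native), 0, tolerance = 1e-9)
  set.seed(8)
  rot <- apply_rigid(d$native, random_rotation(), c(10, -5, 3))
  expect_equal(interface_rmsd(rot, d$native), 0, tolerance = 1e-8)
  expect_equal(interface_rmsd(d$perturbed, d$native),
               oracle_irmsd(d$perturbed, d$native), tolerance = 1e-6)
})

test_that("Fnat counts preserved native contacts exactly", {
  d <- synth_dimer(sim_config(seed = 31))
  expect_equal(fnat(d$native, d$native), 1)
  far <- d$native
  far$atoms$x[far$atoms$chain == "B"] <-
    far$atoms$x[far$atoms$chain == "B"] + 100
  expect_equal(fnat(far, d$native), 0)
  # ladder fixture with exactly half the contacts broken by design
  nat <- ladder_model(10)
  mod <- nat
  brk <- mod$atoms$chain == "B" & mod$atoms$resno <= 5
  mod$atoms$x[brk] <- mod$atoms$x[brk] + 50
  expect_equal(fnat(mod, nat), 0.5)
  expect_error(fnat(ladder_model(4, dx = 50), ladder_model(4, dx = 50)),
               "no interchain contacts")
})

test_that("DockQ composes its components and hits the documented extremes", {
  d <- synth_dimer(sim_config(seed = 33, perturbation_sd = 0.5))
  expect_equal(dockq(d$native, d$native)$dockq, 1, tolerance = 1e-9)
  far <- d$native
  far$atoms$x[far$atoms$chain == "B"] <-
    far$atoms$x[far$atoms$chain == "B"] + 100
  expect_lt(dockq(far, d$native)$dockq, 0.1)
  # perturbed fixture equals the hand-composition of independent components
  cst <- score_constants()$dockq
  got <- dockq(d$perturbed, d$native)
  fn <- oracle_fnat(d$perturbed, d$native, cst$fnat_cutoff)
  ir <- oracle_irmsd(d$perturbed, d$native, cst$interface_cutoff)
  lr <- oracle_lrmsd(d$perturbed, d$native)
  expect_equal(got$fnat, fn, tolerance = 1e-6)
  expect_equal(got$irms, ir, tolerance = 1e-3)
  expect_equal(got$lrms, lr, tolerance = 1e-3)
  expect_equal(got$dockq,
               (fn + 1 / (1 + (ir / cst$d1)^2) + 1 / (1 + (lr / cst$d2)^2)) / 3,
               tolerance = 1e-3)
})

test_that("TM-score is 1 for rigid copies, bounded, and matches the seed-search oracle", {
  d <- synth_dimer(sim_config(seed = 35, perturbation_sd = 0.6))
  expect_equal(tm_score(d$native, d$native), 1, tolerance = 1e-6)
  set.seed(2)
  rot <- apply_rigid(d$native, random_rotation(), c(-8, 4, 12))
  expect_equal(tm_score(rot, d$native), 1, tolerance = 1e-6)
  got <- tm_score(d$perturbed, d$native)
  expect_lte(got, 1)
  expect_equal(got, oracle_tm(d$perturbed, d$native), tolerance = 1e-3)
  # strictly decreasing as one chain is displaced farther
  tms <- vapply(c(0, 2, 5, 10), function(off) {
    m <- d$native
    m$atoms$x[m$atoms$chain == "B"] <- m$atoms$x[m$atoms$chain == "B"] + off
    tm_score(m, d$native)
  }, numeric(1))
  expect_true(all(diff(tms) < 0))
})

test_that("crosslink restraints check C-alpha distances between lysines", {
  m <- structure_model(rbind(
    atom_row("A", 1, "CA", "C", 0, 0, 0, resid = "LYS"),
    atom_row("A", 2, "CA", "C", 0, 0, 40, resid = "LYS"),
    atom_row("B", 1, "CA", "C", 18, 0, 0, resid = "LYS"),
    atom_row("B", 2, "CA", "C", 35, 0, 40, resid = "ALA")), "xl")
  r <- data.frame(chain_a = c("A", "A"), resno_a = c(1, 2),
                  chain_b = c("B", "B"), resno_b = c(1, 1))
  out <- crosslink_check(m, r)
  expect_equal(out$satisfied, 1L)  # 18 A within 20; the 43.8 A one violated
  expect_equal(out$total, 2L)
  expect_equal(out$fraction, 0.5)
  # non-lysine and missing residues are skipped with a warning
  r2 <- data.frame(chain_a = "A", resno_a = 1, chain_b = "B", resno_b = 2)
  expect_warning(out2 <- crosslink_check(m, r2), "skipped")
  expect_equal(out2$total, 0L)
  empty <- crosslink_check(m, NULL)
  expect_equal(empty$total, 0L)
  expect_true(is.na(empty$fraction))
})

test_that("benchmark filter enforces every criterion, order-invariantly", {
  entries <- data.frame(
    pdb_id = sprintf("%04d", 1:7),
    release_date = c("2022-01-01", "2022-01-01", "2020-01-01", "2022-01-01",
                     "2022-01-01", "2022-01-01", "2022-01-01"),
    method = c("xray", "cryoem", "xray", "other", "xray", "xray", "xray"),
    resolution = c(2.0, 1.5, 1.5, 1.5, 2.4, 2.0, 2.0),
    n_distinct_chains = c(2, 2, 2, 2, 2, 3, 2),
    cluster_representative = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    max_identity_to_training = c(0.25, 0.30, 0.2, 0.2, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE)
  kept <- benchmark_filter(entries)
  expect_equal(kept$pdb_id, "0001")  # 2.0 A, 0.25 identity, representative
  # identity 0.30 dropped (strict <), old release dropped, non-xray/cryoem
  # dropped, >2 A dropped, trimer dropped, non-representative dropped
  shuf <- entries[sample(nrow(entries)), ]
  expect_equal(benchmark_filter(shuf)$pdb_id, "0001")
  expect_equal(benchmark_filter(kept), kept)  # idempotent
})

test_that("validation metrics are invariant to independent rigid motions", {
  d <- synth_dimer(sim_config(seed = 40, perturbation_sd = 0.5))
  base <- validation_report(d$perturbed, d$native)
  set.seed(9)
  m2 <- apply_rigid(d$perturbed, random_rotation(), rnorm(3, 0, 15))
  n2 <- apply_rigid(d$native, random_rotation(), rnorm(3, 0, 15))
  r2 <- validation_report(m2, n2)
  expect_equal(r2$fnat, base$fnat, tolerance = 1e-9)
  expect_equal(r2$i_rmsd, base$i_rmsd, tolerance = 1e-6)
  expect_equal(r2$l_rmsd, base$l_rmsd, tolerance = 1e-6)
  expect_equal(r2$dockq, base$dockq, tolerance = 1e-6)
  expect_equal(r2$tm_score, base$tm_score, tolerance = 1e-4)
})
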