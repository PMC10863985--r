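test_that("contact and interface cutoffs behave as documented", {
  cfg <- interface_config()
  expect_equal(nrow(find_contact_residues(two_res_model(50), cfg)), 0)
  expect_equal(nrow(find_contact_residues(two_res_model(4.4), cfg)), 1)
  expect_equal(nrow(find_contact_residues(two_res_model(4.6), cfg)), 0)
  # 9.8 A: interface but not contact; 12 A: neither
  expect_equal(nrow(find_interface_residues(two_res_model(9.8), cfg)), 2)
  expect_equal(nrow(find_contact_residues(two_res_model(9.8), cfg)), 0)
  expect_equal(nrow(find_interface_residues(two_res_model(12), cfg)), 0)
})

test_that("contact set matches brute force and nests inside the interface set", {
  d <- synth_dimer(sim_config(seed = 21, axial_offset = 10))
  cfg <- interface_config()
  cc <- find_contact_residues(d$native, cfg)
  expect_setequal(paste(cc$chain_a, cc$resno_a, cc$chain_b, cc$resno_b),
                  bf_contact_pairs(d$native, cfg$contact_cutoff))
  contact_res <- unique(rbind(
    data.frame(chain = cc$chain_a, resno = cc$resno_a),
    data.frame(chain = cc$chain_b, resno = cc$resno_b)))
  iface <- find_interface_residues(d$native, cfg)
  expect_true(all(paste(contact_res$chain, contact_res$resno) %in%
                    paste(iface$chain, iface$resno)))
})

test_that("SASA reproduces analytic spheres, additivity and the MC oracle", {
  cst <- score_constants()$vdw_radii
  one <- structure_model(atom_row("A", 1, "C", "C", 0, 0, 0), "one")
  s1 <- shrake_rupley_sasa(one)
  expect_equal(as.numeric(s1), 4 * pi * (cst$C + 1.4)^2, tolerance = 0.005)
  # two atoms far apart: isolated-sphere additivity
  two <- structure_model(rbind(atom_row("A", 1, "C", "C", 0, 0, 0),
                               atom_row("A", 2, "C", "C", 100, 0, 0)), "two")
  s2 <- shrake_rupley_sasa(two)
  expect_equal(sum(s2), 2 * 4 * pi * (cst$C + 1.4)^2, tolerance = 0.01)
  # overlapping pair against a high-resolution Monte-Carlo oracle (<1%)
  pair <- structure_model(rbind(atom_row("A", 1, "C", "C", 0, 0, 0),
                                atom_row("A", 2, "N", "N", 2.0, 0.5, 0.3)),
                          "pair")
  got <- shrake_rupley_sasa(pair, sphere_points = 4000)
  mc <- mc_sasa(pair, n_points = 2e5)
  expect_lt(max(abs(got - mc) / mc), 0.01)
  # unknown elements fall back to the default radius with a warning
  odd <- structure_model(atom_row("A", 1, "X1", "X", 0, 0, 0), "odd")
  expect_warning(sx <- shrake_rupley_sasa(odd), "default")
  expect_equal(as.numeric(sx), 4 * pi * (cst$default + 1.4)^2,
               tolerance = 0.01)
})

test_that("SASA quadrature converges as sphere points double", {
  d <- synth_dimer(sim_config(seed = 4, dimer_length = 10))
  s1 <- shrake_rupley_sasa(d$native, sphere_points = 960)
  s2 <- shrake_rupley_sasa(d$native, sphere_points = 1920)
  # relative to each atom's full inflated-sphere area (buried atoms have
  # near-zero exposed area, where a ratio of exposed areas is meaningless)
  cst <- score_constants()$vdw_radii
  full <- 4 * pi * (vapply(attr(s1, "atoms")$elety, function(e)
    cst[[substr(e, 1, 1)]], numeric(1)) + 1.4)^2
  expect_lt(max(abs(s1 - s2) / full), 0.005)
})

test_that("buried interface area is non-negative, zero at separation, monotone", {
  cfg <- interface_config(sphere_points = 500)
  d <- synth_dimer(sim_config(seed = 6, dimer_length = 12))
  apart <- d$native
  bb <- apart$atoms$chain == "B"
  apart$atoms$x[bb] <- apart$atoms$x[bb] + 100
  expect_equal(buried_interface_area(apart, cfg)$buried_area, 0,
               tolerance = 1)
  tight <- buried_interface_area(d$native, cfg)
  expect_gt(tight$buried_area, 0)
  # pulling the chains 2 A apart strictly shrinks the buried area
  pulled <- d$native
  pulled$atoms$x[pulled$atoms$chain == "B"] <-
    pulled$atoms$x[pulled$atoms$chain == "B"] + 2
  expect_lt(buried_interface_area(pulled, cfg)$buried_area,
            tight$buried_area)
})

test_that("surface residues equal per-atom SASA thresholding on isolated chains", {
  d <- synth_dimer(sim_config(seed = 9, dimer_length = 12))
  cfg <- interface_config(sphere_points = 500)
  surf <- find_surface_residues(d$native, cfg)
  # oracle: recompute from per-atom SASA of each isolated chain
  expected <- do.call(rbind, lapply(chain_ids(d$native), function(ch) {
    at <- d$native$atoms[d$native$atoms$chain == ch, ]
    s <- shrake_rupley_sasa(structure_model(at, "iso"), cfg$probe_radius,
                            cfg$sphere_points)
    tab <- attr(s, "atoms")
    unique(data.frame(chain = tab$chain[s >= cfg$surface_atom_sasa_min],
                      resno = tab$resno[s >= cfg$surface_atom_sasa_min]))
  }))
  expect_setequal(paste(surf$chain, surf$resno),
                  paste(expected$chain, expected$resno))
})

test_that("geometry outputs are invariant under rigid-body motion", {
  d <- synth_dimer(sim_config(seed = 30, axial_offset = 8))
  cfg <- interface_config(sphere_points = 300)
  cc0 <- find_contact_residues(d$native, cfg)
  if0 <- find_interface_residues(d$native, cfg)
  ba0 <- buried_interface_area(d$native, cfg)$buried_area
  set.seed(3)
  for (i in 1:3) {
    mt <- apply_rigid(d$native, random_rotation(), rnorm(3, 0, 30))
    expect_equal(find_contact_residues(mt, cfg), cc0, tolerance = 1e-8)
    expect_equal(find_interface_residues(mt, cfg), if0)
    expect_equal(buried_interface_area(mt, cfg)$buried_area, ba0,
                 tolerance = 0.5)
  }
})

test_that("conservation contrast matches the rank-sum oracle and flags shifts", {
  ident <- conservation_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_two_sided, 1)
  # statistic equals the pair-counting (Mann-Whitney) oracle
  x <- c(9, 9, 9); y <- c(1, 1, 1)
  cc <- conservation_contrast(x, y)
  expect_equal(cc$statistic, oracle_rank_sum(x, y))
  set.seed(14)
  for (i in 1:5) {
    a <- sample(1:9, 20, TRUE); b <- sample(1:9, 15, TRUE)
    expect_equal(conservation_contrast(a, b)$statistic,
                 oracle_rank_sum(a, b))
  }
  expect_error(conservation_contrast(1, c(1, 2)), "at least 2")
  # a +2 interface shift at n=200 is detected
  set.seed(22)
  base <- sample(1:9, 100, TRUE)
  shifted <- pmin(sample(1:9, 100, TRUE) + 2, 9)
  expect_lt(conservation_contrast(shifted, base)$p_greater, 0.05)
})

test_that("residue-type network counts side-chain contacts additively", {
  # one ARG-GLU side-chain contact: CB atoms 4 A apart
  m <- structure_model(rbind(
    atom_row("A", 1, "CB", "C", 0, 0, 0, resid = "ARG"),
    atom_row("A", 1, "CA", "C", 0, 0, 1.5, resid = "ARG"),
    atom_row("B", 1, "CB", "C", 4, 0, 0, resid = "GLU"),
    atom_row("B", 1, "CA", "C", 4, 0, 1.5, resid = "GLU")), "pair")
  g1 <- residue_type_network(list(m))
  e1 <- residue_type_edges(g1)
  expect_equal(nrow(e1), 1)
  expect_setequal(c(e1$type_a, e1$type_b), c("ARG", "GLU"))
  expect_equal(e1$weight, 1)
  # the same contact in three models accumulates weight 3
  e3 <- residue_type_edges(residue_type_network(list(m, m, m)))
  expect_equal(e3$weight, 3)
  # backbone-only proximity does not count (side-chain criterion):
  # CA atoms are backbone for non-glycine residues
  m2 <- structure_model(rbind(
    atom_row("A", 1, "CA", "C", 0, 0, 0, resid = "ARG"),
    atom_row("B", 1, "CA", "C", 4, 0, 0, resid = "GLU")), "bbonly")
  expect_equal(nrow(residue_type_edges(residue_type_network(list(m2)))), 0)
  # glycine's side chain is its CA
  m3 <- structure_model(rbind(
    atom_row("A", 1, "CA", "C", 0, 0, 0, resid = "GLY"),
    atom_row("B", 1, "CB", "C", 4, 0, 0, resid = "LEU")), "gly")
  eg <- residue_type_edges(residue_type_network(list(m3)))
  expect_equal(nrow(eg), 1)
  # matches brute-force enumeration on a synthetic dimer (ALA-ALA self-edge)
  d <- synth_dimer(sim_config(seed = 17))
  ed <- residue_type_edges(residue_type_network(list(d$native)))
  a <- d$native$atoms
  sc <- a[a$elety %in% c("CB"), ]
  bf <- bf_contact_pairs(structure_model(sc, "sc"), 4.5)
  if (length(bf) > 0) {
    expect_equal(ed$weight, length(bf))
    expect_equal(c(ed$type_a, ed$type_b), c("ALA", "ALA"))
  } else {
    expect_equal(nrow(ed), 0)
  }
})

test_that("interface report nests residue sets and excludes interface from surface", {
  d <- synth_dimer(sim_config(seed = 25, dimer_length = 16, axial_offset = 14))
  cons <- synth_conservation(d$native, shift = 3, seed = 2)
  rep <- interface_report(d$native, cons, interface_config(sphere_points = 300))
  ik <- paste(rep$interface_residues$chain, rep$interface_residues$resno)
  sk <- paste(rep$surface_residues$chain, rep$surface_residues$resno)
  expect_length(intersect(ik, sk), 0)
  ck <- unique(c(paste(rep$contact_pairs$chain_a, rep$contact_pairs$resno_a),
                 paste(rep$contact_pairs$chain_b, rep$contact_pairs$resno_b)))
  expect_true(all(ck %in% ik))
  expect_gte(rep$buried_area, 0)
  expect_false(is.null(rep$conservation_stats))
})
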