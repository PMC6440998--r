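toy <- generate_toy_complex(seed = 11)

test_that("toy complex is reproducible and PDB IO round-trips coordinates", {
  toy2 <- generate_toy_complex(seed = 11)
  expect_identical(toy$atoms, toy2$atoms)

  path <- tempfile(fileext = ".pdb")
  write_structure(toy, path)
  rt <- read_structure(path, domain_resno = 1:20, anchor_resno = 1)
  # PDB fixes 3 decimal places
  expect_equal(rt$atoms$x, toy$atoms$x, tolerance = 1e-3)
  expect_equal(rt$atoms$z, toy$atoms$z, tolerance = 1e-3)

  # residue-range mask: domain chain D holds exactly the rod atoms
  rt2 <- read_structure(path, domain_resno = 1:20, anchor_resno = 1,
                        chain = "D")
  expect_equal(sum(rt2$atoms$domain), sum(toy$atoms$domain))
})

test_that("conformer grids have the configured size and preserve rigidity", {
  cs_small <- generate_conformers(toy, grid_points_per_axis = 5)
  expect_equal(dim(cs_small$coords)[3], 125)

  # identity rotation is on the grid with zero RMSD to the input
  D0 <- as.matrix(toy$atoms[toy$atoms$domain, c("x", "y", "z")])
  id <- which(rowSums(abs(cs_small$angles)) == 0)
  expect_length(id, 1)
  expect_equal(rmsd_to_reference(cs_small$coords[, , id], D0), 0,
               tolerance = 1e-9)

  # rigid body: intra-domain distances preserved to 1e-6 A
  d0 <- dist(D0)
  for (i in c(1, 40, 125)) {
    expect_equal(max(abs(dist(cs_small$coords[, , i]) - d0)), 0,
                 tolerance = 1e-6)
  }

  # a single-atom domain sweeps a sphere around the anchor
  toy1 <- generate_toy_complex(n_domain_atoms = 1, seed = 3)
  cs1 <- generate_conformers(toy1, grid_points_per_axis = 7)
  r <- apply(cs1$coords, 3, function(m) sqrt(sum((m - toy1$anchor)^2)))
  expect_equal(var(r), 0, tolerance = 1e-12)
})

test_that("clash criterion implements the vdW overlap rule and matches the oracle", {
  # two carbon-like atoms (r = 1.7) at 3.0 A: 3.0 < 1.7 + 1.7 - 0.3 -> clash
  atoms <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 3.0),
                      elem = "C", radius = 1.7, chain = c("B", "D"),
                      resno = 1:2, name = "CA", domain = c(FALSE, TRUE))
  st <- fret_structure(atoms, anchor = c(0, 0, 0))
  cs <- list(angles = matrix(0, 1, 3),
             coords = array(c(0, 0, 3.0), c(1, 3, 1)), structure = st)
  class(cs) <- "conformer_set"
  expect_true(clash_filter(cs, threshold = 0.3)$clash)
  # at 3.2 A the margin is positive (3.2 > 3.1)
  cs$coords[1, 3, 1] <- 3.2
  expect_false(clash_filter(cs, threshold = 0.3)$clash)
  # a domain translated 100 A away trivially survives
  cs$coords[1, 3, 1] <- 100
  expect_false(clash_filter(cs, threshold = 0.3)$clash)

  # grid: both clashing and clash-free conformers exist; box prefilter agrees
  # with the all-pairs oracle everywhere
  cs5 <- clash_filter(generate_conformers(toy, grid_points_per_axis = 5))
  expect_gt(sum(cs5$clash), 0)
  expect_gt(sum(!cs5$clash), 0)
  expect_identical(cs5$clash, clash_filter_allpairs(cs5))

  # monotonicity: a more permissive threshold never shrinks the survivor set
  cs5b <- clash_filter(generate_conformers(toy, grid_points_per_axis = 5),
                       threshold = 0.6)
  expect_true(all(!cs5$clash | !cs5b$clash | cs5b$clash))
  expect_gte(sum(!cs5b$clash), sum(!cs5$clash))
})

test_that("accessible volume fills free space and respects steric walls", {
  # isolated attachment point: cloud fills a ball of the linker length
  lone <- fret_structure(data.frame(x = 0, y = 0, z = 0, elem = "C",
                                    radius = 1.7, chain = "B", resno = 1,
                                    name = "CA", domain = FALSE),
                         anchor = c(0, 0, 0))
  cl <- accessible_volume(lone, 1, linker_length = 20)
  vol_ball <- 4 / 3 * pi * 20^3
  expect_equal(nrow(cl$positions) * cl$spacing^3, vol_ball, tolerance = 0.1)
  expect_true(all(rowSums(sweep(cl$positions, 2, cl$attachment)^2) <= 20^2 + 1e-9))

  # half-space wall: cloud confined to the free side, verified per point
  wall <- expand.grid(x = seq(-30, 30, 2), y = seq(-30, 30, 2), z = -6)
  atoms <- rbind(data.frame(x = 0, y = 0, z = 0, elem = "C", radius = 1.7,
                            chain = "B", resno = 1, name = "CA", domain = FALSE),
                 data.frame(x = wall$x, y = wall$y, z = wall$z, elem = "C",
                            radius = 1.7, chain = "W",
                            resno = seq_len(nrow(wall)) + 1, name = "CA",
                            domain = FALSE))
  stw <- fret_structure(atoms, anchor = c(0, 0, 0))
  clw <- accessible_volume(stw, 1, linker_length = 15)
  wallm <- as.matrix(wall)
  for (i in seq_len(nrow(clw$positions))) {
    dmin <- min(sqrt(rowSums(sweep(wallm, 2, clw$positions[i, ])^2)))
    expect_gte(dmin, 1.7 + 3.5 - 1e-9)  # atom radius + dye radius
  }

  # default dye parameters on the toy complex land in the 600-1200 range
  cl_toy <- accessible_volume(toy, "d_tip")
  expect_gte(nrow(cl_toy$positions), 600)
  expect_lte(nrow(cl_toy$positions), 1200)
})

test_that("pair efficiency is the exact cloud average of the Forster curve", {
  pt <- function(x, y, z) structure(list(positions = matrix(c(x, y, z), 1, 3)),
                                    class = "dye_cloud")
  # two single positions at r = R0 -> E = 0.5; r = 2 R0 -> 1/65
  expect_equal(predict_pair_efficiency(pt(0, 0, 0), pt(50, 0, 0), R0 = 50), 0.5)
  expect_equal(predict_pair_efficiency(pt(0, 0, 0), pt(100, 0, 0), R0 = 50),
               1 / 65, tolerance = 1e-12)

  # 10-point clouds: equals the brute-force double loop
  set.seed(21)
  D <- matrix(rnorm(30, sd = 5), 10, 3)
  A <- matrix(rnorm(30, sd = 5) + 40, 10, 3)
  cd <- structure(list(positions = D), class = "dye_cloud")
  ca <- structure(list(positions = A), class = "dye_cloud")
  brute <- mean(vapply(seq_len(10), function(i) {
    mean(vapply(seq_len(10), function(j) {
      r <- sqrt(sum((D[i, ] - A[j, ])^2))
      1 / (1 + (r / 50)^6)
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(predict_pair_efficiency(cd, ca, 50), brute, tolerance = 1e-12)

  # monotone decreasing with rigid translation apart
  es <- vapply(c(0, 10, 20, 40), function(s) {
    ca2 <- structure(list(positions = sweep(A, 2, c(s, 0, 0), "+")),
                     class = "dye_cloud")
    predict_pair_efficiency(cd, ca2, 50)
  }, numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("chi-squared ranking reproduces the sum-of-squares rule", {
  # hand triple: (0.8,0.6,0.4) vs (0.7,0.6,0.5) -> chi2 = 0.02
  E_model <- rbind(c(0.7, 0.6, 0.5), c(0.8, 0.6, 0.4))
  r <- rank_conformers(E_model, c(0.8, 0.6, 0.4), top_m = 2)
  expect_equal(r$states[[1]]$ranking$chi2, c(0, 0.02), tolerance = 1e-12)
  expect_equal(r$states[[1]]$ranking$conformer, c(2, 1))

  # exact match ranks first with chi2 = 0; NA rows excluded with a notice
  E2 <- rbind(c(0.5, 0.5, 0.5), c(NA, 0.5, 0.5))
  expect_message(r2 <- rank_conformers(E2, c(0.5, 0.5, 0.5)), "excluded")
  expect_equal(r2$states[[1]]$ranking$conformer, 1)
})

test_that("RMSD and tilt behave as rigid-geometry closed forms", {
  D0 <- as.matrix(toy$atoms[toy$atoms$domain, c("x", "y", "z")])
  expect_equal(rmsd_to_reference(D0, D0), 0)
  expect_equal(rmsd_to_reference(sweep(D0, 2, c(1, 0, 0), "+"), D0), 1)
  expect_error(rmsd_to_reference(D0[-1, ], D0), "differ")

  # rotation by theta about an axis through the centroid: per-atom displacement
  # 2 r_i sin(theta/2), r_i = distance from the axis
  rot_about <- function(M, center, axis, deg) {
    axis <- axis / sqrt(sum(axis^2))
    th <- deg * pi / 180
    Kx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                   axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
    sweep(sweep(M, 2, center) %*% t(R), 2, center, "+")
  }
  cen <- colMeans(D0)
  ax <- c(1, 0, 0)
  M10 <- rot_about(D0, cen, ax, 10)
  Mc <- sweep(D0, 2, cen)
  r_axis <- sqrt(rowSums((Mc - outer(as.vector(Mc %*% ax), ax))^2))
  expect_equal(rmsd_to_reference(M10, D0),
               sqrt(mean((2 * r_axis * sin(5 * pi / 180))^2)), tolerance = 1e-9)

  # tilt: rotating about an axis perpendicular to the rod axis gives the angle
  expect_equal(tilt_angle(D0, D0), 0, ignore_attr = TRUE)
  sv <- svd(sweep(D0, 2, colMeans(D0)))
  rod_axis <- sv$v[, 1]
  perp <- c(-rod_axis[2], rod_axis[1], 0)
  M40 <- rot_about(D0, cen, perp, 40)
  expect_equal(as.numeric(tilt_angle(M40, D0)), 40, tolerance = 1e-6)
  expect_equal(as.numeric(tilt_angle(D0, M40)), as.numeric(tilt_angle(M40, D0)),
               tolerance = 1e-9)
})

test_that("toy triangulation recovers a designated true conformer end to end", {
  res <- triangulate(toy, E_measured = c(0.5, 0.5, 0.5), R0 = 45,
                     grid_points_per_axis = 7, top_m = 10,
                     av_params = list(grid_spacing = 3))
  surv <- which(!res$conformers$clash & rowSums(is.na(res$E_model)) == 0)
  expect_gt(length(surv), 20)
  # designate an interior clash-free conformer as truth
  true_id <- surv[which.min(abs(res$conformers$angles[surv, 2] - 45) +
                              abs(res$conformers$angles[surv, 1] - 60))]
  ranking <- rank_conformers(res$E_model, res$E_model[true_id, ], top_m = 10)
  best <- ranking$states[[1]]$ranking
  expect_equal(best$chi2[1], 0, tolerance = 1e-12)
  # the top conformer is geometrically the true one (ties are duplicates)
  expect_equal(rmsd_to_reference(res$conformers$coords[, , best$conformer[1]],
                                 res$conformers$coords[, , true_id]),
               0, tolerance = 1e-6)
})
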