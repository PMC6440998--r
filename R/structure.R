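#' Structure container for rigid-body FRET triangulation
#'
#' A light data-frame representation of a protein (or toy) structure: one row
#' per atom with coordinates (Angstrom), element, van der Waals radius, chain
#' / residue / atom identifiers, and a logical `domain` mask marking the
#' mobile domain. The anchor — the pivot about which the domain rotates — is
#' stored as an attribute, along with named labeling sites usable as FRET
#' attachment points.
#'
#' @param atoms Data frame with columns `x`, `y`, `z`, `elem`, `radius`,
#'   `chain`, `resno`, `name`, `domain`.
#' @param anchor Numeric length-3 pivot coordinates.
#' @param sites Optional named integer vector of attachment atom indices.
#' @return A `fret_structure` object.
#' @export
fret_structure <- function(atoms, anchor, sites = NULL) {
  need <- c("x", "y", "z", "elem", "radius", "chain", "resno", "name", "domain")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (any(atoms$radius <= 0)) stop("van der Waals radii must be positive")
  stopifnot(length(anchor) == 3)
  structure(list(atoms = atoms, anchor = as.numeric(anchor),
                 sites = sites),
            class = "fret_structure")
}

#' @export
print.fret_structure <- function(x, ...) {
  cat(sprintf("<fret_structure> %d atoms (%d mobile-domain), %d site(s)\n",
              nrow(x$atoms), sum(x$atoms$domain), length(x$sites)))
  invisible(x)
}

# element-based van der Waals radii (Angstrom, Bondi-type values)
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98, X = 1.70)

#' Read a PDB structure with a mobile-domain specification
#'
#' Thin wrapper around `bio3d::read.pdb` that assigns element-based van der
#' Waals radii and marks the mobile domain by a residue range. The anchor
#' defaults to the CA atom (or first atom) of `anchor_resno`.
#'
#' @param path PDB file path.
#' @param domain_resno Integer vector of residue numbers forming the mobile
#'   domain.
#' @param anchor_resno Residue number of the pivot (should adjoin the
#'   domain's attachment region).
#' @param chain Optional chain restriction for the domain mask.
#' @return A `fret_structure`.
#' @export
read_structure <- function(path, domain_resno, anchor_resno, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                         substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1),
                         trimws(a$elesy)))
  unknown <- !(elem %in% names(.vdw_table))
  if (any(unknown)) {
    stop("unknown element(s): ", paste(unique(elem[unknown]), collapse = ", "))
  }
  domain <- a$resno %in% domain_resno
  if (!is.null(chain)) domain <- domain & a$chain %in% chain
  anchor_rows <- which(a$resno == anchor_resno &
                         (is.null(chain) | a$chain %in% chain))
  if (!length(anchor_rows)) stop("anchor residue ", anchor_resno, " not found")
  ca <- anchor_rows[a$elety[anchor_rows] == "CA"]
  ai <- if (length(ca)) ca[1] else anchor_rows[1]
  atoms <- data.frame(x = a$x, y = a$y, z = a$z, elem = elem,
                      radius = unname(.vdw_table[elem]),
                      chain = a$chain, resno = a$resno, name = a$elety,
                      domain = domain)
  fret_structure(atoms, anchor = c(a$x[ai], a$y[ai], a$z[ai]))
}

#' Write a structure (or conformer coordinates) to PDB
#'
#' @param structure A `fret_structure`.
#' @param path Output PDB path.
#' @param domain_coords Optional replacement coordinates for the domain atoms
#'   (matrix, one row per domain atom), e.g. one conformer.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, domain_coords = NULL) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!is.null(domain_coords)) xyz[a$domain, ] <- domain_coords
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   resno = a$resno, chain = a$chain,
                   resid = rep("GLY", nrow(a)), elety = a$name,
                   elesy = a$elem)
  invisible(path)
}

#' Generate a toy body-plus-mobile-domain complex
#'
#' Desk-scale stand-in for a large ring assembly with a protruding mobile
#' domain: the fixed "body" is a seeded random packing of pseudo-atoms inside
#' a sphere, and the mobile "domain" is a straight rod of atoms attached at
#' an anchor atom on the body surface, pointing outward. Four labeled sites
#' are provided — two on the domain (tip and midpoint) and two on the body —
#' combined into three body-domain FRET pairs, mirroring a triangulation
#' experiment with three dye pairs.
#'
#' @param n_body_atoms Atoms in the fixed body (default 150).
#' @param n_domain_atoms Atoms in the mobile rod (default 20; 1 gives a
#'   single satellite atom whose rotations sweep a sphere about the anchor).
#' @param anchor_index Which body atom (by descending z) carries the domain
#'   (default 1, the topmost).
#' @param seed Integer seed; coordinates are bitwise reproducible.
#' @return A `fret_structure` with attribute `pairs`: a list of three
#'   `c(donor_site, acceptor_site)` name pairs.
#' @export
generate_toy_complex <- function(n_body_atoms = 150, n_domain_atoms = 20,
                                 anchor_index = 1, seed = 1) {
  stopifnot(n_body_atoms >= 3, n_domain_atoms >= 1,
            anchor_index >= 1, anchor_index <= n_body_atoms)
  withr::with_seed(seed, {
    r_body <- 12
    # uniform points in a ball, thinned to a loose packing
    m <- matrix(rnorm(3 * n_body_atoms * 8), ncol = 3)
    m <- m / sqrt(rowSums(m^2)) * r_body * runif(nrow(m))^(1 / 3)
    keep <- rep(TRUE, nrow(m))
    sel <- integer(0)
    for (i in seq_len(nrow(m))) {
      if (!keep[i]) next
      sel <- c(sel, i)
      if (length(sel) == n_body_atoms) break
      d2 <- rowSums((m - matrix(m[i, ], nrow(m), 3, byrow = TRUE))^2)
      keep[d2 < 2.8^2] <- FALSE
      keep[i] <- FALSE
    }
    while (length(sel) < n_body_atoms) sel <- c(sel, sample(nrow(m), 1))
    body <- m[sel[seq_len(n_body_atoms)], , drop = FALSE]
  })
  ord <- order(body[, 3], decreasing = TRUE)
  anchor_atom <- ord[anchor_index]
  anchor <- body[anchor_atom, ]
  u <- anchor / sqrt(sum(anchor^2))   # outward surface normal
  # rod starts one clear contact distance above the anchor atom so the
  # resting (identity) conformation is clash-free
  rod <- anchor + outer(3.0 + 1.5 * (seq_len(n_domain_atoms) - 1), u)
  atoms <- data.frame(
    x = c(body[, 1], rod[, 1]), y = c(body[, 2], rod[, 2]),
    z = c(body[, 3], rod[, 3]),
    elem = "C", radius = 1.7,
    chain = rep(c("B", "D"), c(n_body_atoms, n_domain_atoms)),
    resno = c(seq_len(n_body_atoms), seq_len(n_domain_atoms)),
    name = "CA",
    domain = rep(c(FALSE, TRUE), c(n_body_atoms, n_domain_atoms)))
  sites <- c(d_tip = n_body_atoms + n_domain_atoms,
             d_mid = n_body_atoms + max(1L, n_domain_atoms %/% 2L),
             b_1 = which.max(atoms$x[seq_len(n_body_atoms)]),
             b_2 = which.min(atoms$x[seq_len(n_body_atoms)]))
  st <- fret_structure(atoms, anchor = anchor, sites = sites)
  attr(st, "pairs") <- list(c("d_tip", "b_1"), c("d_tip", "b_2"),
                            c("d_mid", "b_1"))
  st
}

.euler_zyz <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

#' Generate a rigid-body rotation grid of domain conformers
#'
#' Samples intrinsic z-y-z Euler angles on a uniform grid (default 25 points
#' per axis, 25^3 = 15,625 conformers) and rotates the mobile domain rigidly
#' about the anchor point. The identity rotation is always on the grid.
#'
#' @param structure A `fret_structure` with a marked domain.
#' @param grid_points_per_axis Points per Euler axis (default 25).
#' @param alpha_range,beta_range,gamma_range Angle ranges in degrees. The
#'   defaults cover a full azimuthal sweep with tilts up to 135 degrees,
#'   deliberately overshooting the sterically possible range so the clash
#'   filter has work to do.
#' @return A `conformer_set`: `angles` (n x 3, degrees), `coords` (array
#'   n_domain_atoms x 3 x n), plus the source structure.
#' @export
generate_conformers <- function(structure, grid_points_per_axis = 25,
                                alpha_range = c(-180, 180),
                                beta_range = c(0, 135),
                                gamma_range = c(-180, 180)) {
  g <- grid_points_per_axis
  stopifnot(g >= 1)
  gridseq <- function(r) seq(r[1], r[2], length.out = g)
  ang <- as.matrix(expand.grid(alpha = gridseq(alpha_range),
                               beta = gridseq(beta_range),
                               gamma = gridseq(gamma_range)))
  D <- as.matrix(structure$atoms[structure$atoms$domain, c("x", "y", "z")])
  Dc <- sweep(D, 2, structure$anchor)
  n <- nrow(ang)
  coords <- array(NA_real_, dim = c(nrow(D), 3, n))
  for (i in seq_len(n)) {
    R <- .euler_zyz(ang[i, 1] * pi / 180, ang[i, 2] * pi / 180,
                    ang[i, 3] * pi / 180)
    coords[, , i] <- sweep(Dc %*% t(R), 2, structure$anchor, "+")
  }
  out <- list(angles = ang, coords = coords, structure = structure)
  class(out) <- "conformer_set"
  out
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %d conformers, %d domain atoms%s\n",
              dim(x$coords)[3], dim(x$coords)[1],
              if (!is.null(x$clash)) sprintf(", %d clash-free", sum(!x$clash)) else ""))
  invisible(x)
}

#' Filter conformers by van der Waals steric clashes
#'
#' A conformer is rejected when any mobile-domain atom approaches any
#' non-domain atom closer than the sum of their van der Waals radii minus the
#' clash threshold: a clash is `d_ij < R_v(i) + R_v(j) - threshold`. A
#' bounding-box prefilter restricts the candidate body atoms per conformer;
#' the result is identical to the all-pairs check (see
#' [clash_filter_allpairs()], the reference oracle).
#'
#' @param conformers A `conformer_set`.
#' @param structure The `fret_structure` (defaults to the set's own).
#' @param threshold Clash threshold in Angstrom (default 0.3).
#' @return The `conformer_set` with `clash` (logical), `min_margin` (Angstrom,
#'   smallest `d_ij - (R_i + R_j - threshold)`), and `survival_fraction`.
#' @export
clash_filter <- function(conformers, structure = conformers$structure,
                         threshold = 0.3) {
  a <- structure$atoms
  B <- as.matrix(a[!a$domain, c("x", "y", "z")])
  rb <- a$radius[!a$domain]
  rd <- a$radius[a$domain]
  n <- dim(conformers$coords)[3]
  maxsum <- max(outer(rd, rb, "+")) - threshold
  b2 <- rowSums(B^2)
  clash <- logical(n)
  margin <- numeric(n)
  for (i in seq_len(n)) {
    D <- conformers$coords[, , i, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, 1, 3)
    # box prefilter: body atoms near the domain's bounding box
    lo <- apply(D, 2, min) - maxsum; hi <- apply(D, 2, max) + maxsum
    near <- B[, 1] >= lo[1] & B[, 1] <= hi[1] &
      B[, 2] >= lo[2] & B[, 2] <= hi[2] &
      B[, 3] >= lo[3] & B[, 3] <= hi[3]
    if (!any(near)) { clash[i] <- FALSE; margin[i] <- Inf; next }
    Bn <- B[near, , drop = FALSE]
    d <- sqrt(pmax(outer(rowSums(D^2), b2[near], "+") - 2 * (D %*% t(Bn)), 0))
    lim <- outer(rd, rb[near], "+") - threshold
    margin[i] <- min(d - lim)
    clash[i] <- margin[i] < 0
  }
  conformers$clash <- clash
  conformers$min_margin <- margin
  conformers$threshold <- threshold
  conformers$survival_fraction <- mean(!clash)
  conformers
}

#' All-pairs clash oracle
#'
#' Brute-force version of [clash_filter()] with no spatial prefilter; used to
#' verify the filter's correctness.
#'
#' @inheritParams clash_filter
#' @return Logical clash vector.
#' @export
clash_filter_allpairs <- function(conformers, structure = conformers$structure,
                                  threshold = 0.3) {
  a <- structure$atoms
  B <- as.matrix(a[!a$domain, c("x", "y", "z")])
  rb <- a$radius[!a$domain]
  rd <- a$radius[a$domain]
  n <- dim(conformers$coords)[3]
  vapply(seq_len(n), function(i) {
    D <- matrix(conformers$coords[, , i], ncol = 3)
    d <- sqrt(outer(rowSums(D^2), rowSums(B^2), "+") - 2 * (D %*% t(B)))
    any(d < outer(rd, rb, "+") - threshold)
  }, logical(1))
}

#' Accessible-volume dye cloud at an attachment site
#'
#' Geometric accessible-volume model: candidate dye positions on a cubic grid
#' within the linker length of the attachment atom are kept if the dye sphere
#' does not overlap any protein atom and the straight linker path retains a
#' clearance of half the linker width (checked at sampled points along the
#' segment). The grid spacing is auto-tuned so the cloud holds a target
#' number of positions (default 600-1200).
#'
#' @param structure A `fret_structure`, or a data frame / matrix of atom
#'   coordinates with radii.
#' @param attachment_site Atom index, or a site name from the structure's
#'   `sites`.
#' @param linker_length Maximum dye-to-attachment distance (Angstrom,
#'   default 20).
#' @param linker_width Linker diameter (Angstrom, default 4.5); half of it is
#'   the clearance required along the path.
#' @param dye_radius Dye sphere radius (Angstrom, default 3.5).
#' @param grid_spacing Fixed grid spacing; `NULL` (default) auto-tunes.
#' @param target_points Acceptable cloud size range for auto-tuning.
#' @param domain_coords Optional replacement domain coordinates (one
#'   conformer).
#' @return A `dye_cloud`: `positions` (m x 3), `attachment` (coordinates),
#'   `spacing`, parameters; an empty cloud carries `occluded = TRUE`.
#' @export
accessible_volume <- function(structure, attachment_site, linker_length = 20,
                              linker_width = 4.5, dye_radius = 3.5,
                              grid_spacing = NULL,
                              target_points = c(600, 1200),
                              domain_coords = NULL) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!is.null(domain_coords)) xyz[a$domain, ] <- domain_coords
  if (is.character(attachment_site)) {
    attachment_site <- structure$sites[[attachment_site]]
    if (is.null(attachment_site)) stop("unknown site name")
  }
  stopifnot(attachment_site >= 1, attachment_site <= nrow(xyz))
  att <- xyz[attachment_site, ]
  other <- xyz[-attachment_site, , drop = FALSE]
  rad <- a$radius[-attachment_site]
  cloud_at <- function(s) {
    g <- seq(-linker_length, linker_length, by = s)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- pts[rowSums(pts^2) <= linker_length^2, , drop = FALSE]
    pts <- sweep(pts, 2, att, "+")
    if (!nrow(other)) return(pts)
    free <- function(P, clearance) {
      d2 <- outer(rowSums(P^2), rowSums(other^2), "+") - 2 * (P %*% t(other))
      lim <- (rad + clearance)^2
      rowSums(sweep(d2, 2, lim, "<")) == 0
    }
    ok <- free(pts, dye_radius)
    pts <- pts[ok, , drop = FALSE]
    if (!nrow(pts)) return(pts)
    # straight-path clearance at two interior points of the linker segment
    for (f in c(1 / 3, 2 / 3)) {
      mid <- sweep(pts * f, 2, att * (1 - f), "+")
      keep <- free(mid, linker_width / 2)
      pts <- pts[keep, , drop = FALSE]
      if (!nrow(pts)) break
    }
    pts
  }
  if (!is.null(grid_spacing)) {
    pos <- cloud_at(grid_spacing)
    s <- grid_spacing
  } else {
    s <- linker_length / 6
    pos <- cloud_at(s)
    for (it in 1:8) {
      n <- nrow(pos)
      if (n >= target_points[1] && n <= target_points[2]) break
      scale <- ((max(n, 1)) / mean(target_points))^(1 / 3)
      s <- s * scale
      pos <- cloud_at(s)
    }
  }
  out <- list(positions = pos, attachment = att, spacing = s,
              linker_length = linker_length, linker_width = linker_width,
              dye_radius = dye_radius, occluded = nrow(pos) == 0)
  class(out) <- "dye_cloud"
  if (out$occluded) warning("attachment site fully occluded: empty dye cloud")
  out
}

#' Cloud-averaged FRET efficiency of a dye pair
#'
#' The model efficiency of a pair is the mean over all donor x acceptor
#' position combinations of `1 / (1 + (r / R0)^6)` (position averaging, the
#' isotropic-dye assumption with kappa^2 = 2/3 folded into R0). The mean is
#' exact unless the pair count exceeds `max_pairs`, in which case a seeded
#' random subsample is used (standard error about `0.3 / sqrt(max_pairs)`,
#' far below the measurement uncertainty).
#'
#' @param donor_cloud,acceptor_cloud `dye_cloud` objects (non-empty).
#' @param R0 Forster radius for the pair (Angstrom).
#' @param max_pairs Exact-evaluation bound (default 4e6 pairs).
#' @param seed Seed for subsampling.
#' @return Mean FRET efficiency (scalar).
#' @export
predict_pair_efficiency <- function(donor_cloud, acceptor_cloud, R0,
                                    max_pairs = 4e6, seed = 1) {
  stopifnot(R0 > 0)
  D <- donor_cloud$positions
  A <- acceptor_cloud$positions
  if (!nrow(D) || !nrow(A)) stop("empty dye cloud: cannot predict efficiency")
  nD <- nrow(D); nA <- nrow(A)
  if (as.numeric(nD) * nA <= max_pairs) {
    d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * (D %*% t(A))
    d2[d2 < 0] <- 0
    return(mean(1 / (1 + (d2 / R0^2)^3)))
  }
  withr::with_seed(seed, {
    i <- sample.int(nD, max_pairs, replace = TRUE)
    j <- sample.int(nA, max_pairs, replace = TRUE)
    d2 <- rowSums((D[i, , drop = FALSE] - A[j, , drop = FALSE])^2)
    mean(1 / (1 + (d2 / R0^2)^3))
  })
}

#' Rank conformers against measured efficiencies by chi-square
#'
#' For each conformer with model efficiencies for all pairs, computes
#' `chi2 = sum_i (E_measured(i) - E_model(i))^2` per measured-state vector,
#' sorts ascending with stable (chi2, index) tie-breaking, and returns the
#' `top_m` set per state.
#'
#' @param E_model Matrix of predicted efficiencies, conformers x pairs; rows
#'   with any `NA` are excluded with a notice.
#' @param E_measured Numeric vector (one state) or matrix states x pairs.
#' @param top_m Size of the selected set (default 10).
#' @return A `chi2_ranking` list: per state, a data frame `conformer`,
#'   `chi2` sorted ascending, and `top` (the first `top_m` conformer ids).
#' @export
rank_conformers <- function(E_model, E_measured, top_m = 10) {
  E_model <- as.matrix(E_model)
  if (is.null(dim(E_measured))) E_measured <- matrix(E_measured, nrow = 1)
  stopifnot(ncol(E_model) == ncol(E_measured))
  ok <- rowSums(is.na(E_model)) == 0
  if (!all(ok)) {
    message(sum(!ok), " conformer(s) lacking pair predictions excluded from ranking")
  }
  ids <- which(ok)
  out <- lapply(seq_len(nrow(E_measured)), function(s) {
    chi2 <- colSums((t(E_model[ids, , drop = FALSE]) - E_measured[s, ])^2)
    ord <- order(chi2, ids)   # stable: ties broken by conformer index
    rank <- data.frame(conformer = ids[ord], chi2 = chi2[ord])
    list(ranking = rank, top = head(rank$conformer, top_m))
  })
  names(out) <- rownames(E_measured) %||% paste0("state", seq_along(out))
  structure(list(states = out, top_m = top_m), class = "chi2_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate RMSD between a conformer and a reference domain
#'
#' Plain root-mean-square deviation over matched domain atoms in the shared
#' body frame — no superposition, since all conformers live in the fixed
#' frame of the body.
#'
#' @param conformer_coords,reference_coords Matched coordinate matrices
#'   (n x 3).
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(conformer_coords, reference_coords) {
  conformer_coords <- as.matrix(conformer_coords)
  reference_coords <- as.matrix(reference_coords)
  if (!all(dim(conformer_coords) == dim(reference_coords))) {
    stop("atom sets differ: ", nrow(conformer_coords), " vs ",
         nrow(reference_coords), " atoms")
  }
  sqrt(mean(rowSums((conformer_coords - reference_coords)^2)))
}

#' Tilt angle between a conformer's domain axis and a reference
#'
#' The domain axis is the first principal axis of the domain coordinates;
#' the tilt is the angle between the conformer's and the reference's axes,
#' folded into \[0, 90\] degrees (principal axes are sign-free). A domain
#' with no dominant axis (near-spherical) is flagged.
#'
#' @param conformer_coords,reference_coords Domain coordinate matrices.
#' @return Angle in degrees; attribute `degenerate` marks an ill-defined
#'   axis.
#' @export
tilt_angle <- function(conformer_coords, reference_coords) {
  axis_of <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) < 2) stop("need at least 2 atoms to define a domain axis")
    sv <- svd(sweep(M, 2, colMeans(M)))
    list(v = sv$v[, 1], degenerate = sv$d[1] < 1.5 * sv$d[min(2, length(sv$d))])
  }
  a1 <- axis_of(conformer_coords)
  a2 <- axis_of(reference_coords)
  ang <- acos(pmin(1, abs(sum(a1$v * a2$v)))) * 180 / pi
  attr(ang, "degenerate") <- a1$degenerate || a2$degenerate
  if (a1$degenerate || a2$degenerate) {
    warning("domain axis is ill-defined (near-degenerate principal axes)")
  }
  ang
}

#' FRET-restrained rigid-body triangulation pipeline
#'
#' End-to-end scheme: generate the rotation grid, filter steric clashes,
#' build accessible-volume dye clouds for every pair site on each surviving
#' conformer, predict the cloud-averaged pair efficiencies, and rank the
#' conformers against the measured per-state efficiencies.
#'
#' @param structure A `fret_structure` with `sites` and an attached `pairs`
#'   attribute (or supply `pairs`).
#' @param E_measured Vector or states x pairs matrix of measured
#'   efficiencies.
#' @param R0 Forster radius per pair (recycled if scalar).
#' @param pairs List of site-name pairs; defaults to `attr(structure,
#'   "pairs")`.
#' @param grid_points_per_axis Euler grid resolution.
#' @param top_m Selected set size.
#' @param av_params List of [accessible_volume()] arguments (linker_length,
#'   linker_width, dye_radius, target_points).
#' @param ... Passed to [generate_conformers()] (angle ranges).
#' @return List: `conformers` (clash-annotated set), `E_model` (matrix over
#'   all conformers; NA for clashing ones), `ranking` (a `chi2_ranking`),
#'   `survival_fraction`.
#' @export
triangulate <- function(structure, E_measured, R0, pairs = NULL,
                        grid_points_per_axis = 25, top_m = 10,
                        av_params = list(), ...) {
  pairs <- pairs %||% attr(structure, "pairs")
  if (is.null(pairs)) stop("no FRET pairs supplied")
  R0 <- rep(R0, length.out = length(pairs))
  conf <- generate_conformers(structure, grid_points_per_axis, ...)
  conf <- clash_filter(conf)
  surv <- which(!conf$clash)
  site_names <- unique(unlist(pairs))
  av_call <- function(site, dcoords) {
    do.call(accessible_volume,
            c(list(structure = structure, attachment_site = site,
                   domain_coords = dcoords), av_params))
  }
  n_conf <- dim(conf$coords)[3]
  E_model <- matrix(NA_real_, n_conf, length(pairs))
  domain_sites <- site_names[structure$atoms$domain[structure$sites[site_names]]]
  body_sites <- setdiff(site_names, domain_sites)
  for (i in surv) {
    dc <- matrix(conf$coords[, , i], ncol = 3)
    clouds <- lapply(setNames(site_names, site_names), av_call, dcoords = dc)
    if (any(vapply(clouds, `[[`, logical(1), "occluded"))) next
    E_model[i, ] <- vapply(seq_along(pairs), function(p) {
      predict_pair_efficiency(clouds[[pairs[[p]][1]]],
                              clouds[[pairs[[p]][2]]], R0[p])
    }, numeric(1))
  }
  ranking <- rank_conformers(E_model, E_measured, top_m = top_m)
  list(conformers = conf, E_model = E_model, ranking = ranking,
       survival_fraction = conf$survival_fraction)
}
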