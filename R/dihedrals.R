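#' Signed dihedral (torsion) angle of four atoms
#'
#' Returns the torsion a-b-c-d in degrees, in (-180, 180], using the
#' IUPAC sign convention (viewing down the b->c axis, a clockwise
#' rotation of d relative to a is positive). Invariant under rigid
#' rotation and translation of the frame.
#'
#' @param frame a frame (list with `coords` matrix) from
#'   [read_xyz_trajectory()], or an n x 3 coordinate matrix
#' @param atoms four distinct 1-based atom indices `c(a, b, c, d)`
#' @return angle in degrees
#' @export
dihedral <- function(frame, atoms) {
  coords <- if (is.matrix(frame)) frame else frame$coords
  if (length(atoms) != 4L || anyDuplicated(atoms))
    stop("`atoms` must be four distinct indices")
  if (any(atoms < 1L | atoms > nrow(coords)))
    stop("atom index out of range")
  p <- coords[atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear atoms in dihedral")
  m1 <- cross3(n1, b2 / nb2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral specification for azobenzene-style torsions
#'
#' @param atoms four 1-based atom indices
#' @param label one of `"psi"` (C-N=N-C torsion around the diazene
#'   bond), `"phi1"`/`"phi2"` (C_ortho-C_ipso-N=N torsion around each
#'   C-N bond), or `"custom"`
#' @export
dihedral_spec <- function(atoms, label = c("custom", "psi", "phi1", "phi2")) {
  label <- match.arg(label)
  if (length(atoms) != 4L || anyDuplicated(atoms) || any(atoms < 1L))
    stop("a dihedral spec needs four distinct positive indices")
  structure(list(atoms = as.integer(atoms), label = label),
            class = "dihedral_spec")
}

#' Locate the psi / phi dihedrals of an azobenzene-like frame
#'
#' Convenience auto-detection for azobenzene scaffolds: finds the N=N
#' pair (two nitrogens closer than 1.4 Angstrom), the ipso carbon bonded
#' to each nitrogen, and one ortho carbon on each ring. Returns specs
#' for psi (C_ipso-N=N-C_ipso) and phi1/phi2 (C_ortho-C_ipso-N=N).
#' Explicit specs should be preferred whenever the topology is known.
#'
#' @param frame a frame with `symbols` and `coords`
#' @return named list of [dihedral_spec()]: `psi`, `phi1`, `phi2`
#' @export
detect_azo_dihedrals <- function(frame) {
  sym <- frame$symbols
  xyz <- frame$coords
  n_idx <- which(sym == "N")
  if (length(n_idx) < 2L) stop("no N=N unit found (need two nitrogens)")
  dist <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  nn <- NULL
  for (i in n_idx) for (j in n_idx) if (i < j && dist(i, j) < 1.4) nn <- c(i, j)
  if (is.null(nn)) stop("no N=N bond (< 1.4 Angstrom) among nitrogens")
  ipso_of <- function(n) {
    cs <- which(sym == "C")
    d <- vapply(cs, dist, 0, i = n)
    cand <- cs[d < 1.6]
    if (length(cand) == 0L) stop("no ipso carbon bonded to N", n)
    cand[which.min(d[d < 1.6])]
  }
  c1 <- ipso_of(nn[1]); c2 <- ipso_of(nn[2])
  ortho_of <- function(ipso, exclude) {
    cs <- setdiff(which(sym == "C"), c(ipso, exclude))
    d <- vapply(cs, dist, 0, i = ipso)
    cand <- cs[d < 1.6]
    if (length(cand) == 0L) stop("no ortho carbon bonded to C", ipso)
    cand[1]
  }
  o1 <- ortho_of(c1, c2); o2 <- ortho_of(c2, c1)
  list(
    psi  = dihedral_spec(c(c1, nn[1], nn[2], c2), "psi"),
    phi1 = dihedral_spec(c(o1, c1, nn[1], nn[2]), "phi1"),
    phi2 = dihedral_spec(c(o2, c2, nn[2], nn[1]), "phi2")
  )
}

#' Per-frame dihedral feature table
#'
#' Evaluates the given dihedral specs on every frame and appends the
#' cosine transforms the flexibility analysis uses: `cos_psi` for the
#' central torsion and, for the ring torsions, both `abs_cos_*`
#' (|cos phi| = 1 for a planar ring with the C_ortho-C_ipso-N=N
#' definition) and `abs_sin_*` (the complementary convention in which
#' planarity maps to 0). Angles are reported in degrees.
#'
#' @param frames list of frames
#' @param specs named list of [dihedral_spec()] (e.g. from
#'   [detect_azo_dihedrals()]); names become column prefixes
#' @return data.frame, one row per frame: `frame_index`, `<name>_deg`
#'   per spec, plus transform columns for specs labelled/named psi/phi
#' @export
feature_table <- function(frames, specs) {
  if (length(frames) == 0L) stop("no frames")
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    stop("`specs` must be a named list")
  rows <- lapply(frames, function(fr) {
    ang <- vapply(names(specs), function(nm) {
      tryCatch(dihedral(fr, specs[[nm]]$atoms),
               error = function(e) stop("frame ", fr$frame_index, ": ",
                                        conditionMessage(e)))
    }, 0)
    ang
  })
  ang_mat <- do.call(rbind, rows)
  out <- data.frame(frame_index = vapply(frames, `[[`, 0L, "frame_index"))
  for (nm in names(specs)) {
    a <- ang_mat[, nm]
    out[[paste0(nm, "_deg")]] <- a
    if (grepl("psi", nm)) {
      out[[paste0("cos_", nm)]] <- cos(a * pi / 180)
    } else if (grepl("phi", nm)) {
      out[[paste0("abs_cos_", nm)]] <- abs(cos(a * pi / 180))
      out[[paste0("abs_sin_", nm)]] <- abs(sin(a * pi / 180))
    }
  }
  out
}

#' Circular mean of angles in degrees
#'
#' @param deg angles in degrees
#' @return mean direction in (-180, 180]
#' @export
circular_mean_deg <- function(deg) {
  r <- deg * pi / 180
  m <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (m <= -180) m + 360 else m
}
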