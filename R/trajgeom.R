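#' Dihedral angle of four points
#'
#' Signed torsion about the p2-p3 axis in the IUPAC convention
#' (cis = 0, trans = 180), returned in degrees on (-180, 180]. Accepts
#' four length-3 vectors or four n-by-3 matrices (vectorized over rows).
#'
#' @param p1,p2,p3,p4 3-D points (length-3 numeric or n x 3 matrices).
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (any(rowSums(b1^2) == 0) || any(rowSums(b2^2) == 0) || any(rowSums(b3^2) == 0)) {
    abort("dihedral_angle: consecutive points coincide")
  }
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (any(rowSums(n1^2) < 1e-20) || any(rowSums(n2^2) < 1e-20)) {
    abort("dihedral_angle: collinear atom triple")
  }
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2)  # = (n1 x n2) . b2hat, the IUPAC sign
  ang <- atan2(y, x) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

# chi1 terminal atom (N-CA-CB-X) for the 18 chi1-bearing residue types
CHI1_GAMMA <- c(R = "CG", N = "CG", D = "CG", C = "SG", Q = "CG", E = "CG",
                H = "CG", I = "CG1", L = "CG", K = "CG", M = "CG", F = "CG",
                P = "CG", S = "OG", T = "OG1", W = "CG", Y = "CG", V = "CG1")

#' chi1 atom names for a residue type
#'
#' @param aa One-letter code; Ala and Gly have no chi1 and are rejected.
#' @return Character vector `c("N", "CA", "CB", <gamma atom>)`.
#' @export
#' @examples
#' chi1_atoms("I")  # N CA CB CG1
chi1_atoms <- function(aa) {
  if (!(aa %in% names(CHI1_GAMMA))) {
    abort(sprintf("chi1_atoms: residue type '%s' has no chi1 torsion", aa))
  }
  c("N", "CA", "CB", unname(CHI1_GAMMA[[aa]]))
}

# coordinates of one named atom across frames, as a frames x 3 matrix
atom_coords <- function(frames, residue, atom) {
  sel <- frames[frames$residue == residue & frames$atom == atom, ]
  if (nrow(sel) == 0) {
    abort(sprintf("atom not found: residue %s atom %s", residue, atom))
  }
  sel <- arrange(sel, .data$frame)
  cbind(sel$x, sel$y, sel$z)
}

#' Per-frame chi1 torsion series
#'
#' @param frames Tidy frame table `(frame, residue, atom, x, y, z)`.
#' @param residue Residue index.
#' @param aa Residue one-letter code (selects the gamma atom).
#' @return Tibble `(frame, chi1)` in degrees.
#' @export
chi1_series <- function(frames, residue, aa) {
  atoms <- chi1_atoms(aa)
  ps <- lapply(atoms, function(a) atom_coords(frames, residue, a))
  tibble(frame = sort(unique(frames$frame)),
         chi1 = dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]))
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`; unit masses unless a
#' `mass` column is present and `mass_weighted = TRUE`.
#'
#' @param frames Tidy frame table `(frame, residue, atom, x, y, z[, mass])`.
#' @param mass_weighted Use the `mass` column if present.
#' @return Tibble `(frame, rg)` in the coordinate units (Angstrom).
#' @export
radius_of_gyration <- function(frames, mass_weighted = TRUE) {
  require_columns(frames, c("frame", "x", "y", "z"), "frames")
  m_all <- if (mass_weighted && "mass" %in% names(frames)) frames$mass else rep(1, nrow(frames))
  if (any(!is.finite(m_all)) || any(m_all < 0)) abort("radius_of_gyration: invalid masses")
  rows <- lapply(split(seq_len(nrow(frames)), frames$frame), function(idx) {
    m <- m_all[idx]
    if (sum(m) <= 0) abort("radius_of_gyration: zero total mass")
    xyz <- cbind(frames$x[idx], frames$y[idx], frames$z[idx])
    com <- colSums(xyz * m) / sum(m)
    d2 <- rowSums(sweep(xyz, 2, com)^2)
    tibble(frame = frames$frame[idx][1], rg = sqrt(sum(m * d2) / sum(m)))
  })
  arrange(bind_rows(rows), .data$frame)
}

#' Distance between a selection's center of mass and an atom, per frame
#'
#' @param frames Tidy frame table.
#' @param selection Data frame `(residue, atom)` naming the atoms whose
#'   mass-weighted center of mass is taken (nonempty).
#' @param target List or one-row data frame with `residue` and `atom`.
#' @return Tibble `(frame, distance)` in Angstrom.
#' @export
com_distance <- function(frames, selection, target) {
  require_columns(selection, c("residue", "atom"), "selection")
  if (nrow(selection) == 0) abort("com_distance: empty selection")
  coords <- lapply(seq_len(nrow(selection)), function(i) {
    atom_coords(frames, selection$residue[i], selection$atom[i])
  })
  masses <- if ("mass" %in% names(selection)) selection$mass else rep(1, nrow(selection))
  com <- Reduce(`+`, Map(function(p, m) p * m, coords, masses)) / sum(masses)
  tb <- atom_coords(frames, target$residue, target$atom)
  tibble(frame = sort(unique(frames$frame)),
         distance = sqrt(rowSums((com - tb)^2)))
}

#' Hydrogen-bond occupancy by a distance criterion
#'
#' Fraction of frames in which the donor-acceptor distance is at or below
#' the cutoff (3.5 Angstrom by default). Distance-only criterion, no
#' angle term; whether the donor is the heavy atom or its proton is the
#' caller's choice of atom name.
#'
#' @param frames Tidy frame table.
#' @param donor,acceptor Lists or one-row data frames with `residue` and
#'   `atom`.
#' @param cutoff Angstrom.
#' @return A list: `occupancy` in `[0, 1]` and `distances` tibble
#'   `(frame, distance, bonded)`.
#' @export
hbond_occupancy <- function(frames, donor, acceptor, cutoff = 3.5) {
  if (nrow(frames) == 0) abort("hbond_occupancy: empty frame series")
  pd <- atom_coords(frames, donor$residue, donor$atom)
  pa <- atom_coords(frames, acceptor$residue, acceptor$atom)
  d <- sqrt(rowSums((pd - pa)^2))
  bonded <- d <= cutoff
  list(occupancy = mean(bonded),
       distances = tibble(frame = sort(unique(frames$frame)),
                          distance = d, bonded = bonded))
}

circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Assign rotamer states to a dihedral series and count transitions
#'
#' Each frame is assigned to the nearest state center on the circle
#' (wrap-aware) when within `tolerance` degrees, otherwise left
#' unassigned (`NA`). Transitions are counted between successive assigned
#' frames with different states.
#'
#' @param angles Per-frame dihedral values in degrees.
#' @param states Distinct state centers in degrees; their tolerance
#'   windows must not overlap on the circle.
#' @param tolerance Half-width of each state window, degrees.
#' @return A list: `labels` (state center per frame, `NA` if unassigned),
#'   `transitions` (count), `occupancy` (named fractions of assigned
#'   frames per state).
#' @export
#' @examples
#' s <- switch_detect(c(-70, -178, -69, 179), states = c(-70, -180), tolerance = 30)
#' s$transitions  # 3
switch_detect <- function(angles, states, tolerance) {
  if (length(states) < 2) abort("switch_detect: need >= 2 state centers")
  for (i in seq_along(states)) {
    for (j in seq_along(states)) {
      if (i < j && abs(circ_diff(states[i], states[j])) <= 2 * tolerance) {
        abort("switch_detect: overlapping state windows")
      }
    }
  }
  dmat <- sapply(states, function(s) abs(circ_diff(angles, s)))
  dmat <- matrix(dmat, nrow = length(angles))
  nearest <- max.col(-dmat, ties.method = "first")
  within <- dmat[cbind(seq_along(angles), nearest)] <= tolerance
  labels <- ifelse(within, states[nearest], NA_real_)
  assigned <- labels[!is.na(labels)]
  transitions <- if (length(assigned) >= 2) sum(diff(match(assigned, states)) != 0) else 0L
  occ <- if (length(assigned) > 0) {
    table(factor(assigned, levels = states)) / length(assigned)
  } else {
    setNames(rep(NA_real_, length(states)), states)
  }
  list(labels = labels, transitions = transitions,
       occupancy = setNames(as.numeric(occ), states))
}

#' Read coordinate frames from multi-model PDB or a whitespace table
#'
#' PDB input uses MODEL/ENDMDL records (standard atom-name columns, via
#' bio3d); the plain-table dialect has whitespace-separated columns
#' `frame residue atom x y z`, with an optional header line.
#'
#' @param path File path; format inferred from the `.pdb` extension
#'   unless given.
#' @param format `"auto"`, `"pdb"` or `"table"`.
#' @return Tidy tibble `(frame, residue, atom, x, y, z)`.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("frames file not found: %s", path))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "pdb") "pdb" else "table"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    n_atoms <- nrow(pdb$atom)
    frames <- lapply(seq_len(nrow(xyz)), function(f) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      tibble(frame = f, residue = as.integer(pdb$atom$resno),
             atom = pdb$atom$elety, x = m[, 1], y = m[, 2], z = m[, 3])
    })
    return(bind_rows(frames))
  }
  first <- readLines(path, n = 1)
  has_header <- grepl("frame", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header,
                          col.names = c("frame", "residue", "atom", "x", "y", "z"))
  as_tibble(df) |>
    mutate(frame = as.integer(.data$frame), residue = as.integer(.data$residue),
           atom = as.character(.data$atom))
}
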