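#' @importFrom stats fft sd lm coef var rnorm runif rbinom rgeom aggregate
#' @importFrom utils read.table write.table head tail packageVersion
NULL

# Residue names treated as water when classifying atoms.
.default_water_residues <- c("HOH", "SOL", "WAT")

#' Construct a molecular trajectory
#'
#' A trajectory bundles an atom table with a frames x atoms x 3 coordinate
#' array.  Units are fixed package-wide: coordinates in Angstrom, velocities
#' in Angstrom/ps, time in ps, spectra in cm^-1.  Readers convert on
#' ingestion (GRO nm are multiplied by 10).
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{resno}, \code{resname}, and optionally \code{chain}.  A
#'   \code{category} column (\code{protein} / \code{water} / \code{other})
#'   is derived from \code{resname} if absent.
#' @param coords numeric array of dimension \code{c(n_frames, n_atoms, 3)}
#'   in Angstrom.  A single frame may be given as an \code{n_atoms x 3}
#'   matrix.
#' @param dt frame spacing in ps; must be a single positive number.
#' @param velocities optional array with the same dimensions as
#'   \code{coords}, in Angstrom/ps.
#' @param box optional length-3 numeric, orthorhombic box edges in
#'   Angstrom.  When present, minimum-image distances are used for shell
#'   selection.
#' @param water_residues residue names classified as water.
#' @param velocities_derived logical flag marking velocities obtained by
#'   numerical differentiation rather than stored by the source.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(atoms, coords, dt, velocities = NULL, box = NULL,
                       water_residues = .default_water_residues,
                       velocities_derived = FALSE) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.data.frame(atoms)) stop("'atoms' must be a data.frame")
  req <- c("name", "element", "resno", "resname")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(atoms) != dim(coords)[2]) {
    stop("atom table has ", nrow(atoms), " rows but coords has ",
         dim(coords)[2], " atoms")
  }
  if (any(!nzchar(atoms$element))) stop("every atom needs an element symbol")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number (ps)")
  }
  if (!is.null(velocities)) {
    if (!identical(dim(velocities), dim(coords))) {
      stop("velocities must have the same dimensions as coords")
    }
  }
  if (!is.null(box)) {
    stopifnot(is.numeric(box), length(box) == 3L, all(box > 0))
  }
  if (is.null(atoms$chain)) atoms$chain <- "A"
  atoms$category <- ifelse(atoms$resname %in% water_residues, "water",
                    ifelse(atoms$resname %in% .amino_acids, "protein",
                           "other"))
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, coords = coords, velocities = velocities,
         dt = dt, box = box, derived_velocities = isTRUE(velocities_derived)),
    class = "trajectory")
}

.amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HSD", "HSE", "HSP", "CYX", "HID", "HIE", "HIP")

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory:", d[1], "frames x", d[2], "atoms, dt =", x$dt, "ps\n")
  cat("  categories:",
      paste(names(table(x$atoms$category)), table(x$atoms$category),
            sep = ":", collapse = "  "), "\n")
  cat("  velocities:",
      if (is.null(x$velocities)) "absent"
      else if (x$derived_velocities) "derived (finite differences)"
      else "stored", "\n")
  if (!is.null(x$box)) {
    cat("  box (A):", paste(signif(x$box, 6), collapse = " x "), "\n")
  }
  invisible(x)
}

#' @export
#' @rdname trajectory
n_frames <- function(traj) dim(traj$coords)[1]

#' @export
#' @rdname trajectory
n_atoms <- function(traj) dim(traj$coords)[2]

# ---------------------------------------------------------------------------
# Reading / writing

#' Read a trajectory from a multi-model PDB or a concatenated GRO series
#'
#' PDB files are parsed with \pkg{bio3d} (\code{MODEL}/\code{ENDMDL}
#' delimited frames); GRO files are parsed natively, with nm converted to
#' Angstrom on ingestion (x10) and any velocity columns converted to
#' Angstrom/ps.  Neither format encodes a reliable frame spacing, so
#' \code{dt} must be supplied explicitly: a silent default would corrupt
#' every downstream frequency axis.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"gro"}, or \code{"auto"} (by file
#'   extension).
#' @param dt frame spacing in ps (required).
#' @param water_residues residue names classified as water.
#' @return a \code{\link{trajectory}}.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "gro"), dt = NULL,
                            water_residues = .default_water_residues) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (is.null(dt)) {
    stop("'dt' (frame spacing in ps) must be supplied; ", format,
         " files do not encode it")
  }
  if (format == "pdb") .read_pdb_traj(path, dt, water_residues)
  else .read_gro_traj(path, dt, water_residues)
}

.read_pdb_traj <- function(path, dt, water_residues) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3L), drop = FALSE]
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- .element_from_name(at$elety)
  } else {
    elem <- trimws(elem)
    blank <- is.na(elem) | !nzchar(elem)
    elem[blank] <- .element_from_name(at$elety[blank])
  }
  atoms <- data.frame(name = trimws(at$elety), element = elem,
                      resno = at$resno, resname = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      stringsAsFactors = FALSE)
  trajectory(atoms, coords, dt, water_residues = water_residues)
}

# First alphabetic character of an atom name, ignoring leading digits;
# two-letter guesses are not attempted (H/C/N/O/S/P cover MD systems).
.element_from_name <- function(name) {
  stripped <- sub("^[0-9]*", "", trimws(name))
  toupper(substr(stripped, 1, 1))
}

.read_gro_traj <- function(path, dt, water_residues) {
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  i <- 1L
  nfr <- 0L
  has_vel <- FALSE
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat <= 0) {
      stop("bad atom count at GRO line ", i + 1L)
    }
    nfr <- nfr + 1L
    if (i + 1L + nat + 1L > length(lines)) {
      stop("frame ", nfr, " truncated: expected ", nat, " atom lines")
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    parsed <- .parse_gro_block(block, nfr)
    if (is.null(atoms)) {
      atoms <- parsed$atoms
      has_vel <- parsed$has_vel
    } else if (nrow(parsed$atoms) != nrow(atoms)) {
      stop("frame ", nfr, " has ", nrow(parsed$atoms),
           " atoms; frame 1 has ", nrow(atoms))
    }
    boxline <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i + 1L + nat + 1L]), "\\s+")[[1]]))
    parsed$box <- if (length(boxline) >= 3 && !anyNA(boxline[1:3])) {
      boxline[1:3]
    } else NULL
    frames[[nfr]] <- parsed
    i <- i + 1L + nat + 2L          # title + count + atoms + box line
  }
  if (nfr == 0L) stop("no frames found in ", path)
  na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(nfr, na, 3L))
  vels <- if (has_vel) array(NA_real_, dim = c(nfr, na, 3L)) else NULL
  for (f in seq_len(nfr)) {
    coords[f, , ] <- frames[[f]]$xyz * 10            # nm -> Angstrom
    if (has_vel) vels[f, , ] <- frames[[f]]$vel * 10 # nm/ps -> Angstrom/ps
  }
  box <- frames[[nfr]]$box
  box <- if (!is.null(box) && all(is.finite(box)) && all(box > 0)) box * 10 else NULL
  trajectory(atoms, coords, dt, velocities = vels, box = box,
             water_residues = water_residues)
}

.parse_gro_block <- function(block, frame_id) {
  # fixed-width: resno(5) resname(5) name(5) serial(5) x y z [vx vy vz] %8.3f
  resno <- as.integer(substr(block, 1, 5))
  resname <- trimws(substr(block, 6, 10))
  name <- trimws(substr(block, 11, 15))
  rest <- substr(block, 21, nchar(block))
  nums <- lapply(strsplit(trimws(rest), "\\s+"), as.numeric)
  nn <- lengths(nums)
  if (any(nn != nn[1])) {
    stop("frame ", frame_id, ": inconsistent numeric columns in GRO block")
  }
  if (!nn[1] %in% c(3L, 6L)) {
    stop("frame ", frame_id, ": expected 3 or 6 numeric columns, got ", nn[1])
  }
  m <- do.call(rbind, nums)
  if (any(is.na(resno)) || any(is.na(m))) {
    stop("frame ", frame_id, ": unparseable GRO atom line")
  }
  list(atoms = data.frame(name = name,
                          element = .element_from_name(name),
                          resno = resno, resname = resname,
                          chain = "A", stringsAsFactors = FALSE),
       xyz = m[, 1:3, drop = FALSE],
       vel = if (nn[1] == 6L) m[, 4:6, drop = FALSE] else NULL,
       has_vel = nn[1] == 6L,
       box = NULL)
}

#' Write a trajectory to disk as a fixture file
#'
#' PDB output stores coordinates at 3 decimals (round-trip error at most
#' 5e-4 Angstrom); GRO output stores nm at 3 decimals (5e-4 nm = 5e-3
#' Angstrom) plus velocities at 4 decimals when present.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"gro"}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "gro")) {
  format <- match.arg(format)
  if (format == "pdb") {
    nf <- n_frames(traj)
    na <- n_atoms(traj)
    xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * na)
    for (k in 1:3) xyz[, seq(k, 3L * na, by = 3L)] <- traj$coords[, , k]
    bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                     resno = traj$atoms$resno,
                     resid = traj$atoms$resname,
                     eleno = seq_len(na),
                     elety = traj$atoms$name,
                     chain = traj$atoms$chain,
                     elesy = traj$atoms$element)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    has_vel <- !is.null(traj$velocities)
    box_nm <- if (!is.null(traj$box)) traj$box / 10 else c(0, 0, 0)
    for (f in seq_len(n_frames(traj))) {
      writeLines(sprintf("frame %d, t= %.4f", f, (f - 1) * traj$dt), con)
      writeLines(sprintf("%5d", n_atoms(traj)), con)
      for (a in seq_len(n_atoms(traj))) {
        xyz_nm <- traj$coords[f, a, ] / 10
        base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                        traj$atoms$resno[a], traj$atoms$resname[a],
                        traj$atoms$name[a], ((a - 1L) %% 99999L) + 1L,
                        xyz_nm[1], xyz_nm[2], xyz_nm[3])
        if (has_vel) {
          v_nm <- traj$velocities[f, a, ] / 10
          base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                       v_nm[1], v_nm[2], v_nm[3]))
        }
        writeLines(base, con)
      }
      writeLines(sprintf("%10.5f%10.5f%10.5f",
                         box_nm[1], box_nm[2], box_nm[3]), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection

#' Select atom indices from a trajectory
#'
#' @param traj a \code{\link{trajectory}}.
#' @param query one of \code{"protein"}, \code{"backbone"} (N, CA, C, O),
#'   \code{"calpha"}, \code{"water-oxygen"}, \code{"residue-range"},
#'   \code{"named-atoms"}.
#' @param resno_range length-2 integer vector for \code{"residue-range"}
#'   (inclusive); may also be combined with \code{atom_names}.
#' @param atom_names character vector of atom names for
#'   \code{"named-atoms"} (or to restrict a residue range).
#' @return sorted unique 1-based atom indices; an empty selection is an
#'   error so zero-length analyses never pass silently.
#' @export
select_atoms <- function(traj, query = c("protein", "backbone", "calpha",
                                         "water-oxygen", "residue-range",
                                         "named-atoms"),
                         resno_range = NULL, atom_names = NULL) {
  query <- match.arg(query)
  at <- traj$atoms
  idx <- switch(query,
    "protein" = which(at$category == "protein"),
    "backbone" = which(at$category == "protein" &
                       at$name %in% c("N", "CA", "C", "O")),
    "calpha" = which(at$category == "protein" & at$name == "CA"),
    "water-oxygen" = which(at$category == "water" & at$element == "O"),
    "residue-range" = {
      if (is.null(resno_range) || length(resno_range) != 2L) {
        stop("residue-range query needs resno_range = c(lo, hi)")
      }
      keep <- at$resno >= resno_range[1] & at$resno <= resno_range[2]
      if (!is.null(atom_names)) keep <- keep & at$name %in% atom_names
      which(keep)
    },
    "named-atoms" = {
      if (is.null(atom_names)) stop("named-atoms query needs atom_names")
      which(at$name %in% atom_names)
    })
  idx <- sort(unique(idx))
  if (length(idx) == 0L) {
    stop("selection '", query, "' matched no atoms")
  }
  idx
}

# ---------------------------------------------------------------------------
# Hydration shells

#' Select hydration-shell waters around the protein
#'
#' A water molecule belongs to the shell when its oxygen lies within
#' \code{cutoff} of any protein atom (the default, matching shell counts
#' stated per water molecule); \code{mode = "any-atom"} instead admits a
#' molecule when any of its atoms is within the cutoff.  Minimum-image
#' distances are used when the trajectory carries a box.
#'
#' @param traj a \code{\link{trajectory}} containing protein and water.
#' @param frame frame index (1-based).
#' @param cutoff shell radius in Angstrom (3.8 for the first hydration
#'   layer, 8.0 for a two-layer shell).
#' @param mode membership rule, \code{"oxygen"} or \code{"any-atom"}.
#' @return object of class \code{shell_selection}: the oxygen indices of
#'   member waters, their residue numbers, plus the cutoff and frame used.
#' @export
shell_waters <- function(traj, frame = 1L, cutoff = 3.8,
                         mode = c("oxygen", "any-atom")) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  if (frame < 1L || frame > n_frames(traj)) {
    stop("frame ", frame, " out of range 1..", n_frames(traj))
  }
  at <- traj$atoms
  prot <- which(at$category == "protein")
  wat_o <- which(at$category == "water" & at$element == "O")
  if (length(prot) == 0L) stop("trajectory has no protein atoms")
  if (length(wat_o) == 0L) stop("trajectory has no water oxygens")
  pc <- traj$coords[frame, prot, , drop = TRUE]
  if (is.null(dim(pc))) pc <- matrix(pc, ncol = 3)
  member <- logical(length(wat_o))
  if (mode == "oxygen") {
    wc <- traj$coords[frame, wat_o, , drop = TRUE]
    if (is.null(dim(wc))) wc <- matrix(wc, ncol = 3)
    member <- .min_dist_to_set(wc, pc, traj$box) <= cutoff
  } else {
    wat_res <- at$resno[wat_o]
    for (i in seq_along(wat_o)) {
      mol <- which(at$category == "water" & at$resno == wat_res[i])
      mc <- traj$coords[frame, mol, , drop = TRUE]
      if (is.null(dim(mc))) mc <- matrix(mc, ncol = 3)
      member[i] <- any(.min_dist_to_set(mc, pc, traj$box) <= cutoff)
    }
  }
  structure(list(cutoff = cutoff, frame = frame, mode = mode,
                 water_oxygen_indices = wat_o[member],
                 water_resno = at$resno[wat_o[member]],
                 n_waters = sum(member)),
            class = "shell_selection")
}

#' @export
print.shell_selection <- function(x, ...) {
  cat("hydration shell: ", x$n_waters, " waters within ", x$cutoff,
      " A (frame ", x$frame, ", ", x$mode, " rule)\n", sep = "")
  invisible(x)
}

# Min distance from each row of `a` to the point set `b`, optionally under
# the minimum-image convention for an orthorhombic box.
.min_dist_to_set <- function(a, b, box = NULL) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    if (!is.null(box)) {
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    out[i] <- sqrt(min(rowSums(d * d)))
  }
  out
}

# Pairwise distance between two coordinate matrices (n x 3, m x 3),
# minimum-image when a box is given.  Returns n x m matrix.
.pair_dist <- function(a, b, box = NULL) {
  if (is.null(box)) {
    a2 <- rowSums(a * a); b2 <- rowSums(b * b)
    d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  } else {
    out <- matrix(NA_real_, nrow(a), nrow(b))
    for (k in 1:3) {
      dk <- outer(a[, k], b[, k], "-")
      dk <- dk - box[k] * round(dk / box[k])
      out <- if (k == 1) dk * dk else out + dk * dk
    }
    sqrt(out)
  }
}

# ---------------------------------------------------------------------------
# Velocities

#' Derive velocities by finite differences of positions
#'
#' Central differences \eqn{v(t) = (x(t+dt) - x(t-dt)) / (2 dt)} on
#' interior frames (exact for linear and quadratic motion), one-sided
#' differences on the first and last frame.  The result is flagged as
#' derived.
#'
#' @param traj a \code{\link{trajectory}} with at least 3 frames and no
#'   stored velocities.
#' @return the trajectory with a filled \code{velocities} slot.
#' @export
finite_difference_velocities <- function(traj) {
  nf <- n_frames(traj)
  if (nf < 3L) stop("need at least 3 frames for finite differences")
  if (!is.null(traj$velocities)) {
    stop("trajectory already has velocities")
  }
  dt <- traj$dt
  x <- traj$coords
  v <- array(NA_real_, dim = dim(x))
  v[2:(nf - 1), , ] <- (x[3:nf, , , drop = FALSE] -
                        x[1:(nf - 2), , , drop = FALSE]) / (2 * dt)
  v[1, , ] <- (x[2, , ] - x[1, , ]) / dt
  v[nf, , ] <- (x[nf, , ] - x[nf - 1, , ]) / dt
  traj$velocities <- v
  traj$derived_velocities <- TRUE
  traj
}
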