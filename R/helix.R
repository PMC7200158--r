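#' Helical symmetry of a filament
#'
#' Per-protomer screw parameters of a helical filament: the rotation
#' about the helix axis (twist, degrees) and the translation along it
#' (rise, Angstrom) relating protomer i to protomer i+1 within a strand.
#'
#' @param twist degrees per protomer, in (0, 360].
#' @param rise Angstrom per protomer, > 0.
#' @return A `helical_symmetry` list.
#' @export
helical_symmetry <- function(twist, rise) {
  stopifnot(is.numeric(twist), length(twist) == 1L,
            is.numeric(rise), length(rise) == 1L)
  if (!is.finite(twist) || twist <= 0 || twist > 360)
    stop("twist must be in (0, 360] degrees")
  if (!is.finite(rise) || rise <= 0)
    stop("rise must be > 0 Angstrom")
  structure(list(twist = twist, rise = rise), class = "helical_symmetry")
}

#' Helical pitch
#'
#' The axial distance per full turn: rise * 360 / twist.
#'
#' @param sym a [helical_symmetry()].
#' @return Pitch in Angstrom.
#' @examples
#' pitch(helical_symmetry(48, 13.5))  # 101.25
#' @export
pitch <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  sym$rise * 360 / sym$twist
}

#' Protomers per helical turn
#'
#' @param sym a [helical_symmetry()].
#' @return 360 / twist, dimensionless.
#' @export
protomers_per_turn <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  360 / sym$twist
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

# two-fold rotation about an in-plane (z = 0) axis at angle `deg` from x
dyad_matrix <- function(deg) {
  rot_z(deg) %*% diag(c(1, -1, -1)) %*% rot_z(-deg)
}

#' Build an idealized antiparallel double-stranded filament
#'
#' Places protomer centroids on two helical strands related by a two-fold
#' (dyad) rotation about an axis perpendicular to the helix axis. Strand
#' A centroid i (i = 0, 1, ...) sits at
#' (R cos(i dphi), R sin(i dphi), i dz); strand B is the dyad image of
#' strand A, which reverses the axial polarity (antiparallel). The dyad
#' phase and radius are schematic parameters, not measured quantities.
#'
#' @param sym a [helical_symmetry()].
#' @param n_per_strand protomers per strand, >= 1.
#' @param radius centroid distance from the helix axis, Angstrom.
#' @param dyad_phase angle (degrees) of the in-plane dyad axis.
#' @param handedness `"right"` (positive twist about +z) or `"left"`.
#' @return A `filament_model` data.frame with columns `strand` ("A"/"B"),
#'   `index`, `x`, `y`, `z` (Angstrom) and `polarity` (+1/-1), plus the
#'   generating parameters as attributes.
#' @export
build_double_helix <- function(sym, n_per_strand, radius = 20,
                               dyad_phase = 0,
                               handedness = c("right", "left")) {
  stopifnot(inherits(sym, "helical_symmetry"))
  handedness <- match.arg(handedness)
  if (n_per_strand < 1 || n_per_strand != round(n_per_strand))
    stop("n_per_strand must be an integer >= 1")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  sgn <- if (handedness == "right") 1 else -1
  i <- seq_len(n_per_strand) - 1
  phi <- sgn * i * sym$twist * pi / 180
  a <- cbind(x = radius * cos(phi), y = radius * sin(phi), z = i * sym$rise)
  b <- a %*% t(dyad_matrix(dyad_phase))
  colnames(b) <- colnames(a)
  model <- data.frame(
    strand = rep(c("A", "B"), each = n_per_strand),
    index = rep(i, 2),
    rbind(as.data.frame(a), as.data.frame(b)),
    polarity = rep(c(1, -1), each = n_per_strand))
  attr(model, "symmetry") <- sym
  attr(model, "radius") <- radius
  attr(model, "dyad_phase") <- dyad_phase
  attr(model, "handedness") <- handedness
  class(model) <- c("filament_model", class(model))
  model
}

#' Write filament centroids as a pseudo-atom PDB file
#'
#' One CA pseudo-atom per protomer centroid, chain A/B per strand, so the
#' idealized filament can be inspected in standard structure viewers.
#'
#' @param model a [build_double_helix()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_centroids <- function(model, path) {
  stopifnot(inherits(model, "filament_model"))
  if (nrow(model) < 1L) stop("model is empty")
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  n <- nrow(model)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    type = rep("ATOM", n),
    resno = model$index + 1L,
    resid = rep("DIX", n),
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = model$strand,
    o = rep(1, n), b = rep(0, n))
  invisible(path)
}
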