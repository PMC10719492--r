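#' @rdname packing_angle
#' @format NULL
#' @export
GEOMETRY_POSITIONS_LIGHT <- paste0("L", c(35:38, 85:88))

#' @rdname packing_angle
#' @format NULL
#' @export
GEOMETRY_POSITIONS_HEAVY <- paste0("H", c(36:39, 89:92))

#' Conserved C-alpha sets for the packing-angle calculation
#'
#' Extracts the C-alpha coordinates of the eight structurally conserved
#' framework positions in each domain: L35-L38 and L85-L88 in the light
#' chain, H36-H39 and H89-H92 in the heavy chain, in that fixed order.
#'
#' @param fv An [fv_structure].
#' @return A list with `light` and `heavy`, each an 8 x 3 coordinate matrix
#'   (rows in position order, columns x/y/z in Angstroms).
#' @export
conserved_ca_sets <- function(fv) {
  stopifnot(inherits(fv, "fv_structure"))
  take <- function(keys) {
    idx <- match(keys, fv$residues$key)
    coords <- as.matrix(fv$residues[idx, c("x", "y", "z")])
    missing <- keys[is.na(idx) | rowSums(is.na(coords)) > 0]
    list(coords = coords, missing = missing)
  }
  l <- take(GEOMETRY_POSITIONS_LIGHT)
  h <- take(GEOMETRY_POSITIONS_HEAVY)
  absent <- c(l$missing, h$missing)
  if (length(absent) > 0) {
    abort(paste0("Missing C-alpha at conserved position(s): ",
                 paste(absent, collapse = ", ")),
          class = "vhvl_missing_position")
  }
  dimnames(l$coords) <- list(GEOMETRY_POSITIONS_LIGHT, c("x", "y", "z"))
  dimnames(h$coords) <- list(GEOMETRY_POSITIONS_HEAVY, c("x", "y", "z"))
  list(light = l$coords, heavy = h$coords)
}

#' Total-least-squares line through a point set
#'
#' Fits the line minimizing the sum of squared perpendicular distances: the
#' principal axis of the centred coordinates, from the dominant singular
#' direction. The sign of `direction` is arbitrary unless `orient_toward`
#' is supplied, in which case the direction is flipped to have a positive
#' dot product with it.
#'
#' @param points An n x 3 coordinate matrix, n >= 2, not all coincident.
#' @param orient_toward Optional 3-vector fixing the direction's sign.
#' @return A list with `direction` (unit 3-vector) and `centroid`
#'   (3-vector, the arithmetic mean of the points).
#' @export
best_fit_vector <- function(points, orient_toward = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  centroid <- colMeans(points)
  centred <- sweep(points, 2, centroid)
  if (all(abs(centred) < 1e-12)) {
    abort("Degenerate geometry: all points coincident")
  }
  direction <- svd(centred, nu = 0, nv = 1)$v[, 1]
  if (!is.null(orient_toward) && sum(direction * orient_toward) < 0) {
    direction <- -direction
  }
  list(direction = direction, centroid = centroid)
}

#' Signed dihedral of four points (IUPAC convention, degrees)
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  atan2(y, x) * 180 / pi
}

#' VH/VL packing angle of an Fv structure
#'
#' The packing angle summarizes the relative orientation of the VL and VH
#' domains as a single signed torsion. A total-least-squares line is fitted
#' through the eight conserved C-alpha positions of each domain
#' ([conserved_ca_sets]); each fitted direction is oriented from the
#' centroid of the first four positions (L35-L38 / H36-H39) toward the
#' centroid of the last four (L85-L88 / H89-H92). The torsion is then the
#' dihedral of the four points (light pivot + light vector, light pivot,
#' heavy pivot, heavy pivot + heavy vector), where each pivot is the
#' projection of that domain's residue-set centroid onto its fitted line
#' (which, for a total-least-squares line, is the centroid itself). Natural
#' antibodies score near -46 degrees.
#'
#' `GEOMETRY_POSITIONS_LIGHT` / `GEOMETRY_POSITIONS_HEAVY` name the sixteen
#' positions used.
#'
#' @param fv An [fv_structure] with C-alpha coordinates at all sixteen
#'   conserved positions.
#' @return An object of class `packing_angle`: a list with `degrees`,
#'   unit `light_vector` / `heavy_vector`, and `light_pivot` /
#'   `heavy_pivot` (Angstroms).
#' @export
packing_angle <- function(fv) {
  sets <- conserved_ca_sets(fv)
  fit_domain <- function(coords) {
    toward <- colMeans(coords[5:8, , drop = FALSE]) -
      colMeans(coords[1:4, , drop = FALSE])
    fit <- best_fit_vector(coords, orient_toward = toward)
    # the pivot is the projection of the residue-set centroid onto the
    # fitted line; a TLS line passes through that centroid, so the
    # projection is the centroid itself
    list(direction = fit$direction, pivot = fit$centroid)
  }
  l <- fit_domain(sets$light)
  h <- fit_domain(sets$heavy)
  degrees <- dihedral_deg(l$pivot + l$direction, l$pivot,
                          h$pivot, h$pivot + h$direction)
  structure(
    list(degrees = degrees,
         light_vector = l$direction, heavy_vector = h$direction,
         light_pivot = l$pivot, heavy_pivot = h$pivot),
    class = "packing_angle"
  )
}

#' @export
print.packing_angle <- function(x, ...) {
  cat(sprintf("VH/VL packing angle: %.2f degrees\n", x$degrees))
  invisible(x)
}

#' Packing angles for a batch of PDB files
#'
#' Computes the packing angle for each readable, computable structure.
#' Files that cannot be read or lack conserved positions are excluded from
#' the result and reported in the `failures` attribute (and as messages),
#' not raised as errors.
#'
#' @param paths Character vector of PDB file paths.
#' @param ... Passed to [read_fv()] (e.g. `light_chain`, `heavy_chain`).
#' @return A tibble with columns `id` and `angle_deg` (degrees, one row per
#'   successful structure), with attribute `failures`: a tibble of `path`
#'   and `reason` for the excluded files.
#' @export
batch_angles <- function(paths, ...) {
  rows <- vector("list", length(paths))
  fails <- list()
  for (i in seq_along(paths)) {
    res <- tryCatch({
      fv <- read_fv(paths[i], ...)
      tibble(id = fv$id, angle_deg = packing_angle(fv)$degrees)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("Excluding %s: %s", paths[i], conditionMessage(res)))
      fails[[length(fails) + 1L]] <-
        tibble(path = paths[i], reason = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(id = character(0), angle_deg = numeric(0))
  attr(out, "failures") <- if (length(fails) > 0) {
    dplyr::bind_rows(fails)
  } else {
    tibble(path = character(0), reason = character(0))
  }
  out
}
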