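#' Construct a QM region
#'
#' The QM region is the set of atoms treated quantum mechanically: element
#' symbols, Cartesian coordinates in angstrom, nuclear charges, and optional
#' fixed force-field reference charges (used by mechanical embedding and the
#' MM-level long-range correction). It is also the set of multipole expansion
#' sites for every long-range representation.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of positions in angstrom.
#' @param q_ref optional numeric vector of per-atom reference charges (e).
#' @param net_charge integer total charge of the region (e).
#' @param multiplicity integer spin multiplicity (carried, not used by the
#'   classical surrogate backend).
#' @return A tibble of class `qm_region` with columns `element`, `x`, `y`,
#'   `z`, `Z`, `q_ref` and attributes `net_charge`, `multiplicity`.
#' @examples
#' qm_region("O", matrix(c(0, 0, 0), 1), q_ref = -1, net_charge = -1)
#' @export
qm_region <- function(elements, coords, q_ref = NULL, net_charge = 0L,
                      multiplicity = 1L) {
  coords <- .as_coord_matrix(coords, length(elements), "QM region")
  Z <- .element_lookup(elements, "Z")
  if (!is.null(q_ref) && length(q_ref) != length(elements)) {
    rlang::abort("q_ref must have one entry per atom",
                 class = "qmmbed_validation_error")
  }
  out <- tibble::tibble(
    element = as.character(elements),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    Z = as.numeric(Z),
    q_ref = if (is.null(q_ref)) NA_real_ else as.numeric(q_ref)
  )
  attr(out, "net_charge") <- as.integer(net_charge)
  attr(out, "multiplicity") <- as.integer(multiplicity)
  class(out) <- c("qm_region", class(out))
  out
}

#' Construct an MM charge environment
#'
#' Point charges with coordinates in angstrom and an integer charge-group
#' label per charge (one group per water molecule or residue). Groups are the
#' unit of inclusion for group-based cutoffs, chosen so that cutting never
#' creates artificial net charges inside a neutral molecule.
#'
#' @param coords numeric matrix (n x 3), angstrom.
#' @param q numeric vector of charges (e).
#' @param group non-negative integer vector of group labels.
#' @return A tibble of class `mm_charges` with columns `x`, `y`, `z`, `q`,
#'   `group`.
#' @export
mm_charges <- function(coords, q, group) {
  coords <- .as_coord_matrix(coords, length(q), "MM charges")
  if (length(group) != length(q)) {
    rlang::abort("q and group must have equal lengths",
                 class = "qmmbed_validation_error")
  }
  group <- as.integer(group)
  if (length(group) && any(group < 0L)) {
    rlang::abort("group labels must be non-negative",
                 class = "qmmbed_validation_error")
  }
  out <- tibble::tibble(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    q = as.numeric(q), group = group
  )
  class(out) <- c("mm_charges", class(out))
  out
}

.as_coord_matrix <- function(coords, n, what) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 3L && ncol(coords) != 3L) coords <- t(coords)
  if (ncol(coords) != 3L || nrow(coords) != n) {
    rlang::abort(paste0(what, ": coords must be an n x 3 matrix matching the ",
                        "number of atoms"),
                 class = "qmmbed_validation_error")
  }
  storage.mode(coords) <- "double"
  coords
}

# n x 3 coordinate matrix in bohr
.coords_bohr <- function(df) {
  cbind(df$x, df$y, df$z) * qmm_constants$bohr_per_angstrom
}

.coords_ang <- function(df) cbind(df$x, df$y, df$z)

.qm_ff_charges <- function(qm) {
  q <- qm$q_ref
  if (anyNA(q)) {
    rlang::abort("QM region has no force-field reference charges (q_ref)",
                 class = "qmmbed_validation_error")
  }
  q
}

#' @export
print.qm_region <- function(x, ...) {
  cat(sprintf("<qm_region> %d atoms, net charge %+d, multiplicity %d\n",
              nrow(x), attr(x, "net_charge"), attr(x, "multiplicity")))
  NextMethod()
}

#' @export
print.mm_charges <- function(x, ...) {
  cat(sprintf("<mm_charges> %d charges in %d groups, total %+.4f e\n",
              nrow(x), length(unique(x$group)), sum(x$q)))
  NextMethod()
}

# min distance (angstrom) from each MM charge to its closest QM atom
.min_dist_to_qm <- function(mm, qm) {
  if (nrow(mm) == 0L) return(numeric(0))
  A <- .coords_ang(qm)
  B <- .coords_ang(mm)
  # pairwise distances via the usual |a-b|^2 expansion; n_qm is small
  d2 <- outer(rowSums(B^2), rowSums(A^2), "+") - 2 * B %*% t(A)
  sqrt(pmax(apply(d2, 1, min), 0))
}
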