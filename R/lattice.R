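# Subcell lattice: the discretized cell volume holding integer molecule
# counts per species per subcell, with 6-connected neighbor topology and an
# inside-the-membrane mask.

#' Build the subcell lattice for an ellipsoidal cell
#'
#' Tiles the bounding box of the ellipsoid with cubic subcells of side
#' `l_SV`, centered so that the origin is a subcell center. A subcell is
#' inside the cell when its center satisfies
#' (x/a)^2 + (y/b)^2 + (z/c)^2 < 1.
#'
#' @param a,b,c ellipsoid semi-axes in nm.
#' @param l_SV subcell side in nm.
#' @return A `subcell_lattice`: `dims` (3), `l_SV`, `centers` (V_box x 3, nm),
#'   `inside` (logical), `nbr` (V_box x 6 neighbor indices, 0 where the
#'   neighbor is outside the mask or the box -> reflecting), `counts`
#'   (0-row matrix until species are added), `species` (character).
#' @examples
#' lat <- build_lattice(1000, 1000, 1000, 250)
#' sum(lat$inside)  # ~ (4/3) pi 4^3 = 268 subcells
#' @export
build_lattice <- function(a, b, c, l_SV = 250) {
  if (any(c(a, b, c) <= l_SV)) stop("semi-axes must exceed the subcell size")
  half <- function(s) ceiling((s - l_SV / 2) / l_SV)
  nh <- c(half(a), half(b), half(c))
  dims <- 2L * as.integer(nh) + 1L
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - nh[k] - 1) * l_SV)
  centers <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  inside <- (centers[, 1] / a)^2 + (centers[, 2] / b)^2 +
    (centers[, 3] / c)^2 < 1
  V <- nrow(centers)
  idx <- array(seq_len(V), dim = dims)

  nbr <- matrix(0L, V, 6)
  ii <- arrayInd(seq_len(V), dims)
  for (d in 1:3) {
    for (s in c(1L, -1L)) {
      col <- 2L * (d - 1L) + if (s == 1L) 1L else 2L
      jj <- ii
      jj[, d] <- jj[, d] + s
      ok <- jj[, d] >= 1L & jj[, d] <= dims[d]
      tgt <- rep(0L, V)
      tgt[ok] <- idx[jj[ok, , drop = FALSE]]
      tgt[tgt > 0L & !inside[pmax(tgt, 1L)]] <- 0L
      nbr[, col] <- tgt
    }
  }
  nbr[!inside, ] <- 0L

  structure(list(
    dims = dims, l_SV = l_SV, centers = centers, inside = inside,
    nbr = nbr, ellipse = c(a, b, c),
    counts = matrix(0L, 0, V), species = character(0)
  ), class = "subcell_lattice")
}

#' @export
print.subcell_lattice <- function(x, ...) {
  cat("<subcell_lattice> ", paste(x$dims, collapse = " x "),
      " subcells (", sum(x$inside), " inside), l_SV = ", x$l_SV, " nm, ",
      length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Subcell index containing a point
#'
#' @param lattice a `subcell_lattice`.
#' @param pos matrix (n x 3) or vector of coordinates in nm.
#' @return integer subcell indices (`NA` outside the box).
#' @export
subcell_of <- function(lattice, pos) {
  pos <- matrix(pos, ncol = 3)
  nh <- (lattice$dims - 1L) %/% 2L
  ijk <- sweep(round(pos / lattice$l_SV), 2, nh + 1, "+")
  bad <- ijk < 1 | sweep(ijk, 2, lattice$dims, ">")
  ijk[bad] <- NA
  out <- ijk[, 1] + lattice$dims[1] * (ijk[, 2] - 1) +
    prod(lattice$dims[1:2]) * (ijk[, 3] - 1)
  as.integer(out)
}

#' Register a species on the lattice
#' @param lattice a `subcell_lattice`.
#' @param name species name.
#' @param D diffusion constant, nm^2/s (0 = immobile).
#' @return the lattice with a new (zero) counts row.
#' @export
add_species <- function(lattice, name, D = 0) {
  if (name %in% lattice$species) stop("species already present: ", name)
  lattice$species <- c(lattice$species, name)
  lattice$D <- c(lattice$D, setNames(D, name))
  lattice$counts <- rbind(lattice$counts,
                          matrix(0L, 1, ncol(lattice$counts)))
  rownames(lattice$counts) <- lattice$species
  lattice
}

#' Place molecules multinomially on the lattice
#' @param lattice a `subcell_lattice`.
#' @param name species name.
#' @param n number of molecules.
#' @param weights per-subcell placement weights (zeroed outside the mask).
#' @return the lattice with updated counts.
#' @export
place_molecules <- function(lattice, name, n, weights) {
  j <- match(name, lattice$species)
  if (is.na(j)) stop("unknown species: ", name)
  if (n < 0) stop("count must be non-negative")
  weights[!lattice$inside] <- 0
  if (n > 0) {
    if (sum(weights) <= 0) stop("no admissible subcells for ", name)
    draw <- as.integer(rmultinom(1, n, weights))
    lattice$counts[j, ] <- lattice$counts[j, ] + draw
  }
  lattice
}

#' Total molecule count per species
#' @param lattice a `subcell_lattice`.
#' @param name species name, or `NULL` for all.
#' @return named totals.
#' @export
species_total <- function(lattice, name = NULL) {
  if (is.null(name)) return(rowSums(lattice$counts))
  sum(lattice$counts[match(name, lattice$species), ])
}
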