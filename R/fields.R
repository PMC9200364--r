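# Spatial enzyme fields: uniform phosphatase, Aurora B gaussian about the
# centromere, Aurora A twin gaussians about the poles.

# Subcells within `reach` nm of the centromere surface, i.e. within
# R_CH + reach of either kinetochore center.
corona_neighborhood <- function(lattice, kt_centers, params,
                                reach = params$ab_spread) {
  lim <- params$R_CH + reach
  d1 <- sqrt(colSums((t(lattice$centers) - kt_centers[1, ])^2))
  d2 <- sqrt(colSums((t(lattice$centers) - kt_centers[2, ])^2))
  pmin(d1, d2) <= lim & lattice$inside
}

# Gaussian weights about `center` restricted to `mask`.
gaussian_weights <- function(lattice, center, sigma, mask) {
  r2 <- colSums((t(lattice$centers) - center)^2)
  w <- exp(-r2 / (2 * sigma^2))
  w[!mask] <- 0
  w
}

#' Initialize the enzyme fields on the lattice
#'
#' Phosphatase (PH) is placed as explicit, immobile integer counts, sampled
#' multinomially with uniform weight over the corona neighborhood (subcells
#' within `ab_spread` of the centromere surface): its low copy number is a
#' real source of stochasticity and is never smoothed. Aurora B is an
#' isotropic gaussian centered on the kinetochore midpoint, truncated at the
#' same neighborhood; Aurora A is a pair of gaussians centered on the
#' centrosomes, truncated at `aa_confine`. In `"field"` mode (default) the
#' Aurora distributions enter propensities as static expected counts per
#' subcell; in `"explicit"` mode they are sampled as integer molecules that
#' hop on the lattice with reflecting confinement.
#'
#' @param lattice a `subcell_lattice`.
#' @param kt_centers 2-by-3 matrix of kinetochore bead centers (nm).
#' @param cs_positions 2-by-3 matrix of centrosome centers, or `NULL`.
#' @param params a `spindle_params` (counts `n_PH`, `n_AB`, `n_AA`).
#' @param mode `"field"` or `"explicit"` for the Aurora kinases.
#' @return the lattice, with `counts` rows for explicit species and a
#'   `fields` element holding expected-count vectors (`AB`, `AA`) plus the
#'   neighborhood mask.
#' @export
init_enzyme_fields <- function(lattice, kt_centers, cs_positions = NULL,
                               params = validate_params(),
                               mode = c("field", "explicit")) {
  mode <- match.arg(mode)
  params <- validate_params(params)
  if (any(c(params$n_PH, params$n_AB, params$n_AA) < 0)) {
    stop("enzyme counts must be non-negative")
  }
  hood <- corona_neighborhood(lattice, kt_centers, params)
  mid <- colMeans(kt_centers)

  lattice <- add_species(lattice, "PH", D = 0)
  lattice <- place_molecules(lattice, "PH", params$n_PH, as.numeric(hood))

  w_ab <- gaussian_weights(lattice, mid, params$sigma_AB, hood)
  if (sum(w_ab) > 0) w_ab <- w_ab / sum(w_ab)
  w_aa <- rep(0, nrow(lattice$centers))
  if (!is.null(cs_positions) && params$n_AA > 0) {
    for (s in 1:2) {
      m <- sqrt(colSums((t(lattice$centers) - cs_positions[s, ])^2)) <=
        params$aa_confine & lattice$inside
      w_aa <- w_aa + gaussian_weights(lattice, cs_positions[s, ],
                                      params$sigma_AA, m)
    }
    if (sum(w_aa) > 0) w_aa <- w_aa / sum(w_aa)
  }

  if (mode == "explicit") {
    lattice <- add_species(lattice, "AB", D = params$D_aurora)
    lattice <- place_molecules(lattice, "AB", params$n_AB, w_ab)
    if (params$n_AA > 0) {
      lattice <- add_species(lattice, "AA", D = params$D_aurora)
      lattice <- place_molecules(lattice, "AA", params$n_AA, w_aa)
    }
    lattice$fields <- list(mode = "explicit", hood = hood,
                           confine = list(AB = hood))
  } else {
    lattice$fields <- list(
      mode = "field", hood = hood,
      AB = w_ab * params$n_AB,
      AA = if (params$n_AA > 0) w_aa * params$n_AA else NULL)
  }
  lattice
}

# Expected kinase count in each subcell (field mode) or current explicit
# counts; used by phosphorylation propensities.
kinase_counts <- function(lattice) {
  if (identical(lattice$fields$mode, "field")) {
    ab <- lattice$fields$AB
    if (!is.null(lattice$fields$AA)) ab <- ab + lattice$fields$AA
    return(ab)
  }
  ab <- lattice$counts[match("AB", lattice$species), ]
  j <- match("AA", lattice$species)
  if (!is.na(j)) ab <- ab + lattice$counts[j, ]
  as.numeric(ab)
}

phosphatase_counts <- function(lattice) {
  as.numeric(lattice$counts[match("PH", lattice$species), ])
}
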