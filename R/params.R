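# Parameter registry: every physical constant, rate, rigidity and geometry
# default of the model lives here, addressable by name.

#' Default model parameters
#'
#' Returns the full parameter registry of the spindle model: component sizes,
#' spring constants and rigidities, microtubule dynamic-instability rates,
#' Ndc80 (de)phosphorylation and attachment kinetics, enzyme transport
#' properties, copy numbers, and cell morphology. Units are the internal
#' system (nm, pN, pN ps/nm, s for kinetic rates) except for the two bending
#' rigidities and the excluded-volume energy scale, which are specified in
#' kJ/mol( rad^2) as usually tabulated and converted to pN nm by
#' [validate_params()].
#'
#' The printed friction coefficients (`gamma_KT`, `gamma_MT`) and the Aurora
#' diffusion constant `D_aurora` are stored independently: they are mutually
#' consistent only to a few percent through the Stokes-Einstein relation, so
#' each is used where it is quoted. The viscosity `eta` (pN ps/nm^2;
#' 1 cP = 1000 pN ps/nm^2) defaults to the value that makes Stokes-Einstein at
#' bead radius 2.9 nm reproduce `D_aurora`, and is used only where no printed
#' friction exists.
#'
#' @return A named list of class `spindle_params` (units not yet normalized;
#'   pass through [validate_params()] before use).
#' @export
default_params <- function() {
  p <- list(
    ## -- geometry (nm unless noted) --
    R_CS  = 400,      # centrosome radius
    R_MT  = 12,       # microtubule bead radius
    R_CH  = 362.5,    # kinetochore / chromosome-arm bead radius
    R_Ndc = 4,        # corona (Ndc80 seed) bead radius
    A_KT  = 0.15,     # corona patch area, um^2
    chi   = 0.5,      # corona curvature parameter in [0,1] (0 curved, 1 flat)
    l_Ndc = 65,       # Ndc80 linker rest length / capture radius
    d_KT  = 725,      # sister kinetochore rest separation
    l_SV  = 250,      # subcell (lattice voxel) side
    ## -- spring constants / rigidities --
    K_MT_r     = 16.7,    # pN/nm, MT stretching
    K_MT_theta = 7.7e5,   # kJ/mol rad^2, MT bending
    K_CH_r     = 3.3e3,   # pN/nm, chromosome-arm stretching
    K_CH_theta = 2.5e5,   # kJ/mol rad^2, chromosome-arm bending
    K_KT_r     = 3.3e3,   # pN/nm, centromere + corona-grid + corona-to-KT
    K_Ndc_r    = 3.1e2,   # pN/nm, Ndc80 linker
    K_coh_r    = 3.3e3,   # pN/nm, cohesin springs (not separately printed;
                          # defaults to the arm stretching stiffness)
    K_mem      = 3.3e3,   # pN/nm, membrane soft repulsion
    eps_LJ     = 2.1e5,   # kJ/mol, excluded-volume energy scale
    R_Ndc_bond = 200,     # nm, corona-grid bond cutoff (50 for flexible KT)
    K_KT_r_flex = 82.5,   # pN/nm, 40-fold softened corona-to-KT springs
    R_Ndc_bond_flex = 50, # nm, corona-grid cutoff in the flexible-KT variant
    ## -- microtubule dynamic instability (1/s, nm) --
    k_gr    = 5.0,
    k_sh    = 18.6,
    w_cat   = 2.5e-3,
    w_res   = 3.0e-2,
    delta_l = 24,
    ## -- Ndc80 phospho-regulated attachment kinetics --
    k_phos      = 1.5e7,   # 1/(s M)
    k_dephos    = 3.0e7,   # 1/(s M)
    k_on_NdcMT  = 3.8e9,   # 1/(s M)
    k_off_base  = 1.5e-3,  # 1/s
    k_off_perP  = 0.2e-3,  # 1/s per phosphate
    p_max       = 7L,
    ## -- transport / thermodynamics --
    D_aurora = 7.3e7,      # nm^2/s
    T        = 300,        # K
    eta      = NA_real_,   # pN ps/nm^2; filled by validate_params()
    R_aurora = 2.9,        # nm, Aurora hydrodynamic radius
    gamma_KT = 6.8e6,      # pN ps/nm (printed; = 6 pi eta R_CH at ~1 cP)
    gamma_MT = 4.5e5,      # pN ps/nm (printed)
    dt_LD    = 50,         # ps
    ## -- copy numbers --
    n_MT_per_CS    = 750L,
    n_corona_beads = 750L,  # per corona; each bead is one Ndc80 site
    n_PH = 10L,             # phosphatase molecules in the corona neighborhood
    n_AB = 100L,            # Aurora B near the centromere
    n_AA = 0L,              # Aurora A at the poles (off unless requested)
    ## -- morphology (um) --
    ellipse_a = 8,
    ellipse_b = 5.04,
    ellipse_c = 5.04,
    pole_separation = 12,
    ## -- enzyme field shape (nm) --
    ab_spread  = 250,   # AB reaches this far beyond the centromere surface
    sigma_AA   = 1000,  # width of the polar Aurora A gaussians
    aa_confine = 2000   # confinement radius of Aurora A about each pole
  )
  class(p) <- "spindle_params"
  p
}

#' Validate and unit-normalize a parameter set
#'
#' Fills omitted fields from [default_params()], rejects non-physical values
#' (non-positive rates, lengths, stiffnesses; `chi` outside `[0,1]`), and
#' converts the molar energy parameters (`K_MT_theta`, `K_CH_theta`, `eps_LJ`,
#' in kJ/mol) to internal pN nm units. The number of Ndc80 phosphosites is
#' pinned at 7 unless `allow_p_max_override = TRUE`.
#'
#' @param raw named list (or `spindle_params`) of overrides; may be empty.
#' @param allow_p_max_override permit a non-default `p_max`.
#' @return A fully populated `spindle_params` with `units_normalized = TRUE`;
#'   derived fields `kT` (pN nm), `sigma_AB` (nm) and `eta` are added.
#' @examples
#' p <- validate_params(list(chi = 0.25))
#' p$eps_LJ  # ~3.49e5 pN nm
#' @export
validate_params <- function(raw = list(), allow_p_max_override = FALSE) {
  if (isTRUE(attr(raw, "units_normalized"))) {
    return(raw)
  }
  unknown <- setdiff(names(raw), names(default_params()))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- modifyList(default_params(), raw[!vapply(raw, is.null, logical(1))])

  pos_fields <- c(
    "R_CS", "R_MT", "R_CH", "R_Ndc", "A_KT", "l_Ndc", "d_KT", "l_SV",
    "K_MT_r", "K_MT_theta", "K_CH_r", "K_CH_theta", "K_KT_r", "K_Ndc_r",
    "K_coh_r", "K_mem", "eps_LJ", "R_Ndc_bond", "K_KT_r_flex",
    "R_Ndc_bond_flex", "k_gr", "k_sh", "w_cat", "w_res", "delta_l",
    "k_phos", "k_dephos", "k_on_NdcMT", "k_off_base", "k_off_perP",
    "D_aurora", "T", "dt_LD", "gamma_KT", "gamma_MT", "R_aurora",
    "ellipse_a", "ellipse_b", "ellipse_c", "pole_separation",
    "ab_spread", "sigma_AA", "aa_confine"
  )
  for (f in pos_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("parameter '", f, "' must be a positive finite number")
    }
  }
  if (p$chi < 0 || p$chi > 1) stop("chi must lie in [0, 1]")
  for (f in c("n_MT_per_CS", "n_corona_beads", "n_PH", "n_AB", "n_AA")) {
    if (p[[f]] < 0) stop("count '", f, "' must be non-negative")
    p[[f]] <- as.integer(p[[f]])
  }
  if (p$p_max != 7L && !allow_p_max_override) {
    stop("p_max is fixed at 7 phosphosites; set allow_p_max_override = TRUE ",
         "to change it")
  }
  p$p_max <- as.integer(p$p_max)

  # molar -> mechanical energy units
  p$K_MT_theta <- kjmol_to_pnnm(p$K_MT_theta)  # pN nm / rad^2
  p$K_CH_theta <- kjmol_to_pnnm(p$K_CH_theta)
  p$eps_LJ     <- kjmol_to_pnnm(p$eps_LJ)      # pN nm

  p$kT <- kB_T(p$T)
  if (is.na(p$eta)) {
    # viscosity making Stokes-Einstein at R_aurora reproduce D_aurora;
    # D [nm^2/s] = kT / (6 pi eta R) with eta in pN s/nm^2 = 1e-12 pN ps/nm^2
    eta_pn_s <- p$kT / (6 * pi * p$R_aurora * p$D_aurora)  # pN s/nm^2
    p$eta <- eta_pn_s * 1e12                               # pN ps/nm^2
  }
  # AB gaussian width: 95% of an isotropic gaussian lies within 2 sigma,
  # matched to the confinement shell R_CH + ab_spread
  p$sigma_AB <- (p$R_CH + p$ab_spread) / 2

  attr(p, "units_normalized") <- TRUE
  class(p) <- "spindle_params"
  p
}

#' @export
print.spindle_params <- function(x, ...) {
  cat("<spindle_params> (", length(x), " fields; units ",
      if (isTRUE(attr(x, "units_normalized"))) "internal nm/pN/s" else
        "as tabulated (not yet normalized)", ")\n", sep = "")
  invisible(x)
}
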