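# Configuration files: YAML with three sections -- morphology, kinetics,
# mechanics -- mapping onto the parameter registry and run controls.

# which registry fields belong to which section (for validation/echo)
section_fields <- list(
  morphology = c("R_CS", "R_MT", "R_CH", "R_Ndc", "A_KT", "chi", "d_KT",
                 "l_SV", "ellipse_a", "ellipse_b", "ellipse_c",
                 "pole_separation", "n_MT_per_CS", "n_corona_beads",
                 "n_PH", "n_AB", "n_AA", "ab_spread", "sigma_AA",
                 "aa_confine", "R_aurora"),
  kinetics = c("k_gr", "k_sh", "w_cat", "w_res", "delta_l", "k_phos",
               "k_dephos", "k_on_NdcMT", "k_off_base", "k_off_perP",
               "p_max", "D_aurora"),
  mechanics = c("K_MT_r", "K_MT_theta", "K_CH_r", "K_CH_theta", "K_KT_r",
                "K_Ndc_r", "K_coh_r", "K_mem", "eps_LJ", "l_Ndc",
                "R_Ndc_bond", "K_KT_r_flex", "R_Ndc_bond_flex", "T", "eta",
                "gamma_KT", "gamma_MT", "dt_LD")
)

run_fields <- c("kt_offset", "orientation", "with_arms", "flexible",
                "n_corona", "mt_length_range", "bio_time",
                "output_interval", "field_mode", "relax_max_steps",
                "relax_ftol", "dt", "seed")

#' Read a simulation configuration file
#'
#' YAML with sections `morphology`, `kinetics`, `mechanics` (parameter
#' registry fields) and optionally `run` (placement, durations, output and
#' relaxation controls). Unknown keys are errors; an empty file yields the
#' full defaults. The merged parameter set is validated (positivity, chi
#' range, unit normalization) before use.
#'
#' @param path configuration file.
#' @return a [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad_sec <- setdiff(names(raw), c(names(section_fields), "run"))
  if (length(bad_sec)) stop("unknown config section(s): ",
                            paste(bad_sec, collapse = ", "))
  params <- list()
  for (sec in names(section_fields)) {
    vals <- raw[[sec]]
    if (is.null(vals)) next
    bad <- setdiff(names(vals), section_fields[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    }
    params <- c(params, vals)
  }
  cfg <- simulation_config(params = params)
  if (!is.null(raw$run)) {
    bad <- setdiff(names(raw$run), run_fields)
    if (length(bad)) stop("unknown key(s) in [run]: ",
                          paste(bad, collapse = ", "))
    cfg[names(raw$run)] <- raw$run
  }
  validate_params(cfg$params)  # fail fast on bad values
  cfg
}

#' Write a configuration echo (run manifest)
#'
#' @param config a `simulation_config`.
#' @param seed_used RNG seed actually applied.
#' @param outputs character vector of files written.
#' @param path destination YAML file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed_used, outputs, path) {
  man <- list(
    package = "spindlesim",
    version = as.character(utils::packageVersion("spindlesim")),
    seed = seed_used,
    config = unclass(config),
    outputs = as.list(outputs))
  yaml::write_yaml(man, path)
  invisible(path)
}
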