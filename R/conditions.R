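## Registered pharmacological scenarios, emulated as parameter remaps.
## Multipliers are relative to control and qualitative: directions follow
## the cholesterol biology (lowering cholesterol suppresses MVR and Pr,
## shrinks the spatial footprint, favors ultrafast endocytosis and
## excessive retrieval; raising cholesterol does the opposite); the
## magnitudes are this package's own emulation choices, not fitted data.
condition_table <- function() {
  row <- function(mvr, pr, space, uf, exc, par)
    list(f_mvr = mvr, f_pr = pr, f_space = space, f_ultrafast = uf,
         f_excessive = exc, f_partial = par)
  list(
    control = row(1, 1, 1, 1, 1, 1),
    dmso = row(1, 1, 1, 1, 1, 1),
    ## acute cholesterol extraction ladder (10 min MbCD)
    "mbcd_0.1mM" = row(0.75, 0.95, 0.95, 1.30, 1.20, 1.00),
    "mbcd_1mM" = row(0.45, 0.85, 0.90, 1.60, 1.40, 1.00),
    "mbcd_2.5mM" = row(0.20, 0.75, 0.85, 2.00, 1.60, 1.00),
    "mbcd_5mM" = row(0.10, 0.65, 0.80, 2.40, 1.80, 1.00),
    "mbcd_10mM" = row(0.065, 0.55, 0.75, 2.80, 2.00, 1.00),
    ## acute cholesterol supplementation ladder (water-soluble chol.)
    "wsc_0.1mgml" = row(1.12, 1.05, 1.03, 0.85, 1.00, 1.20),
    "wsc_0.5mgml" = row(1.25, 1.10, 1.06, 0.70, 1.00, 1.40),
    "wsc_1mgml" = row(1.36, 1.15, 1.10, 0.60, 1.00, 1.60),
    ## 2-day blocks of the astrocyte-to-neuron cholesterol supply chain
    lovastatin = row(0.50, 0.85, 0.90, 1.60, 1.40, 1.00),
    probucol_valspodar = row(0.35, 0.80, 0.87, 1.80, 1.50, 1.00),
    pcsk9 = row(0.40, 0.82, 0.88, 1.70, 1.45, 1.00),
    u18666a = row(0.35, 0.80, 0.87, 1.80, 1.50, 1.00),
    ## LDL re-supplementation bypasses the transporter block (rescue)
    ## but not the lysosomal NPC1 block (no rescue)
    probucol_valspodar_ldl = row(1, 1, 1, 1, 1, 1),
    u18666a_ldl = row(0.35, 0.80, 0.87, 1.80, 1.50, 1.00))
}

#' List the registered experimental conditions
#'
#' @return character vector of condition names accepted by
#'   [apply_condition_map()].
#' @export
list_conditions <- function() names(condition_table())

#' Remap a generator configuration to an experimental condition
#'
#' Returns a copy of `config` with release and endocytosis parameters
#' remapped to emulate a registered pharmacological condition. Relative
#' to control, cholesterol-lowering conditions monotonically decrease
#' `p_mvr`, `pr_true` and the spatial scale and increase `p_ultrafast`
#' and the excessive-retrieval weight; cholesterol-raising conditions do
#' the opposite. LDL supplementation rescues the transporter-block
#' scenario but not the NPC1-block scenario.
#'
#' @param config a [generator_config()].
#' @param condition_name one of [list_conditions()].
#' @return a remapped `generator_config`.
#' @export
apply_condition_map <- function(config, condition_name) {
  tab <- condition_table()
  if (!condition_name %in% names(tab))
    stop("unknown condition '", condition_name, "'; registered: ",
         paste(names(tab), collapse = ", "))
  m <- tab[[condition_name]]
  cfg <- config
  cfg$p_mvr <- min(1, config$p_mvr * m$f_mvr)
  cfg$pr_true <- min(1, config$pr_true * m$f_pr)
  cfg$p_ultrafast <- min(0.95, config$p_ultrafast * m$f_ultrafast)
  cfg$az_radius_nm <- config$az_radius_nm * m$f_space
  cfg$site_min_sep_nm <- config$site_min_sep_nm * m$f_space
  ## reweight retrieval categories, keeping the "none" weight fixed
  w <- config$p_retrieval
  w[3] <- w[3] * m$f_excessive
  w[1] <- w[1] * m$f_partial
  w[1:3] <- w[1:3] * (1 - w[4]) / sum(w[1:3])
  cfg$p_retrieval <- w
  validate_generator_config(cfg)
}
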