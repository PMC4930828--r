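#' Gastric acid secretion rate
#'
#' Saturable (Michaelis-Menten type) response of the acid glands in the upper
#' antrum wall to the dissolved food (protein, fat, carbohydrate) sensed near
#' the wall:
#' S = F21 * (s0 + Sum_i s_i c_i / (s' + Sum_i c_i)), scaled linearly by the
#' secretory functionality F(2)(1). At zero food concentration only the basal
#' term remains; at saturation by protein the total approaches the maximal
#' physiological rate s0 + s_protein. Water is co-secreted at a fixed
#' mass-rate ratio (`water` coupling) so the gland fluid composition is
#' constant.
#'
#' @param conc named vector or list with elements `protein`, `fat`,
#'   `carbohydrate`: near-wall mass concentrations rho1 alpha1 Y_i, kg/m^3.
#' @param params the `secretion$acid` block of a [gi_config()] (rates in kg/s
#'   regional totals).
#' @param F21 secretory functionality of the acid region, in [0, 1].
#' @return List with `acid` and `water` regional secretion rates, kg/s.
#' @export
#' @examples
#' acid_secretion(c(protein = 0, fat = 0, carbohydrate = 0))  # basal
acid_secretion <- function(conc, params = gi_config()$secretion$acid,
                           F21 = 1) {
  conc <- unlist(conc)[c("protein", "fat", "carbohydrate")]
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  if (F21 < 0 || F21 > 1) stop("functionality must lie in [0, 1]")
  tot <- sum(conc)
  stim <- sum(c(params$protein, params$fat, params$carbohydrate) * conc) /
    (params$half_sat + tot)
  s <- F21 * (params$basal + stim)
  list(acid = s, water = params$water * s)
}

#' Pepsin secretion rate
#'
#' Saturable response to the near-wall dissolved-protein concentration alone:
#' S = F21 * (s0 + s_max c3 / (s' + c3)).
#'
#' @param protein_conc near-wall protein mass concentration, kg/m^3.
#' @param params the `secretion$pepsin` block of a [gi_config()].
#' @param F21 secretory functionality of the acid region.
#' @return Regional pepsin secretion rate, kg/s.
#' @export
pepsin_secretion <- function(protein_conc,
                             params = gi_config()$secretion$pepsin, F21 = 1) {
  if (any(protein_conc < 0)) stop("concentration must be nonnegative")
  if (F21 < 0 || F21 > 1) stop("functionality must lie in [0, 1]")
  F21 * (params$basal + params$max * protein_conc /
           (params$half_sat + protein_conc))
}

#' Bicarbonate secretion rate
#'
#' Alkaline secretion in the lower antrum (l = 3), duodenal wall (l = 4) and
#' pancreatic inflow region (l = 5) responds to the near-wall acid
#' concentration (feedback: more acid elicits more bicarbonate):
#' S = F_l1 * (s0 + s_max c0 / (s' + c0)), with water co-secreted at the
#' region's fixed coupling ratio.
#'
#' @param acid_conc near-wall acid mass concentration rho1 alpha1 Y0, kg/m^3.
#' @param l wall region, 3, 4 or 5.
#' @param params the `secretion$bicarbonate` block of a [gi_config()].
#' @param F_l1 secretory functionality of region l.
#' @return List with `bicarbonate` and `water` regional rates, kg/s.
#' @export
bicarbonate_secretion <- function(acid_conc, l,
                                  params = gi_config()$secretion$bicarbonate,
                                  F_l1 = 1) {
  if (!(l %in% 3:5)) stop("bicarbonate secretion is defined for regions 3..5")
  if (any(acid_conc < 0)) stop("concentration must be nonnegative")
  if (F_l1 < 0 || F_l1 > 1) stop("functionality must lie in [0, 1]")
  p <- params[[paste0("r", l)]]
  s <- F_l1 * (p$basal + p$max * acid_conc / (p$half_sat + acid_conc))
  list(bicarbonate = s, water = p$water * s)
}

#' Chemical absorption flux through the tract wall
#'
#' Passive diffusion of the trace chemical (lead) into blood:
#' S = -F_l2 * s6 * (c6 - h6 * C6_blood), nonpositive whenever the cavity
#' concentration exceeds the blood-side equilibrium. Scaled linearly by the
#' absorptive functionality F(l)(2).
#'
#' @param chem_conc cavity mass concentration rho1 alpha1 Y6, kg/m^3.
#' @param params the `absorption` block of a [gi_config()].
#' @param F_l2 absorptive functionality of the region.
#' @return Volumetric sink kg/(m^3 s) (<= 0 when cavity exceeds blood).
#' @export
#' @examples
#' absorption_flux(1e-3)  # -3.34e-6
absorption_flux <- function(chem_conc, params = gi_config()$absorption,
                            F_l2 = 1) {
  if (F_l2 < 0 || F_l2 > 1) stop("functionality must lie in [0, 1]")
  -F_l2 * params$rate * (chem_conc - params$h * params$blood_conc)
}
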