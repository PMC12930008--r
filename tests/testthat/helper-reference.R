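# Reference parameter set used throughout the tests: disposition chosen so
# the analytic single-dose GM AUC_inf is 100/5.151 = 19.414 mg*h/L and the
# terminal half-life ln(2)*97/5.151 = 13.053 h, with ka = 1.2 1/h.
ref_compound <- function(iiv = list(cl_f = 0, v_f = 0, ka = 0)) {
  compound_profile(
    name = "ref", mol_weight = 425.75, logP = 3.0, pKa = 1.6,
    ionization_class = "monoprotic_base", fu_plasma = 0.24,
    cl_f = 5.151, v_f = 97.0, ka = 1.2, f_abs = 1, iiv_cv = iiv)
}

ref_auc_inf <- 100 / 5.151          # analytic F*D/(CL/F)
ref_ke <- 5.151 / 97.0
ref_t_half <- log(2) / ref_ke

# the clinical sampling schedules
plasma_grid <- c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 24)
milk_grid <- c(0, 2, 4, 6, 12, 24)

# a generic moderately lipophilic weak base with pKa near milk pH, used for
# ion-trapping tests where pH sensitivity must be visible
base_compound <- function(pKa = 8) {
  compound_profile(
    name = "baseX", mol_weight = 300, logP = 2, pKa = pKa,
    ionization_class = "monoprotic_base", fu_plasma = 0.5,
    cl_f = 10, v_f = 100, ka = 1)
}
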