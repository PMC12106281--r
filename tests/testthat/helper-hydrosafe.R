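# shared fixtures: reference-species parameter sets used across tests

euclea_params <- function()
  species_params("Euclea", a = -2.23, b = -8.02,
                 psi_osm_ft = 2.92, eps = 12.43)

boscia_params <- function()
  species_params("Boscia", a = -3.34, b = -6.39,
                 psi_osm_ft = 1.37, eps = 4.61)

schotia_params <- function()
  species_params("Schotia", a = -4.03, b = -4.64,
                 psi_osm_ft = 0.93, eps = 3.87)

searsia_params <- function()
  species_params("Searsia", a = -10.07, b = -8.09,
                 psi_osm_ft = 2.17, eps = 6.14)

# noiseless model-evaluated trace on a psi grid (plain data frame)
model_trace <- function(a, b, n = 40) {
  psi <- seq(px(a, b, 99.5), px(a, b, 0.5), length.out = n)
  data.frame(psi_mpa = psi, cum_pct = sigmoid_pe(psi, a, b))
}

# generator -> OV quantification -> trace, with the synthetic-friendly
# filter (single-pixel events)
synthetic_trace <- function(params, seed, n_pixels = 2000) {
  camp <- gen_embolism_campaign(params,
                                gen_config(seed = seed,
                                           n_pixels = n_pixels))
  ov_quantify(camp$events, camp$psychrometer, min_size = 1,
              max_size_quantile = 1)
}
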