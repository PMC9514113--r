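# Small shared fixtures, built in code.

fix_panel <- function(half_life = c(30, 20, 0.3),
                      names = paste0("P", seq_along(half_life))) {
  peptide_panel(names,
                rep(c("SVASTITGV", "VMAGDIYSV", "STAPPVHNV",
                      "ALADGVQKV", "LLGATCMFV", "SVFAGVVGV",
                      "ALFDGDPHL", "YVDPVITSI", "LAALPHSCL"),
                    length.out = length(half_life)),
                half_life = half_life)
}

fix_schedule <- function(D = 300, transit = 30, p = 10)
  build_arrival_schedule(D, transit_time = transit, t_first_departure = 6,
                         p = p)

fix_pool <- function(phi = 2e-5, bio = biophysical_params())
  cognate_pool(phi, bio = bio)

small_scenario <- function(...) synthetic_scenario(...)
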