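# shared lactose-at-25C defaults used across the suite
lactose_margules <- function() margules_model(-5.8)
lactose_mut <- function(slope = 0) mutarotation_model(1.60, slope = slope, k_alpha = 0.64)
lactose_sle <- function(slope = 0) {
  solubility_model(0.00494, lactose_margules(), lactose_mut(slope))
}

# independent hand computation of the composition example used in several tests
hand_xw_for_loading <- function(loading, M_l = 342.30, M_w = 18.015) {
  n_w <- 1 / M_w
  n_l <- loading / M_l
  n_w / (n_w + n_l)
}
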