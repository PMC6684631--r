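# Independent CO2-system oracle for cross-checking solve_speciation().
#
# Deliberately a separate implementation: constants re-typed from the
# published parameterizations, and the root found in a different way --
# instead of bisecting the alkalinity residual in pH at fixed DIC, this
# solver computes, at each trial pH, the DIC implied by the carbonate
# alkalinity (total alkalinity minus borate and water terms) and
# root-finds the implied-vs-target DIC mismatch with uniroot().

oracle_constants <- function(tC, S) {
  TK <- tC + 273.15
  K0 <- exp(93.4517 * 100 / TK - 60.2409 + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * TK / 100 +
                     0.0047036 * (TK / 100)^2))
  K1 <- 10^(-(3633.86 / TK - 61.2172 + 9.6777 * log(TK) - 0.011555 * S +
                0.0001152 * S^2))
  K2 <- 10^(-(471.78 / TK + 25.929 - 3.16967 * log(TK) - 0.01781 * S +
                0.0001122 * S^2))
  KB <- exp((-8966.90 - 2890.53 * S^0.5 - 77.942 * S + 1.728 * S^1.5 -
               0.0996 * S^2) / TK +
              148.0248 + 137.1942 * S^0.5 + 1.62142 * S +
              log(TK) * (-24.4344 - 25.085 * S^0.5 - 0.2474 * S) +
              0.053105 * S^0.5 * TK)
  KW <- exp(148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
              S^0.5 * (118.67 / TK - 5.977 + 1.0495 * log(TK)) -
              0.01615 * S)
  list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW)
}

oracle_pco2 <- function(alk, dic, tC = 25, S = 35,
                        bt = 0.0004157 * S / 35) {
  k <- oracle_constants(tC, S)
  implied_dic <- function(ph) {
    h <- 10^(-ph)
    ca <- alk - bt * k$KB / (k$KB + h) - k$KW / h + h   # carbonate alk
    # CA = DIC * (K1 h + 2 K1 K2) / (h^2 + K1 h + K1 K2)
    ca * (h^2 + k$K1 * h + k$K1 * k$K2) / (k$K1 * h + 2 * k$K1 * k$K2)
  }
  ph <- stats::uniroot(function(p) implied_dic(p) - dic,
                       c(3, 11.5), tol = 1e-12)$root
  h <- 10^(-ph)
  co2 <- dic * h^2 / (h^2 + k$K1 * h + k$K1 * k$K2)
  list(pH = ph, pco2 = co2 / k$K0 * 1e6)
}
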