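# Seawater CO2-system speciation from total alkalinity and DIC.
#
# Alkalinity is approximated by its carbonate + borate + water terms:
#   ALK = [HCO3-] + 2[CO3^2-] + [B(OH)4-] + [OH-] - [H+]
# which is adequate for the deep-ocean / global-budget questions the
# package addresses (no phosphate, silicate or fluoride terms).
# Equilibrium constants are on the total pH scale, mol/kg-SW:
#   K0  Weiss (1974); K1, K2 Lueker et al. (2000); KB Dickson (1990);
#   KW  Millero (1995); total boron from salinity, Uppstrom (1974).

#' Define a seawater carbonate-system state
#'
#' @param alkalinity Total alkalinity (mol/kg), > 0.
#' @param dic Dissolved inorganic carbon, HCO3- + CO3^2- + CO2(aq)
#'   (mol/kg), >= 0.
#' @param temperature Temperature (degrees C).
#' @param salinity Practical salinity, in [0, 45].
#' @param total_boron Total boron (mol/kg); default scales with salinity
#'   (Uppstrom 1974: 0.0004157 * S / 35).
#' @return An object of class `seawater_state`.
#' @export
#' @examples
#' seawater_state(2300e-6, 2000e-6, 25, 35)
seawater_state <- function(alkalinity, dic, temperature = 25,
                           salinity = 35, total_boron = NULL) {
  stopifnot(alkalinity > 0, dic >= 0,
            salinity >= 0, salinity <= 45)
  if (is.null(total_boron)) total_boron <- 0.0004157 * salinity / 35
  structure(list(alkalinity = alkalinity, dic = dic,
                 temperature = temperature, salinity = salinity,
                 total_boron = total_boron),
            class = "seawater_state")
}

#' Equilibrium constants for the aqueous CO2 system
#'
#' Returns K0 (mol/kg/atm), K1, K2 (Lueker et al. 2000, total scale),
#' KB (Dickson 1990), and KW (Millero 1995) at the given temperature and
#' salinity. The constant set is a documented configuration choice and is
#' recorded in solver output metadata.
#'
#' @param temperature Degrees C.
#' @param salinity Practical salinity.
#' @return Named list `K0`, `K1`, `K2`, `KB`, `KW`, plus a `set` tag.
#' @export
co2_constants <- function(temperature, salinity) {
  TK <- temperature + 273.15
  S <- salinity
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
             1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * log(TK) +
    0.053105 * sqrt(S) * TK
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S
  list(K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
       KB = exp(lnKB), KW = exp(lnKW),
       set = "K0 Weiss74; K1K2 Lueker00 (total); KB Dickson90; KW Millero95")
}

# Alkalinity implied by [H+] h at fixed DIC (carbonate+borate+water terms)
alk_of_h <- function(h, dic, bt, k) {
  denom <- h * h + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  hco3 + 2 * co3 + bt * k$KB / (k$KB + h) + k$KW / h - h
}

#' Solve CO2-system speciation from alkalinity and DIC
#'
#' Finds the [H+] root of the alkalinity balance
#' ALK = [HCO3-] + 2[CO3^2-] + [B(OH)4-] + [OH-] - [H+]
#' by bisection on pH in [2, 12] (total scale), iterated to machine
#' precision so species sums and alkalinity reconstruction hold to ~1e-12
#' relative. pCO2 = [CO2(aq)] / K0.
#'
#' @param state A [seawater_state()].
#' @return A list of class `carbonate_speciation` with elements `pH`
#'   (total scale), `co2_aq`, `hco3`, `co3` (mol/kg), `pco2` (micro-atm),
#'   and `constants` (the constant set used).
#' @export
#' @examples
#' sp <- solve_speciation(seawater_state(2300e-6, 2000e-6, 25, 35))
#' sp$pco2
solve_speciation <- function(state) {
  stopifnot(inherits(state, "seawater_state"))
  k <- co2_constants(state$temperature, state$salinity)
  bt <- state$total_boron
  dic <- state$dic
  alk <- state$alkalinity

  if (dic == 0) {
    # carbonate-free: check alkalinity attainable from borate+water alone
    f <- function(ph) bt * k$KB / (k$KB + 10^(-ph)) +
      k$KW / 10^(-ph) - 10^(-ph) - alk
    if (f(12) < 0)
      abort("no solution: alkalinity exceeds borate+water capacity at dic = 0")
  }

  resid <- function(ph) alk_of_h(10^(-ph), dic, bt, k) - alk
  lo <- 2; hi <- 12
  flo <- resid(lo); fhi <- resid(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    abort("no solution: alkalinity balance root not bracketed on pH in [2, 12]")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (fm == 0) { lo <- hi <- mid; break }
    if (flo * fm < 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
    if ((hi - lo) < 1e-14) break
  }
  ph <- (lo + hi) / 2
  h <- 10^(-ph)
  denom <- h * h + k$K1 * h + k$K1 * k$K2
  co2_aq <- if (dic == 0) 0 else dic * h * h / denom
  hco3 <- if (dic == 0) 0 else dic * k$K1 * h / denom
  co3 <- if (dic == 0) 0 else dic * k$K1 * k$K2 / denom
  structure(list(pH = ph, co2_aq = co2_aq, hco3 = hco3, co3 = co3,
                 pco2 = co2_aq / k$K0 * 1e6,
                 constants = k$set),
            class = "carbonate_speciation")
}

#' @export
print.carbonate_speciation <- function(x, ...) {
  cat(sprintf("<carbonate_speciation> pH %.4f (total), pCO2 %.1f uatm\n",
              x$pH, x$pco2))
  cat(sprintf("  CO2(aq) %.2f, HCO3- %.1f, CO3^2- %.1f umol/kg\n",
              x$co2_aq * 1e6, x$hco3 * 1e6, x$co3 * 1e6))
  invisible(x)
}

#' pCO2 response to a fractional alkalinity increase
#'
#' Solves the speciation at the baseline state and again with alkalinity
#' increased by `alk_increase_fraction` (DIC held fixed), and reports the
#' ratio pCO2_before / pCO2_after (>= 1 for any positive increase).
#'
#' The default baseline (ALK 2300, DIC 2000 umol/kg, 25 C, S 35) is a
#' documented representative present-day surface-ocean state, not a value
#' taken from any single observation.
#'
#' @param state Baseline [seawater_state()].
#' @param alk_increase_fraction Fractional alkalinity increase (>= 0),
#'   e.g. 0.25 for a 25 percent increase.
#' @return A list with `ratio`, and the `before`/`after` speciations.
#' @export
#' @examples
#' pco2_alkalinity_response(alk_increase_fraction = 0.25)$ratio
pco2_alkalinity_response <- function(state = seawater_state(2300e-6, 2000e-6,
                                                            25, 35),
                                     alk_increase_fraction) {
  stopifnot(alk_increase_fraction >= 0)
  before <- solve_speciation(state)
  after_state <- state
  after_state$alkalinity <- state$alkalinity * (1 + alk_increase_fraction)
  after <- solve_speciation(after_state)
  list(ratio = before$pco2 / after$pco2, before = before, after = after)
}
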