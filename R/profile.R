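# Porewater profile container and delimited-text I/O.

#' Create a porewater concentration-depth profile
#'
#' Depth-indexed porewater concentrations with the porosity and temperature
#' context needed for rate inversion. Depths are meters below seafloor,
#' positive downward, 0 at the sediment-water interface.
#'
#' @param species One of `"O2"`, `"SO4"`, `"DIC"`.
#' @param depth Strictly increasing depths (m), >= 4 samples.
#' @param conc Concentrations (mol per m3 of porewater), >= 0.
#' @param porosity Porosity at each depth, in (0, 1]. Scalars are recycled.
#' @param temperature Temperature at each depth (degrees C). Scalars are
#'   recycled (constant-temperature sites are permitted).
#' @param conc_sd Per-sample measurement SD (mol/m3); scalar or vector;
#'   default 0.
#' @return An object of class `porewater_profile` (also a data.frame).
#' @export
porewater_profile <- function(species = c("O2", "SO4", "DIC"),
                              depth, conc, porosity, temperature,
                              conc_sd = 0) {
  species <- match.arg(species)
  n <- length(depth)
  if (n < 4) abort("a porewater profile needs at least 4 samples")
  if (any(diff(depth) <= 0)) abort("depth must be strictly increasing")
  porosity <- rep_len(porosity, n)
  temperature <- rep_len(temperature, n)
  conc_sd <- rep_len(conc_sd, n)
  stopifnot(length(conc) == n)
  if (any(conc < 0)) abort("concentrations must be non-negative")
  if (any(porosity <= 0 | porosity > 1)) abort("porosity must be in (0, 1]")
  if (any(conc_sd < 0)) abort("conc_sd must be non-negative")
  out <- data.frame(depth = depth, conc = conc, porosity = porosity,
                    temperature = temperature, conc_sd = conc_sd)
  attr(out, "species") <- species
  class(out) <- c("porewater_profile", "data.frame")
  out
}

#' Write a porewater profile as CSV
#'
#' Header: `depth_m, conc_mol_m3, porosity, temp_C, conc_sd_mol_m3`.
#' The species is recorded as a `#species:` comment on the first line.
#'
#' @param profile A [porewater_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "porewater_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#species: ", attr(profile, "species")), con)
  df <- data.frame(depth_m = profile$depth,
                   conc_mol_m3 = profile$conc,
                   porosity = profile$porosity,
                   temp_C = profile$temperature,
                   conc_sd_mol_m3 = profile$conc_sd)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a porewater profile CSV
#'
#' @param path File written by [write_profile_csv()] (or any CSV with the
#'   same header).
#' @param species Species override; by default taken from the `#species:`
#'   header comment, falling back to `"SO4"`.
#' @return A [porewater_profile()].
#' @export
read_profile_csv <- function(path, species = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(species)) {
    species <- if (grepl("^#species:", first))
      trimws(sub("^#species:", "", first)) else "SO4"
  }
  df <- utils::read.csv(path, comment.char = "#")
  porewater_profile(species, df$depth_m, df$conc_mol_m3,
                    df$porosity, df$temp_C, df$conc_sd_mol_m3)
}
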