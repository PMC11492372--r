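#' Shipped ion and small-analyte property table
#'
#' Molecular weights, crystallographic ionic radii and valences for the
#' electrolyte ions (Li, Na, K, F, Cl) and the four small-molecule validation
#' analytes (oxalic acid OA, hydroquinone HQ, ascorbic acid AA, citric acid
#' CA). Mobilities are limiting ionic mobilities from standard tables
#' (mu = lambda0 / F); the small molecules ship without a mobility and require
#' explicit entry where one is needed.
#'
#' @param path Optional path to a user CSV with the same columns
#'   (`name`, `molecular_weight_g_per_mol`, `radius_nm`, `valence`,
#'   `mobility_m2_per_Vs`).
#' @return A tibble with one row per species.
#' @export
#' @examples
#' ion_table()
ion_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ion_table.csv", package = "poresignal")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Define a single ionic species
#'
#' @param name Species label.
#' @param molecular_weight Molecular weight, g/mol.
#' @param radius_nm Ionic radius, nm.
#' @param valence Signed integer valence charge (non-zero).
#' @param mobility Mobility, m^2/V/s, or `NA` if unknown.
#' @return A one-row tibble describing the species (radius stored in m).
#' @export
#' @examples
#' ion_species("Na", 22.99, 0.116, 1, 5.19e-8)
ion_species <- function(name, molecular_weight, radius_nm, valence,
                        mobility = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be positive", call. = FALSE)
  if (!is.finite(radius_nm) || radius_nm <= 0)
    stop("radius must be positive", call. = FALSE)
  if (valence == 0 || valence != round(valence))
    stop("valence must be a non-zero signed integer", call. = FALSE)
  if (!is.na(mobility) && mobility <= 0)
    stop("mobility must be positive when set", call. = FALSE)
  tibble::tibble(
    name = name,
    molecular_weight = as.numeric(molecular_weight),
    radius = radius_nm * 1e-9,
    valence = as.integer(valence),
    mobility = as.numeric(mobility)
  )
}

#' Look up a species from the shipped ion table
#'
#' @param name Species label present in [ion_table()].
#' @param table Ion table to look in, defaults to the shipped one.
#' @return A one-row species tibble as from [ion_species()].
#' @export
ion <- function(name, table = ion_table()) {
  row <- table[table$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown species '", name, "'; add it to the ion table", call. = FALSE)
  ion_species(row$name, row$molecular_weight_g_per_mol, row$radius_nm,
              row$valence, row$mobility_m2_per_Vs)
}

#' Define an electrolyte solution
#'
#' An electrolyte is a set of ionic species with molar concentrations. The
#' composition must be electroneutral (sum of valence times concentration
#' equal to zero within 1e-12 relative tolerance).
#'
#' @param ... Named concentrations in mol/L, e.g. `electrolyte(Na = 1e-3,
#'   F = 1e-3)`; names are looked up in `table`. Alternatively pass a single
#'   `species` tibble (rows as from [ion_species()]) plus a `conc` vector.
#' @param species Optional species tibble, bypassing the table lookup.
#' @param conc Concentrations (mol/L) matching the rows of `species`.
#' @param temperature Temperature in K (default 298).
#' @param table Ion table used to resolve names.
#' @return An object of class `"electrolyte"`: a list with a `species`
#'   tibble (name, molecular_weight, radius, valence, mobility, conc) and
#'   `temperature`.
#' @export
#' @examples
#' electrolyte(Na = 1e-3, F = 1e-3)
electrolyte <- function(..., species = NULL, conc = NULL, temperature = 298,
                        table = ion_table()) {
  if (is.null(species)) {
    conc <- c(...)
    if (length(conc) < 1L || is.null(names(conc)))
      stop("supply named concentrations, e.g. electrolyte(Na = 1e-3, F = 1e-3)",
           call. = FALSE)
    species <- dplyr::bind_rows(lapply(names(conc), ion, table = table))
  } else {
    species <- dplyr::bind_rows(
      lapply(seq_len(nrow(species)), function(i) species[i, ])
    )
  }
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("every concentration must be positive", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  net <- sum(species$valence * conc)
  scale <- sum(abs(species$valence) * conc)
  if (abs(net) > 1e-12 * scale)
    stop("electrolyte is not electroneutral: sum(z_i * c_i) = ",
         signif(net, 4), call. = FALSE)
  species$conc <- conc
  structure(list(species = species, temperature = temperature),
            class = "electrolyte")
}

#' @export
print.electrolyte <- function(x, ...) {
  cat("<electrolyte> T =", x$temperature, "K\n")
  print(x$species)
  invisible(x)
}

#' Rescale an electrolyte to a new total concentration
#'
#' Keeps the composition ratios fixed and rescales every concentration so the
#' total ion concentration equals `total` (mol/L). Used for concentration
#' sweeps.
#'
#' @param solution An [electrolyte()].
#' @param total Target total ion concentration, mol/L.
#' @return A rescaled `electrolyte`.
#' @export
rescale_electrolyte <- function(solution, total) {
  stopifnot(inherits(solution, "electrolyte"), total > 0)
  f <- total / sum(solution$species$conc)
  electrolyte(species = solution$species[, c("name", "molecular_weight",
                                             "radius", "valence", "mobility")],
              conc = solution$species$conc * f,
              temperature = solution$temperature)
}

# Debye coefficients A (log10, L^1/2 mol^-1/2) and B (m^-1 L^1/2 mol^-1/2)
# from physical constants; eps_r of water held fixed.
debye_AB <- function(temperature) {
  eps <- .eps_r_water * .eps0
  kT <- .k_B * temperature
  B <- sqrt(2 * .e_charge^2 * .N_Av * 1000 / (eps * kT))
  A <- B * .e_charge^2 / (log(10) * 8 * pi * eps * kT)
  list(A = A, B = B)
}

# Ionic strength in mol/L.
ionic_strength <- function(solution) {
  sp <- solution$species
  0.5 * sum(sp$conc * sp$valence^2)
}

# Average ion radius (m); unweighted mean by default, optionally
# concentration-weighted.
average_radius <- function(solution, weighting = c("unweighted", "concentration")) {
  weighting <- match.arg(weighting)
  sp <- solution$species
  if (weighting == "unweighted") mean(sp$radius)
  else stats::weighted.mean(sp$radius, sp$conc)
}

#' Debye activity coefficient
#'
#' Activity coefficient of each species from Debye theory at the solution's
#' ionic strength: `log10 f_i = -A z_i^2 sqrt(I) / (1 + B r sqrt(I))`, with
#' `I = 1/2 sum c_i z_i^2` in mol/L, `r` the average ion radius of the
#' solution, and `A`, `B` computed from physical constants at the solution
#' temperature. Valence enters only through even powers, so `f` is invariant
#' under flipping the sign of every valence, and `f` is in (0, 1], tending to
#' 1 at infinite dilution.
#'
#' @param solution An [electrolyte()].
#' @param species Optional species index (or name); when omitted, a vector of
#'   coefficients for all species is returned.
#' @param radius_weighting How the average ion radius is formed:
#'   `"unweighted"` (default) or `"concentration"`.
#' @return Dimensionless activity coefficient(s) in (0, 1].
#' @export
#' @examples
#' activity_coefficient(electrolyte(Na = 0.1, F = 0.1))
activity_coefficient <- function(solution, species = NULL,
                                 radius_weighting = "unweighted") {
  stopifnot(inherits(solution, "electrolyte"))
  sp <- solution$species
  if (is.character(species)) species <- match(species, sp$name)
  if (!is.null(species) &&
      (is.na(species) || species < 1 || species > nrow(sp)))
    stop("species index out of range", call. = FALSE)
  ab <- debye_AB(solution$temperature)
  I <- ionic_strength(solution)
  r <- average_radius(solution, radius_weighting)
  log10f <- -ab$A * sp$valence^2 * sqrt(I) / (1 + ab$B * r * sqrt(I))
  f <- 10^log10f
  if (is.null(species)) f else f[[species]]
}

#' Majority ion of an electrolyte
#'
#' The majority ion within the nanopore is the species with the smallest
#' ionic radius (size selection: the smaller ion enters the confined pore
#' preferentially). An exact radius tie is ambiguous and must be resolved by
#' the `override` argument, which is honoured and reported with a message.
#'
#' @param solution An [electrolyte()] with at least two species.
#' @param override Optional species name forced to be the majority ion.
#' @return A one-row species tibble (with its `conc` column).
#' @export
#' @examples
#' majority_ion(electrolyte(K = 1e-3, Cl = 1e-3))$name  # "K"
majority_ion <- function(solution, override = NULL) {
  stopifnot(inherits(solution, "electrolyte"))
  sp <- solution$species
  if (nrow(sp) < 2L) stop("need at least two species", call. = FALSE)
  if (!is.null(override)) {
    i <- match(override, sp$name)
    if (is.na(i)) stop("override '", override, "' not in solution", call. = FALSE)
    message("majority ion overridden to ", override)
    return(sp[i, ])
  }
  rmin <- min(sp$radius)
  cand <- which(sp$radius == rmin)
  if (length(cand) > 1L)
    stop("ambiguous majority ion: species ",
         paste(sp$name[cand], collapse = ", "),
         " share the smallest radius; set `override`", call. = FALSE)
  sp[cand, ]
}

# Smallest-radius species of polarity opposite to the majority ion; the
# minority partner used by the partition coefficient.
minority_ion <- function(solution, majority) {
  sp <- solution$species
  opp <- sp[sign(sp$valence) != sign(majority$valence), , drop = FALSE]
  if (nrow(opp) == 0L) stop("no counter-ion present", call. = FALSE)
  opp[which.min(opp$radius), ]
}

#' Ionic activities inside and outside the pore
#'
#' The reservoir activity sums `a_i = c_i f_i` over all ions; the nanopore
#' activity sums only the ions sharing the majority ion's polarity (the pore
#' is charge-selective in the baseline state).
#'
#' @param solution An [electrolyte()].
#' @param majority_override Optional majority-ion override name.
#' @return A list with `a_nanopore` and `a_reservoir`, both mol/L.
#' @export
#' @examples
#' ionic_activities(electrolyte(Na = 1e-3, F = 1e-3))
ionic_activities <- function(solution, majority_override = NULL) {
  stopifnot(inherits(solution, "electrolyte"))
  sp <- solution$species
  if (nrow(sp) == 0L) stop("empty solution", call. = FALSE)
  f <- activity_coefficient(solution)
  a <- sp$conc * f
  maj <- majority_ion(solution, override = majority_override)
  same <- sign(sp$valence) == sign(maj$valence)
  list(a_nanopore = sum(a[same]), a_reservoir = sum(a))
}

#' Knudsen-ratio partition coefficient
#'
#' Size-partition factor of the baseline state,
#' `P_bs = (D_Kn,maj / D_Kn,min) * (L_C / r_np)`, with the ratio of Knudsen
#' diffusion coefficients implemented through the ionic radii
#' (`D_Kn,maj / D_Kn,min = r_min / r_maj`; the smaller ion diffuses faster in
#' confinement) and `L_C` the characteristic length of the system (1 nm).
#'
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param L_C Characteristic length, m.
#' @param majority_override Optional majority-ion override name.
#' @return Dimensionless partition coefficient.
#' @export
#' @examples
#' partition_coefficient(electrolyte(Na = 1e-3, F = 1e-3), nanopore(2.3))
partition_coefficient <- function(solution, pore,
                                  L_C = model_constants()$L_C,
                                  majority_override = NULL) {
  stopifnot(inherits(solution, "electrolyte"), inherits(pore, "nanopore"))
  if (L_C <= 0) stop("L_C must be positive", call. = FALSE)
  maj <- majority_ion(solution, override = majority_override)
  mino <- minority_ion(solution, maj)
  if (mino$radius <= 0) stop("minority radius must be positive", call. = FALSE)
  (mino$radius / maj$radius) * (L_C / pore$r_np)
}
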