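#' Nanopore geometry
#'
#' The pore is modelled as a cylinder through the full membrane stack: a
#' silicon nitride support plus a thin metal (gold) layer. `A = pi r^2` and
#' `V_total = A L` are derived.
#'
#' @param radius_nm Pore radius, nm.
#' @param length_nm Total pore length, nm (default 55).
#' @param metal_length_nm Metal-layer length, nm (default 5).
#' @return An object of class `"nanopore"` with SI fields `r_np`, `L`,
#'   `L_Au`, `A` (m^2) and `V_total` (m^3).
#' @export
#' @examples
#' nanopore(2.3)
nanopore <- function(radius_nm, length_nm = 55, metal_length_nm = 5) {
  r <- radius_nm * 1e-9
  L <- length_nm * 1e-9
  L_Au <- metal_length_nm * 1e-9
  if (!is.finite(r) || r <= 0) stop("pore radius must be positive", call. = FALSE)
  if (L_Au <= 0 || L_Au > L)
    stop("metal-layer length must satisfy 0 < L_Au <= L", call. = FALSE)
  A <- pi * r^2
  structure(list(r_np = r, L = L, L_Au = L_Au, A = A, V_total = A * L),
            class = "nanopore")
}

#' @export
print.nanopore <- function(x, ...) {
  cat(sprintf("<nanopore> r = %.3g nm, L = %.3g nm, L_Au = %.3g nm\n",
              x$r_np * 1e9, x$L * 1e9, x$L_Au * 1e9))
  invisible(x)
}

#' Analyte description
#'
#' A translocating analyte of radius `r_analyte` and signed valence charge
#' `z_analyte`. When `use_stokes` is `TRUE` the volumetric occlusion is
#' computed from the Stokes radius `r_analyte + water_layer` (a bound water
#' shell); the bare radius is used otherwise, as is appropriate for larger
#' nanoparticles.
#'
#' @param name Label.
#' @param radius_nm Bare analyte radius, nm (may be 0 for a null analyte).
#' @param valence Signed integer valence charge (0 allowed: neutral analyte).
#' @param use_stokes Use the Stokes radius for the occluded volume?
#' @param water_layer_nm Water-layer thickness, nm (default 0.14, one water
#'   molecule radius).
#' @return An object of class `"pore_analyte"` with SI fields, including the
#'   effective radius `r_eff` and occluded volume `V_analyte`.
#' @export
#' @examples
#' analyte("ceria", 1.27, 112, use_stokes = FALSE)
analyte <- function(name, radius_nm, valence, use_stokes = TRUE,
                    water_layer_nm = 0.14) {
  r <- radius_nm * 1e-9
  w <- water_layer_nm * 1e-9
  if (!is.finite(r) || r < 0) stop("analyte radius must be >= 0", call. = FALSE)
  if (valence != round(valence)) stop("valence must be an integer", call. = FALSE)
  r_eff <- if (use_stokes && r > 0) r + w else r
  structure(list(name = name, r_analyte = r, z_analyte = as.integer(valence),
                 use_stokes = isTRUE(use_stokes), water_layer = w,
                 r_eff = r_eff, V_analyte = 4 / 3 * pi * r_eff^3),
            class = "pore_analyte")
}

#' @export
print.pore_analyte <- function(x, ...) {
  cat(sprintf("<analyte> %s: r = %.3g nm (%s), z = %+d\n", x$name,
              x$r_analyte * 1e9,
              if (x$use_stokes) sprintf("Stokes %.3g nm", x$r_eff * 1e9)
              else "bare", x$z_analyte))
  invisible(x)
}
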