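#' Five-band reflectance conventions
#'
#' The package works on five-band multispectral reflectance with nominal
#' central wavelengths 475 (blue), 560 (green), 668 (red), 717 (red edge)
#' and 842 nm (near infrared). Bands are always ordered blue, green, red,
#' rededge, nir.
#'
#' @return Character vector of the five canonical band names.
#' @export
band_names <- function() c("blue", "green", "red", "rededge", "nir")

# narrowband literature wavelength -> sensor band; fixed configuration table
.band_map <- c(
  "445" = "blue", "475" = "blue",
  "531" = "green", "550" = "green", "560" = "green",
  "668" = "red", "670" = "red",
  "700" = "rededge", "705" = "rededge", "710" = "rededge", "717" = "rededge",
  "750" = "nir", "800" = "nir", "842" = "nir", "850" = "nir"
)

#' Map a narrowband wavelength to a sensor band
#'
#' Many chlorophyll indices are defined on narrowband wavelengths (for
#' example mND705 uses 445, 705 and 750 nm) while the sensor provides only
#' five broad bands. This function resolves a requested wavelength to the
#' sensor band whose configured mapping covers it, using a fixed table.
#'
#' @param wavelength_nm Requested central wavelength in nanometres.
#'   Must lie within the sensor range 400-900 nm.
#' @return One of `band_names()`.
#' @examples
#' resolve_band(705) # "rededge"
#' resolve_band(445) # "blue"
#' @export
resolve_band <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1L,
            is.finite(wavelength_nm))
  if (wavelength_nm < 400 || wavelength_nm > 900) {
    stop("wavelength outside sensor range (400-900 nm): ", wavelength_nm)
  }
  key <- as.character(round(wavelength_nm))
  if (!key %in% names(.band_map)) {
    stop("no sensor band configured for wavelength ", wavelength_nm,
         " nm; mapped wavelengths: ", paste(names(.band_map), collapse = ", "))
  }
  unname(.band_map[key])
}

#' Construct a validated five-band reflectance vector
#'
#' @param blue,green,red,rededge,nir Reflectance fractions in [0, 1].
#' @return A named numeric vector of class `band_set`.
#' @examples
#' band_set(0.04, 0.08, 0.05, 0.22, 0.45)
#' @export
band_set <- function(blue, green, red, rededge, nir) {
  b <- c(blue = blue, green = green, red = red, rededge = rededge, nir = nir)
  validate_bands(b, band_names())
  structure(b, class = "band_set")
}

# Validate that `bands` (named vector or list) carries the `required` bands
# as finite reflectance fractions in [0, 1].
validate_bands <- function(bands, required) {
  b <- unlist(bands)
  missing_bands <- setdiff(required, names(b))
  if (length(missing_bands)) {
    stop("missing band(s): ", paste(missing_bands, collapse = ", "))
  }
  v <- b[required]
  if (!all(is.finite(v))) {
    stop("non-finite reflectance in band(s): ",
         paste(required[!is.finite(v)], collapse = ", "))
  }
  if (any(v < 0 | v > 1)) {
    stop("reflectance outside [0, 1] in band(s): ",
         paste(required[v < 0 | v > 1], collapse = ", "))
  }
  invisible(v)
}

#' @export
print.band_set <- function(x, ...) {
  cat("<band_set>", paste(sprintf("%s=%.4f", names(x), unclass(x)),
                          collapse = " "), "\n")
  invisible(x)
}
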