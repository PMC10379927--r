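#' Define an analyte for the catalog
#'
#' An analyte definition couples the identity of a compound (name, molecular
#' weight, expected deprotonated ion m/z for reporting) with its chromatographic
#' retention time and a reference UV absorbance profile over 200--400 nm. The
#' reference profile is what peak-purity assessment compares observed spectra
#' against.
#'
#' @param name Analyte label, e.g. `"AnAc 15:3"`.
#' @param retention_time Expected apex retention time in minutes; must be > 0.
#' @param molecular_weight Molecular weight in g/mol; must be > 0.
#' @param expected_mz Expected `[M-H]-` m/z in Da. Stored for reporting only;
#'   no mass-spectral processing is performed.
#' @param uv_profile A [uv_spectrum] giving the reference absorbance profile.
#' @return An object of class `analyte_def`.
#' @seealso [anac_catalog()] for the default anacardic-acid catalog.
#' @export
analyte_def <- function(name, retention_time, molecular_weight,
                        expected_mz = NA_real_, uv_profile = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(retention_time) || retention_time <= 0)
    stop("retention_time must be a positive number of minutes")
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be positive (g/mol)")
  if (is.null(uv_profile))
    uv_profile <- make_uv_spectrum(c(247, 310), c(16, 28), c(1, 0.45))
  stopifnot(inherits(uv_profile, "uv_spectrum"))
  if (any(uv_profile$values < 0) || !any(uv_profile$values > 0))
    stop("uv_profile must be non-negative with at least one positive value")
  structure(
    list(name = name, retention_time = retention_time,
         molecular_weight = molecular_weight, expected_mz = expected_mz,
         uv_profile = uv_profile),
    class = "analyte_def")
}

#' Default anacardic-acid catalog
#'
#' The three anacardic acids quantified in cashew peduncle: the triene (15:3),
#' diene (15:2) and monoene (15:1), i.e. C15 alkyl side chains with 3, 2 and 1
#' C=C unsaturations. Under isocratic reversed-phase (C18) conditions the most
#' unsaturated (most polar) species elutes first, so retention increases from
#' 15:3 to 15:1. Expected `[M-H]-` ions are 341.2079, 343.2228 and 345.2405 Da.
#' All three share the salicylic-acid chromophore, so the default reference UV
#' profiles are identical (absorbance bands near 247 and 310 nm); quantification
#' is monitored at 280 nm.
#'
#' Retention times are representative of a 30-min isocratic C18 separation; on
#' another column the catalog should be rebuilt with [analyte_def()].
#'
#' @return A list of three [analyte_def()] objects named `"AnAc 15:3"`,
#'   `"AnAc 15:2"`, `"AnAc 15:1"`.
#' @export
anac_catalog <- function() {
  profile <- make_uv_spectrum(c(247, 310), c(16, 28), c(1, 0.45))
  list(
    `AnAc 15:3` = analyte_def("AnAc 15:3", retention_time = 7.9,
                              molecular_weight = 342.21, expected_mz = 341.2079,
                              uv_profile = profile),
    `AnAc 15:2` = analyte_def("AnAc 15:2", retention_time = 10.6,
                              molecular_weight = 344.23, expected_mz = 343.2228,
                              uv_profile = profile),
    `AnAc 15:1` = analyte_def("AnAc 15:1", retention_time = 14.8,
                              molecular_weight = 346.25, expected_mz = 345.2405,
                              uv_profile = profile))
}

#' Construct a UV spectrum
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param values Absorbance values (arbitrary scale), same length.
#' @return An object of class `uv_spectrum`: a list with `wavelengths` and
#'   `values`.
#' @export
uv_spectrum <- function(wavelengths, values) {
  stopifnot(length(wavelengths) == length(values),
            is.numeric(wavelengths), is.numeric(values))
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values)),
            class = "uv_spectrum")
}

#' Build a reference UV spectrum from Gaussian absorbance bands
#'
#' Sums Gaussian bands on a wavelength grid and rescales so the maximum is 1.
#' Used to construct reference profiles for synthetic analytes and purity tests.
#'
#' @param band_centers Band centers in nm (within 200--400).
#' @param band_widths Band SD widths in nm, same length.
#' @param band_weights Relative band weights, same length.
#' @param grid Strictly increasing wavelength grid in nm within `[200, 400]`;
#'   defaults to integer nm 200..400.
#' @return A [uv_spectrum] with unit maximum.
#' @examples
#' s <- make_uv_spectrum(280, 15, 1)
#' s$wavelengths[which.max(s$values)]  # 280
#' @export
make_uv_spectrum <- function(band_centers, band_widths, band_weights,
                             grid = 200:400) {
  n <- length(band_centers)
  if (n == 0L) stop("at least one absorbance band is required")
  if (length(band_widths) != n || length(band_weights) != n)
    stop("band_centers, band_widths and band_weights must have the same length")
  if (any(band_widths <= 0)) stop("band widths must be positive")
  if (any(grid < 200) || any(grid > 400))
    stop("wavelength grid must lie within [200, 400] nm")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  v <- rep(0, length(grid))
  for (i in seq_len(n))
    v <- v + band_weights[i] * exp(-0.5 * ((grid - band_centers[i]) / band_widths[i])^2)
  m <- max(v)
  if (m > 0) v <- v / m
  uv_spectrum(grid, v)
}

#' Cosine similarity between two spectra
#'
#' The spectral-similarity measure used for peak purity: the cosine of the angle
#' between the two absorbance vectors after restriction to a common wavelength
#' range. Both spectra must share the same wavelength grid on that range.
#'
#' @param a,b [uv_spectrum] objects on the same grid.
#' @param range Optional `c(lo, hi)` nm window to restrict to (e.g.
#'   `c(220, 400)` for purity assessment).
#' @return Cosine similarity in `[-1, 1]`; 0 if either vector is all-zero.
#' @export
cosine_similarity <- function(a, b, range = NULL) {
  stopifnot(inherits(a, "uv_spectrum"), inherits(b, "uv_spectrum"))
  wa <- a$wavelengths; wb <- b$wavelengths
  if (!is.null(range)) {
    ia <- wa >= range[1] & wa <= range[2]
    ib <- wb >= range[1] & wb <= range[2]
  } else {
    ia <- rep(TRUE, length(wa)); ib <- rep(TRUE, length(wb))
  }
  if (sum(ia) != sum(ib) || any(wa[ia] != wb[ib]))
    stop("spectra are not on the same wavelength grid over the requested range")
  x <- a$values[ia]; y <- b$values[ib]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' @export
print.analyte_def <- function(x, ...) {
  cat(sprintf("<analyte> %s  rt %.2f min  MW %.2f  [M-H]- %s\n",
              x$name, x$retention_time, x$molecular_weight,
              ifelse(is.na(x$expected_mz), "-", format(x$expected_mz))))
  invisible(x)
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %d points, %g-%g nm, max %.3g\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              max(x$values)))
  invisible(x)
}
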