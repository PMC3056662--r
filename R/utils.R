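# Decibel helpers. SPL is 20 log10(p_rms / 1 uPa); energy quantities use
# 10 log10. Pressures are carried in micropascal throughout the package.

#' Convert RMS pressure in micropascal to sound pressure level
#'
#' @param p_rms_upa RMS pressure in micropascal.
#' @return SPL in dB re 1 uPa; `NA` where the pressure is zero.
#' @export
db_spl <- function(p_rms_upa) {
  out <- ifelse(p_rms_upa > 0, 20 * log10(p_rms_upa), NA_real_)
  as.numeric(out)
}

#' Convert sound pressure level to RMS pressure in micropascal
#'
#' @param spl_db SPL in dB re 1 uPa.
#' @return RMS pressure in micropascal.
#' @export
upa_from_db <- function(spl_db) 10^(spl_db / 20)

db_from_energy <- function(e) ifelse(e > 0, 10 * log10(e), NA_real_)

# Spherical Earth, consistent across all distance computations.
EARTH_RADIUS_M <- 6371000
KM_PER_DEG <- EARTH_RADIUS_M * pi / 180 / 1000  # ~111.195 km per degree

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", what))
  }
  invisible(x)
}

# Time in seconds for either numeric or POSIXct input.
time_as_seconds <- function(t) {
  if (inherits(t, "POSIXt")) as.numeric(t) else as.numeric(t)
}
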