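# Structured error conditions shared across the package.
# Three classes mirror the kinds of failure the pipeline distinguishes:
#   validation (bad values), format (bad files), range (outside tabulated data).

abort_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("radioyield_validation_error", "radioyield_error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("radioyield_format_error", "radioyield_error")))
}

abort_range <- function(msg) {
  stop(errorCondition(msg, class = c("radioyield_range_error", "radioyield_error")))
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort_validation(sprintf("'%s' must be strictly positive", name))
  if (nonneg && x < 0)
    abort_validation(sprintf("'%s' must be non-negative", name))
  invisible(x)
}

# Physical constants used throughout (CODATA).
AVOGADRO <- 6.02214076e23        # 1/mol
ELEMENTARY_CHARGE <- 1.602176634e-19  # C
MB_TO_CM2 <- 1e-27               # 1 millibarn in cm^2
DOTA_MOLAR_MASS <- 404.42        # g/mol, for microgram -> nmol conversion
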