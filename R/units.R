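AVOGADRO <- 6.02214076e23

#' Convert molarity to absolute copy number (and back)
#'
#' `molarity_copies()` returns the number of molecules contained in
#' `volume` litres of a solution at concentration `c` molar:
#' `copies = c * volume * 6.02214e23`. For example 10 aM in 0.2 mL is
#' about 1204 copies. `copies_molarity()` is the inverse.
#'
#' @param concentration molar (mol/L), >= 0.
#' @param volume_l sample volume in litres, > 0.
#' @return number of copies (unrounded).
#' @export
molarity_copies <- function(concentration, volume_l) {
  stopifnot(all(concentration >= 0), all(volume_l > 0))
  concentration * volume_l * AVOGADRO
}

#' @rdname molarity_copies
#' @param copies molecule count, >= 0.
#' @export
copies_molarity <- function(copies, volume_l) {
  stopifnot(all(copies >= 0), all(volume_l > 0))
  copies / (volume_l * AVOGADRO)
}

MOLARITY_SUFFIXES <- c(aM = 1e-18, fM = 1e-15, pM = 1e-12, nM = 1e-9,
                       uM = 1e-6, mM = 1e-3, M = 1)

#' Parse and format SI-suffixed molarity strings
#'
#' `parse_molarity()` turns strings like `"100aM"`, `"1 fM"` or `"1pM"`
#' into molar values; suffixes are case-sensitive (`aM`, `fM`, `pM`, `nM`,
#' `uM`, `mM`, `M`). `format_molarity()` renders a molar value with the
#' largest suffix that keeps the mantissa >= 1.
#'
#' @param x character vector of molarity strings.
#' @return numeric molar values.
#' @export
parse_molarity <- function(x) {
  vapply(as.character(x), function(s) {
    m <- regmatches(s, regexec("^([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\s*(aM|fM|pM|nM|uM|mM|M)$",
                               s))[[1L]]
    if (length(m) == 0L) stop("cannot parse molarity string: '", s, "'")
    as.numeric(m[2L]) * MOLARITY_SUFFIXES[[m[4L]]]
  }, numeric(1L), USE.NAMES = FALSE)
}

#' @rdname parse_molarity
#' @param c_molar numeric molar values.
#' @param digits significant digits.
#' @export
format_molarity <- function(c_molar, digits = 3) {
  vapply(c_molar, function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == 0) return("0 M")
    idx <- which(v / MOLARITY_SUFFIXES >= 1)
    suf <- if (length(idx)) names(MOLARITY_SUFFIXES)[idx[length(idx)]] else "aM"
    sprintf("%s %s", signif(v / MOLARITY_SUFFIXES[[suf]], digits), suf)
  }, character(1L))
}
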