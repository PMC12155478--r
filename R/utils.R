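#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for reported OAV integers and
#' percent changes. `base::round()` rounds half to even, which would turn an
#' OAV of 0.5 into 0; reported tables in this field round 0.5 up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.45, 2.5), 0)
#' round_half_up(5.65, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared sample-key helpers ---------------------------------------------------

default_regions <- c("HY", "LM", "SX", "YT")
default_grades <- c("S", "P")

split_sample_key <- function(sample, regions, grades) {
  parts <- stringr::str_match(sample, "^(.+)-([^-]+)$")
  region <- parts[, 2]
  grade <- parts[, 3]
  bad <- is.na(region) | !(region %in% regions) | !(grade %in% grades)
  if (any(bad)) {
    abort(paste0(
      "unknown region/grade code in sample name(s): ",
      paste(unique(sample[bad]), collapse = ", ")
    ))
  }
  list(region = region, grade = grade)
}

# canonical number formatting used by the CSV writers so that
# write(parse(file)) round-trips byte-for-byte
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}
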