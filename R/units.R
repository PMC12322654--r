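#' Absolute temperature
#'
#' Constructs a temperature in kelvin, either directly or from Celsius
#' (offset exactly 273.15). `"rt"` (room temperature) maps to 298.15 K.
#'
#' @param kelvin temperature in K
#' @param celsius temperature in degrees Celsius (alternative to `kelvin`)
#' @return a `temperature` object (numeric kelvin with class attribute)
#' @examples
#' temperature(celsius = 55)   # 328.15 K
#' room_temperature()          # 298.15 K
#' @export
temperature <- function(kelvin = NULL, celsius = NULL) {
  if (is.null(kelvin) == is.null(celsius))
    stop("supply exactly one of `kelvin` or `celsius`")
  k <- if (is.null(kelvin)) celsius + 273.15 else kelvin
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("temperature must be a single finite value > 0 K")
  structure(as.numeric(k), class = "temperature")
}

#' @rdname temperature
#' @export
room_temperature <- function() temperature(kelvin = 298.15)

#' @export
print.temperature <- function(x, ...) {
  cat(sprintf("%.2f K (%.2f °C)\n", unclass(x), unclass(x) - 273.15))
  invisible(x)
}

as_temperature <- function(x) {
  if (inherits(x, "temperature")) return(x)
  if (is.character(x) && length(x) == 1L && tolower(x) == "rt")
    return(room_temperature())
  temperature(kelvin = as.numeric(x))
}

# seconds per unit; year = 365.25 days
.halflife_units <- c(
  s = 1, sec = 1, min = 60, h = 3600, hr = 3600,
  d = 86400, day = 86400, y = 31557600, yr = 31557600
)

#' First-order half-life
#'
#' A positive duration, stored in seconds. Accepts the mixed units used
#' in relaxation tables: `"s"`, `"min"`, `"h"`, `"d"`, `"y"` (1 y =
#' 365.25 d), either via the `unit` argument or embedded in a string
#' such as `"3.16 h"` (see [parse_halflife()]).
#'
#' @param value duration (numeric, > 0) or a string like `"3.16 h"`
#' @param unit time unit: `"s"`, `"min"`, `"h"`, `"d"`, `"y"` (aliases
#'   `sec`, `hr`, `day`, `yr`)
#' @return a `halflife` object (numeric seconds with class attribute)
#' @examples
#' halflife(3.16, "h")
#' halflife("12.6 s")
#' @export
halflife <- function(value, unit = "s") {
  if (is.character(value)) return(parse_halflife(value))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop("half-life must be a single finite value > 0")
  unit <- match.arg(unit, names(.halflife_units))
  structure(as.numeric(value) * .halflife_units[[unit]], class = "halflife")
}

#' @rdname halflife
#' @param text string of the form `"<number> <unit>"` or `"<number><unit>"`
#' @export
parse_halflife <- function(text) {
  m <- regmatches(text, regexec("^\\s*([0-9.eE+-]+)\\s*([a-zA-Z]+)\\s*$", text))[[1]]
  if (length(m) != 3L)
    stop("cannot parse half-life from ", sQuote(text))
  halflife(as.numeric(m[2]), m[3])
}

#' @rdname halflife
#' @param x a `halflife`
#' @export
format_halflife <- function(x) {
  s <- unclass(x)
  if (s < 60)            sprintf("%.3g s", s)
  else if (s < 3600)     sprintf("%.3g min", s / 60)
  else if (s < 86400)    sprintf("%.3g h", s / 3600)
  else if (s < 31557600) sprintf("%.3g d", s / 86400)
  else                   sprintf("%.3g y", s / 31557600)
}

#' @export
print.halflife <- function(x, ...) {
  cat(format_halflife(x), sprintf("(%.6g s)\n", unclass(x)))
  invisible(x)
}

as_halflife <- function(x) {
  if (inherits(x, "halflife")) return(x)
  if (is.character(x)) return(parse_halflife(x))
  halflife(as.numeric(x), "s")
}

#' First-order rate constant from a half-life
#'
#' k = ln(2) / t_half.
#'
#' @param t_half a [halflife()], string, or seconds
#' @return rate in 1/s
#' @export
rate_from_halflife <- function(t_half) {
  log(2) / unclass(as_halflife(t_half))
}

#' @rdname rate_from_halflife
#' @param k first-order rate constant in 1/s (> 0)
#' @export
halflife_from_rate <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("rate constant must be a single finite value > 0")
  halflife(log(2) / k, "s")
}
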