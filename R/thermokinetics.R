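#' Eyring activation free energy from a thermal relaxation half-life
#'
#' Inverts the Eyring equation k = kappa * (kB*T/h) * exp(-dG/(R*T)) for
#' the activation free energy, with k = ln(2)/t_half and the transmission
#' coefficient kappa fixed at 1. This is the standard route from a
#' measured thermal cis->trans relaxation half-life of an azobenzene to
#' the free-energy barrier of the back-isomerisation.
#'
#' @param t_half a [halflife()] (or string/seconds coercible to one)
#' @param temp a [temperature()] (or kelvin / `"rt"`)
#' @return a `barrier_estimate`: list with `delta_g` (kcal/mol),
#'   `at_temperature` (K), `rate_per_s`, and `provenance`
#'   (`"from_experiment"`)
#' @examples
#' barrier_from_halflife(halflife(3.16, "h"), temperature(celsius = 55))
#' @seealso [halflife_from_barrier()], [extrapolate_halflife()]
#' @export
barrier_from_halflife <- function(t_half, temp) {
  t_half <- as_halflife(t_half)
  temp <- as_temperature(temp)
  k <- rate_from_halflife(t_half)
  T_K <- unclass(temp)
  dg <- with(azo_constants,
             R_kcal * T_K * log(kappa * kB * T_K / (h * k)))
  new_barrier(dg, temp, rate_per_s = k, provenance = "from_experiment")
}

new_barrier <- function(delta_g, temp, rate_per_s = NA_real_,
                        provenance = c("from_experiment", "supplied_computed")) {
  provenance <- match.arg(provenance)
  if (!is.finite(delta_g)) stop("barrier must be finite")
  structure(
    list(delta_g = delta_g, at_temperature = as_temperature(temp),
         rate_per_s = rate_per_s, provenance = provenance),
    class = "barrier_estimate"
  )
}

#' Record an externally computed activation barrier
#'
#' Wraps a barrier obtained elsewhere (e.g. from quantum-chemical
#' transition-state calculations) so it carries its provenance alongside
#' barriers inverted from experiment.
#'
#' @param delta_g activation free energy, kcal/mol
#' @param temp reference [temperature()]
#' @export
supplied_barrier <- function(delta_g, temp) {
  new_barrier(delta_g, temp, provenance = "supplied_computed")
}

#' @export
print.barrier_estimate <- function(x, ...) {
  cat(sprintf("dG* = %.2f kcal/mol at %.2f K [%s]\n",
              x$delta_g, unclass(x$at_temperature), x$provenance))
  invisible(x)
}

#' Half-life implied by an activation free energy (Eyring)
#'
#' t_half = ln(2) * h / (kappa * kB * T) * exp(dG/(R*T)). Very large
#' barriers that overflow the exponential are reported as `Inf` with a
#' warning rather than an error.
#'
#' @param dg a `barrier_estimate` or a plain number (kcal/mol)
#' @param temp a [temperature()]; defaults to the barrier's own
#'   temperature when `dg` is a `barrier_estimate`
#' @return a [halflife()]
#' @export
halflife_from_barrier <- function(dg, temp = NULL) {
  if (inherits(dg, "barrier_estimate")) {
    if (is.null(temp)) temp <- dg$at_temperature
    dg <- dg$delta_g
  }
  if (is.null(temp)) stop("`temp` is required when `dg` is a bare number")
  if (!is.finite(dg)) stop("barrier must be finite")
  temp <- as_temperature(temp)
  T_K <- unclass(temp)
  t_s <- with(azo_constants,
              log(2) * h / (kappa * kB * T_K) * exp(dg / (R_kcal * T_K)))
  if (!is.finite(t_s)) {
    warning("barrier too large: half-life overflows, reported as +Inf")
    return(structure(Inf, class = "halflife"))
  }
  halflife(t_s, "s")
}

#' Extrapolate a half-life to another temperature
#'
#' Default mode inverts the measured half-life to an Eyring barrier at
#' the measurement temperature, assumes the barrier is
#' temperature-independent, and re-evaluates the half-life at the target
#' temperature. Single-temperature data cannot separate the enthalpic
#' and entropic parts of the barrier, so this constant-dG assumption is
#' the only defensible single-point extrapolation; published
#' "extrapolated" columns obtained from multi-temperature fits will in
#' general differ.
#'
#' `method = "arrhenius"` instead assumes a fixed pre-exponential factor
#' (default 1e13 1/s): Ea = R*T*ln(A/k) at the measured point, then
#' k(T_target) = A*exp(-Ea/(R*T_target)).
#'
#' @param t_half measured [halflife()]
#' @param temp_measured [temperature()] of the measurement
#' @param temp_target [temperature()] to extrapolate to
#' @param method `"eyring"` (constant dG, default) or `"arrhenius"`
#' @param preexponential Arrhenius A factor, 1/s (Arrhenius mode only)
#' @return a [halflife()] at `temp_target`
#' @examples
#' extrapolate_halflife(halflife(3.16, "h"),
#'                      temperature(celsius = 55), room_temperature())
#' @export
extrapolate_halflife <- function(t_half, temp_measured, temp_target,
                                 method = c("eyring", "arrhenius"),
                                 preexponential = 1e13) {
  method <- match.arg(method)
  t_half <- as_halflife(t_half)
  temp_measured <- as_temperature(temp_measured)
  temp_target <- as_temperature(temp_target)
  if (method == "eyring") {
    b <- barrier_from_halflife(t_half, temp_measured)
    halflife_from_barrier(b, temp_target)
  } else {
    k <- rate_from_halflife(t_half)
    Tm <- unclass(temp_measured); Tt <- unclass(temp_target)
    Ea <- azo_constants$R_kcal * Tm * log(preexponential / k)
    kt <- preexponential * exp(-Ea / (azo_constants$R_kcal * Tt))
    halflife_from_rate(kt)
  }
}

#' Batch conversion of measured half-lives to Eyring barriers
#'
#' One call reproduces a whole experimental-barrier column from a table
#' of (compound, half-life, temperature) measurements. Per-row failures
#' are collected into an `error` column, not raised.
#'
#' @param records data.frame with columns `compound`, `t_half`
#'   (string with unit, e.g. `"3.16 h"`, or seconds), and `temp_C`
#'   (Celsius) or `temp_K` (kelvin); `"rt"` is accepted in either
#' @return data.frame: `compound`, `t_half_s`, `temp_K`, `k_per_s`,
#'   `dG_kcal_mol`, `dG_rounded` (1 decimal), `error`
#' @export
batch_barrier_table <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame")
  if (!"compound" %in% names(records) || !"t_half" %in% names(records))
    stop("`records` needs `compound` and `t_half` columns")
  if (anyDuplicated(records$compound))
    warning("duplicate compound ids kept as separate rows")
  temp_of <- function(row) {
    if (!is.null(row$temp_K) && !is.na(row$temp_K)) return(as_temperature(row$temp_K))
    tc <- row$temp_C
    if (is.character(tc) && tolower(tc) == "rt") return(room_temperature())
    temperature(celsius = as.numeric(tc))
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    row <- as.list(records[i, , drop = FALSE])
    res <- tryCatch({
      b <- barrier_from_halflife(as_halflife(row$t_half[[1]]), temp_of(row))
      data.frame(compound = as.character(row$compound),
                 t_half_s = log(2) / b$rate_per_s,
                 temp_K = unclass(b$at_temperature),
                 k_per_s = b$rate_per_s,
                 dG_kcal_mol = b$delta_g,
                 dG_rounded = round(b$delta_g, 1),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(compound = as.character(row$compound),
                 t_half_s = NA_real_, temp_K = NA_real_, k_per_s = NA_real_,
                 dG_kcal_mol = NA_real_, dG_rounded = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, out)
}
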