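#' Benchmark half-life / barrier table for a red-shifted azobenzene library
#'
#' Measured thermal cis->trans relaxation half-lives (with measurement
#' temperature) and the corresponding reported experimental activation
#' free energies for a published library of twenty ortho-substituted and
#' para-functionalised azobenzene photoswitches. `"rt"` denotes room
#' temperature (298.15 K). The reported barrier of compound 38 is known
#' not to follow from single-point Eyring inversion of its listed
#' half-life; `consistent` flags this.
#'
#' @return data.frame with columns `compound`, `t_half` (string with
#'   unit), `temp_C` (Celsius, or `"rt"`), `dG_exp_kcal_mol` (reported
#'   experimental barrier), `consistent` (logical)
#' @examples
#' tab <- azo_benchmark_halflives()
#' batch_barrier_table(tab)
#' @export
azo_benchmark_halflives <- function() {
  df <- data.frame(
    compound = c("1", "2", "3", "4", "6", "9", "12", "17", "19", "20",
                 "21", "22", "23", "24", "28", "38", "39", "46", "48", "49"),
    t_half   = c("3.16 h", "3.97 h", "3.7 h", "1.82 h", "9.03 h", "3.27 h",
                 "60.1 min", "69.6 min", "12.6 s", "25.7 min", "44.0 min",
                 "27.9 min", "1.95 h", "79.0 min", "38.8 min", "52.2 min",
                 "46.2 min", "4.31 h", "33.0 s", "0.12 s"),
    temp_C   = c("55", "90", "90", "90", "55", "90", "70", "90", "rt", "rt",
                 "90", "90", "45", "90", "55", "60", "90", "45", "rt", "rt"),
    dG_exp_kcal_mol = c(25.6, 28.6, 28.5, 28.0, 26.3, 28.4, 26.0, 27.7,
                        19.2, 22.0, 27.4, 27.0, 24.5, 27.8, 24.6, 23.3,
                        27.4, 25.0, 19.7, 16.4),
    stringsAsFactors = FALSE
  )
  df$consistent <- df$compound != "38"
  df
}
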