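# All internal computation is in SI units (Pa, m/s, s). mmHg is accepted at
# I/O boundaries only; 1 mmHg = 133.32 Pa.

#' Unit conversion between mmHg and Pa
#'
#' All internal computation in reswave uses SI units. These helpers convert
#' clinical pressures (mmHg) at the package boundary using the factor
#' 133.32 Pa/mmHg.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(60)   # 7999.2 Pa
#' pa_to_mmhg(13332) # 100 mmHg
#' @export
mmhg_to_pa <- function(x) x * 133.32

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.32
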