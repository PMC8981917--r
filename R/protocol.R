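#' Uniaxial test protocol
#'
#' Describes the tensile test: rings are mounted over two gripper pins,
#' brought to an initial grip-to-grip distance, and pulled at a constant
#' strain rate (fraction of initial length per second) while load and
#' extension are sampled until the instrument detects a large load drop.
#'
#' @param initial_grip_distance Initial grip-to-grip distance in mm
#'   (default 5.0, the nominal inner diameter of the ring molds).
#' @param strain_rate Crosshead strain rate as a fraction of the initial
#'   length per second (default 0.001, i.e. 0.1 % s^-1, quasi-static).
#' @param sampling_rate Acquisition rate in Hz (default 20).
#' @param termination_drop_fraction Fractional drop in load, relative to
#'   the running maximum, that terminates the test (default 0.40).
#' @return An object of class `test_protocol`.
#' @examples
#' p <- test_protocol()
#' crosshead_speed(p)  # 0.005 mm/s = 5 um/s
#' @export
test_protocol <- function(initial_grip_distance = 5.0,
                          strain_rate = 0.001,
                          sampling_rate = 20,
                          termination_drop_fraction = 0.40) {
  stopifnot(is.numeric(initial_grip_distance), is.numeric(strain_rate),
            is.numeric(sampling_rate), is.numeric(termination_drop_fraction))
  if (initial_grip_distance <= 0) stop("initial_grip_distance must be positive")
  if (strain_rate <= 0) stop("strain_rate must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (termination_drop_fraction <= 0 || termination_drop_fraction >= 1)
    stop("termination_drop_fraction must be in (0, 1)")
  structure(list(initial_grip_distance = initial_grip_distance,
                 strain_rate = strain_rate,
                 sampling_rate = sampling_rate,
                 termination_drop_fraction = termination_drop_fraction),
            class = "test_protocol")
}

#' Commanded crosshead speed for a protocol
#'
#' The crosshead speed is the strain rate times the initial grip-to-grip
#' distance; for the default protocol (5 mm, 0.1 % s^-1) this is
#' 0.005 mm/s, i.e. 5 micrometres per second.
#'
#' @param protocol A [test_protocol()].
#' @param units `"mm_s"` (default) or `"um_s"`.
#' @return Speed in the requested units.
#' @export
crosshead_speed <- function(protocol, units = c("mm_s", "um_s")) {
  units <- match.arg(units)
  stopifnot(inherits(protocol, "test_protocol"))
  v <- protocol$strain_rate * protocol$initial_grip_distance
  if (units == "um_s") v * 1000 else v
}

#' Read or write a test protocol as YAML
#'
#' YAML keys mirror the `test_protocol` field names.
#'
#' @param path File path.
#' @return `read_protocol()` returns a `test_protocol`.
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(test_protocol, x[intersect(names(x),
    c("initial_grip_distance", "strain_rate", "sampling_rate",
      "termination_drop_fraction"))])
}

#' @rdname read_protocol
#' @param protocol A `test_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "test_protocol"))
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' @export
print.test_protocol <- function(x, ...) {
  cat("Uniaxial test protocol\n")
  cat(sprintf("  initial grip distance : %.3f mm\n", x$initial_grip_distance))
  cat(sprintf("  strain rate           : %.4f /s (%.1f um/s crosshead)\n",
              x$strain_rate, crosshead_speed(x, "um_s")))
  cat(sprintf("  sampling rate         : %g Hz\n", x$sampling_rate))
  cat(sprintf("  termination drop      : %.0f %%\n",
              100 * x$termination_drop_fraction))
  invisible(x)
}
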