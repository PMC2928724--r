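## Folding configuration and the simplified nearest-neighbour parameter set
## of the reference engine.

GAS_CONSTANT_KCAL <- 0.0019872  # kcal/(mol*K)

#' Reference-model energy parameters
#'
#' The simplified nearest-neighbour parameterisation of the built-in
#' reference engine (kcal/mol). Stacking of two pairs contributes minus the
#' sum of their half-strengths; hairpin and interior/bulge loops pay an
#' affine size penalty; multiloops pay `ml_a + ml_b * branches +
#' ml_c * unpaired` (the closing helix counts as a branch). These constants
#' define the model; they are not fitted thermodynamic measurements, so
#' absolute kcal/mol values from this engine are comparative, not
#' calorimetric.
#'
#' @return A named list of model constants.
#' @export
reference_energy_params <- function() {
  list(stack_half = c(AU = 1.1, UA = 1.1, GC = 1.7, CG = 1.7,
                      GU = 0.6, UG = 0.6),
       hairpin_a = 4.0, hairpin_b = 0.15,
       interior_a = 2.0, interior_b = 0.3,
       ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
       max_interior = 30L)
}

#' Folding configuration
#'
#' @param backend `"reference"` for the built-in Zuker/McCaskill engine over
#'   the simplified model of [reference_energy_params()], or
#'   `"thermodynamic"` for the ViennaRNA `RNAfold` program with Turner
#'   nearest-neighbour parameters (required to reproduce published
#'   kcal/mol values).
#' @param temperature Folding temperature in degrees Celsius (default 37).
#' @param min_hairpin_loop Minimum unpaired residues in a hairpin loop
#'   (>= 3).
#' @param parameter_set Thermodynamic-backend energy table: `"default"`
#'   (the installed RNAfold's own default, Turner 2004 for ViennaRNA 2.x)
#'   or `"turner1999"` (the revision used by ViennaRNA 1.x; choose this to
#'   reproduce analyses performed with those versions). Ignored by the
#'   reference backend, whose table is `parameters`.
#' @param parameters Reference-model constants (ignored by the
#'   thermodynamic backend).
#' @return A `fold_config` object. `rt` is the thermal energy
#'   (kcal/mol) at `temperature`.
#' @export
fold_config <- function(backend = c("reference", "thermodynamic"),
                        temperature = 37,
                        min_hairpin_loop = 3L,
                        parameter_set = c("default", "turner1999"),
                        parameters = reference_energy_params()) {
  backend <- match.arg(backend)
  parameter_set <- match.arg(parameter_set)
  min_hairpin_loop <- as.integer(min_hairpin_loop)
  if (min_hairpin_loop < 3L)
    stop("min_hairpin_loop must be >= 3", call. = FALSE)
  rt <- GAS_CONSTANT_KCAL * (temperature + 273.15)
  if (rt <= 0) stop("temperature too low: rt must be > 0", call. = FALSE)
  structure(list(backend = backend, temperature = temperature, rt = rt,
                 min_hairpin_loop = min_hairpin_loop,
                 parameter_set = parameter_set,
                 parameters = parameters),
            class = "fold_config")
}

#' @export
print.fold_config <- function(x, ...) {
  cat("fold_config: backend=", x$backend, ", T=", x$temperature,
      "C (RT=", format(x$rt, digits = 5), " kcal/mol), min hairpin loop ",
      x$min_hairpin_loop, "\n", sep = "")
  invisible(x)
}

## flat parameter list handed to the C++ engine
engine_params <- function(config) {
  c(config$parameters,
    list(min_hairpin = config$min_hairpin_loop, rt = config$rt))
}
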