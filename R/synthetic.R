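#' Measurement-noise model for synthetic HPLC-style data
#'
#' Quantitation of oligosaccharide peaks against a standard curve is well
#' described by a multiplicative error proportional to the signal plus a
#' small additive floor near the detection limit. Each observation y becomes
#' `y * (1 + cv * e1) + floor_mM * e2` with independent standard normal
#' e1, e2, truncated at zero.
#'
#' @param cv Multiplicative coefficient of variation (fraction, default
#'   0.05).
#' @param floor_mM Additive noise floor, mM (default 0.005).
#' @param seed Integer seed making the realization reproducible.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, floor_mM = 0.005, seed = 1L) {
  if (cv < 0 || floor_mM < 0) {
    abort("`cv` and `floor_mM` must be >= 0", class = "chitokin_invalid_input")
  }
  structure(list(cv = cv, floor_mM = floor_mM, seed = as.integer(seed)),
            class = "noise_model")
}

#' Design of a degradation time-course experiment
#'
#' Defaults reproduce the reference HPLC time-course conditions: 1.25 mM
#' chitohexaose, 38 uM enzyme, 30 degrees C, sampled at 5, 10, 15, 30, 60,
#' 120 and 180 min; the extended preset follows the reaction to 1,500 min
#' (25 h), the horizon over which the hexamer is converted essentially
#' completely to monomer.
#'
#' @param chain_length Substrate degree of polymerisation (default 6).
#' @param s0_mM Initial substrate concentration, mM (default 1.25).
#' @param e0_uM Enzyme concentration, micromolar (default 38).
#' @param temperature_C Reaction temperature (default 30).
#' @param times_min Sampling times, minutes; default the 7-point 180-min
#'   grid, or the 1,500-min grid when `extended = TRUE`.
#' @param extended Use the long-horizon sampling grid.
#'
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(chain_length = 6, s0_mM = 1.25, e0_uM = 38,
                              temperature_C = 30, times_min = NULL,
                              extended = FALSE) {
  if (is.null(times_min)) {
    times_min <- if (extended) {
      c(5, 10, 15, 30, 60, 120, 180, 300, 450, 600, 800, 1000, 1250, 1500)
    } else {
      c(5, 10, 15, 30, 60, 120, 180)
    }
  }
  if (any(times_min <= 0) || is.unsorted(times_min)) {
    abort("`times_min` must be positive and sorted",
          class = "chitokin_invalid_input")
  }
  structure(
    list(chain_length = as.integer(chain_length), s0_mM = s0_mM,
         e0_uM = e0_uM, temperature_C = temperature_C,
         times_min = times_min),
    class = "experiment_design"
  )
}

apply_noise <- function(values, noise) {
  e1 <- stats::rnorm(length(values))
  e2 <- stats::rnorm(length(values))
  pmax(values * (1 + noise$cv * e1) + noise$floor_mM * e2, 0)
}

#' Generate a synthetic degradation time course
#'
#' Simulates the deterministic course for a design under a ground-truth
#' kinetic system, then perturbs every observation with the noise model.
#' Identical seeds give identical tables; `cv = 0` and `floor_mM = 0`
#' return the deterministic simulation unchanged.
#'
#' @param truth A [kinetic_system()], the generating ground truth.
#' @param design An [experiment_design()].
#' @param noise A [noise_model()]; `NULL` for a noiseless course.
#' @param scheme Integration scheme passed to [simulate_time_course()].
#'
#' @return A `time_course` whose metadata records the design and seed.
#' @export
#' @examples
#' tc <- generate_time_course(kinetic_system(), experiment_design(),
#'                            noise_model(seed = 42))
generate_time_course <- function(truth, design = experiment_design(),
                                 noise = noise_model(),
                                 scheme = c("explicit", "collapsed")) {
  truth$enzyme_total_uM <- design$e0_uM
  truth$temperature <- rxn_temperature(design$temperature_C)
  init <- setNames(design$s0_mM, design$chain_length)
  tc <- simulate_time_course(truth, init, design$times_min,
                             scheme = match.arg(scheme))
  if (!is.null(noise) && (noise$cv > 0 || noise$floor_mM > 0)) {
    sp <- tc_species(tc)
    m <- as.matrix(tc[sp])
    withr_seed <- noise$seed
    old <- get_global_seed()
    set.seed(withr_seed)
    m[] <- apply_noise(as.numeric(m), noise)
    restore_seed(old)
    tc[sp] <- as.data.frame(m)
  }
  meta <- attr(tc, "meta")
  meta$design <- design
  meta$noise <- noise
  attr(tc, "meta") <- meta
  tc
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate a synthetic initial-rate dataset
#'
#' Rates on the Michaelis-Menten curve for a grid of substrate
#' concentrations, perturbed by the noise model (multiplicative CV only; the
#' additive floor, expressed in mM, does not apply to rates).
#'
#' @param Km_uM,kcat_s,E0_uM Ground-truth parameters.
#' @param S_grid_uM Substrate concentrations, micromolar.
#' @param noise A [noise_model()]; `NULL` for noiseless rates.
#'
#' @return A tibble with `substrate_uM` and `rate` columns and attributes
#'   recording the truth.
#' @export
generate_initial_rates <- function(Km_uM, kcat_s, E0_uM = 1,
                                   S_grid_uM = c(25, 50, 100, 200, 400, 500),
                                   noise = noise_model()) {
  if (length(S_grid_uM) == 0) {
    abort("`S_grid_uM` must be nonempty", class = "chitokin_invalid_input")
  }
  v <- michaelis_menten_rate(S_grid_uM, Km_uM, kcat_s, E0_uM)
  if (!is.null(noise) && noise$cv > 0) {
    old <- get_global_seed()
    set.seed(noise$seed)
    v <- pmax(v * (1 + noise$cv * stats::rnorm(length(v))), 0)
    restore_seed(old)
  }
  out <- tibble(substrate_uM = S_grid_uM, rate = v)
  attr(out, "truth") <- list(Km_uM = Km_uM, kcat_s = kcat_s, E0_uM = E0_uM,
                             noise = noise)
  out
}

#' Canonical synthetic fixture bundle
#'
#' The named datasets used throughout the tests and documentation: noiseless
#' and noisy hexamer degradation courses generated from the fitted VhNag2
#' parameter set under the reference conditions (38 uM enzyme, 1.25 mM
#' substrate, 30 C, sampling to 1,500 min), plus one noiseless initial-rate
#' dataset per published Km/kcat row.
#'
#' @param seed Base seed; each noisy dataset derives its own seed from it.
#'
#' @return A named list of datasets with a `manifest` attribute recording
#'   seeds, truth parameters and designs.
#' @export
#' @examples
#' fx <- make_fixture_bundle(seed = 1)
#' names(fx)
make_fixture_bundle <- function(seed = 1L) {
  seed <- as.integer(seed)
  truth <- kinetic_system()
  design <- experiment_design(extended = TRUE)
  out <- list(
    hexamer_noiseless = generate_time_course(truth, design, noise = NULL),
    hexamer_noisy = generate_time_course(truth, design,
                                         noise = noise_model(seed = seed))
  )
  tab <- vhnag2_kinetic_table()
  for (r in seq_len(nrow(tab))) {
    nm <- paste0("rates_", tolower(gsub("[^A-Za-z0-9]", "", tab$substrate[r])),
                 "_", tolower(tab$enzyme[r]))
    out[[nm]] <- generate_initial_rates(tab$Km_uM[r], tab$kcat_s[r],
                                        E0_uM = 1, noise = NULL)
  }
  attr(out, "manifest") <- list(
    seed = seed,
    truth_energies = truth$cleft$energies,
    k_plus1 = truth$rates$k_plus1,
    k_plus2 = truth$rates$k_plus2,
    design = design,
    rate_truth = tab
  )
  out
}
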