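#' Rate constants of the cleavage cycle
#'
#' Three elementary constants govern each catalytic cycle: `k_plus1`, the
#' glycosidic-bond cleavage constant of the Michaelis complex (one value per
#' substrate chain length, taken from steady-state kcat); `k_minus1`, the
#' reverse (transglycosylation) constant, zero because no transglycosylation
#' products are observed; and `k_plus2`, the hydration constant for breakdown
#' of the post-cleavage intermediate, set to 50 s^-1, far above every
#' `k_plus1`, so cleavage is rate-limiting.
#'
#' @param k_plus1 Named numeric vector, chain length -> cleavage rate (s^-1).
#' @param k_minus1 Reverse rate constant (s^-1), default 0.
#' @param k_plus2 Hydration rate constant (s^-1), default 50.
#'
#' @return An object of class `rate_constants`.
#' @export
#' @examples
#' rate_constants()
rate_constants <- function(k_plus1 = c(`2` = 0.01, `3` = 0.10, `4` = 0.10,
                                       `5` = 0.09, `6` = 0.07),
                           k_minus1 = 0,
                           k_plus2 = 50) {
  if (is.null(names(k_plus1)) || anyNA(suppressWarnings(as.integer(names(k_plus1))))) {
    abort("`k_plus1` must be named by chain length", class = "chitokin_invalid_rates")
  }
  if (any(k_plus1 < 0) || k_minus1 < 0 || k_plus2 < 0) {
    abort("rate constants must be non-negative", class = "chitokin_invalid_rates")
  }
  structure(list(k_plus1 = k_plus1, k_minus1 = k_minus1, k_plus2 = k_plus2),
            class = "rate_constants")
}

k1_for <- function(rates, n) {
  v <- unname(rates$k_plus1[as.character(n)])
  v[is.na(v)] <- 0
  v
}

#' Assemble a kinetic system
#'
#' Bundles the cleft, rate constants, temperature and total enzyme
#' concentration that together define the mass-action system for sequential
#' exolytic degradation of GlcNAc_n chains up to `max_chain`.
#'
#' @param cleft A [subsite_cleft()]; default the fitted VhNag2 cleft.
#' @param rates A [rate_constants()].
#' @param temperature A [rxn_temperature()].
#' @param enzyme_total_uM Total enzyme concentration, micromolar (default 38).
#' @param max_chain Longest chain tracked (default 6).
#' @param include_overhangs Passed to [enumerate_binding_modes()].
#'
#' @return An object of class `kinetic_system`.
#' @export
#' @examples
#' kinetic_system()
kinetic_system <- function(cleft = cleft_vhnag2(),
                           rates = rate_constants(),
                           temperature = rxn_temperature(),
                           enzyme_total_uM = 38,
                           max_chain = 6,
                           include_overhangs = TRUE) {
  if (enzyme_total_uM < 0) {
    abort("`enzyme_total_uM` must be >= 0", class = "chitokin_invalid_system")
  }
  max_chain <- as.integer(max_chain)
  if (max_chain < 1) abort("`max_chain` must be >= 1", class = "chitokin_invalid_system")
  ks <- suppressWarnings(as.integer(names(rates$k_plus1)))
  if (any(ks > max_chain, na.rm = TRUE)) {
    abort("`k_plus1` refers to chain lengths above `max_chain`",
          class = "chitokin_invalid_system")
  }
  structure(
    list(cleft = cleft, rates = rates, temperature = temperature,
         enzyme_total_uM = enzyme_total_uM, max_chain = max_chain,
         include_overhangs = include_overhangs),
    class = "kinetic_system"
  )
}

#' @export
print.kinetic_system <- function(x, ...) {
  cat("<kinetic_system> max_chain =", x$max_chain,
      " E0 =", x$enzyme_total_uM, "uM  T =", x$temperature$kelvin, "K\n")
  cat("subsite energies (kcal/mol):\n")
  print(x$cleft$energies)
  invisible(x)
}

# Precompute, per chain length: the binding-mode table with association
# constants, the total binding capacity kappa_n = sum K, and the productive
# capacity grouped by left-fragment length. Also the (i, j) fragment pairs a
# post-cleavage intermediate can hold.
mode_tables <- function(system) {
  nmax <- system$max_chain
  modes <- vector("list", nmax)
  kappa <- numeric(nmax)
  prod_lf <- vector("list", nmax)
  for (n in seq_len(nmax)) {
    m <- enumerate_binding_modes(n, system$cleft,
                                 include_overhangs = system$include_overhangs)
    m$K <- association_constant(mode_free_energy(m, system$cleft),
                                system$temperature)
    modes[[n]] <- m
    kappa[n] <- sum(m$K)
    pr <- m[m$productive, , drop = FALSE]
    prod_lf[[n]] <- if (nrow(pr)) {
      v <- tapply(pr$K, pr$left_fragment, sum)
      setNames(as.numeric(v), names(v))
    } else numeric(0)
  }
  pairs <- NULL
  for (n in seq_len(nmax)) {
    lf <- suppressWarnings(as.integer(names(prod_lf[[n]])))
    if (length(lf)) pairs <- rbind(pairs, cbind(i = lf, j = n - lf))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2,
                                      dimnames = list(NULL, c("i", "j")))
  pairs <- unique(pairs)
  list(modes = modes, kappa = kappa, prod_lf = prod_lf, pairs = pairs)
}

# Safeguarded Newton solve of the enzyme mass balance
#   E + sum_n kappa_n E T_n / (1 + kappa_n E) = E_avail
# which is strictly increasing in E, so the root in [0, E_avail] is unique.
solve_free_enzyme <- function(kappa, totals, E_avail, guess = E_avail) {
  if (E_avail <= 0) return(list(E = 0, residual = 0))
  g_at <- function(E) E + sum(kappa * E * totals / (1 + kappa * E)) - E_avail
  lo <- 0; hi <- E_avail
  E <- min(max(guess, 0), E_avail)
  for (it in seq_len(200)) {
    d <- 1 + kappa * E
    g <- E + sum(kappa * E * totals / d) - E_avail
    if (abs(g) < 1e-14 * E_avail) break
    if (g > 0) hi <- E else lo <- E
    gp <- 1 + sum(kappa * totals / d^2)
    En <- E - g / gp
    if (!is.finite(En) || En <= lo || En >= hi) En <- (lo + hi) / 2
    if (abs(En - E) < 1e-17 + 1e-15 * E_avail) { E <- En; break }
    E <- En
  }
  res <- abs(g_at(E))
  # in deeply saturated regimes (huge kappa) bisection stalls around 1e-6
  # relative; that is still far below any concentration we report
  if (res > 1e-6 * E_avail) {
    abort(paste0("free-enzyme balance did not converge (residual ",
                 format(res), " M)"),
          class = "chitokin_numerical_failure")
  }
  list(E = E, residual = res)
}

as_total_substrate <- function(x, max_chain) {
  out <- numeric(max_chain)
  if (is.null(names(x))) {
    if (length(x) != max_chain) {
      abort("unnamed substrate vector must have one entry per chain length",
            class = "chitokin_invalid_input")
    }
    out <- as.numeric(x)
  } else {
    idx <- suppressWarnings(as.integer(names(x)))
    if (anyNA(idx) || any(idx < 1) || any(idx > max_chain)) {
      abort("substrate names must be chain lengths within 1..max_chain",
            class = "chitokin_invalid_input")
    }
    out[idx] <- as.numeric(x)
  }
  if (any(out < 0) || anyNA(out)) {
    abort("substrate concentrations must be non-negative",
          class = "chitokin_invalid_input")
  }
  out
}

#' Solve the rapid binding equilibrium
#'
#' Under the rapid-equilibrium assumption every Michaelis complex satisfies
#' `[C_{n,r}] = K_{n,r} [E]free [S_n]free` at all times. Given total (free +
#' complexed) substrate per chain length, this solves the enzyme mass balance
#' for free enzyme by safeguarded Newton iteration (the balance is monotone,
#' so the root is unique) and returns every complex concentration.
#'
#' @param system A [kinetic_system()].
#' @param total_substrate_mM Total substrate per chain length, mM: either an
#'   unnamed vector of length `max_chain` or a vector named by chain length,
#'   e.g. `c("6" = 1.25)`.
#'
#' @return A list of class `binding_equilibrium`: `free_enzyme_M`,
#'   `free_substrate_M` (per chain length), `complexes` (tibble with
#'   `chain_length`, `register`, `productive`, `left_fragment`, `K_Minv`,
#'   `conc_M`), `enzyme_total_M`, `residual_M`.
#' @export
#' @examples
#' eq <- solve_binding_equilibrium(kinetic_system(), c("6" = 1.25))
#' eq$free_enzyme_M
solve_binding_equilibrium <- function(system, total_substrate_mM) {
  tabs <- mode_tables(system)
  totals <- as_total_substrate(total_substrate_mM, system$max_chain) * 1e-3
  E0 <- system$enzyme_total_uM * 1e-6
  sol <- solve_free_enzyme(tabs$kappa, totals, E0, E0)
  E <- sol$E
  Sfree <- totals / (1 + tabs$kappa * E)
  cx <- bind_rows(lapply(seq_len(system$max_chain), function(n) {
    m <- tabs$modes[[n]]
    tibble(chain_length = n, register = m$register, productive = m$productive,
           left_fragment = m$left_fragment, K_Minv = m$K,
           conc_M = m$K * E * Sfree[n])
  }))
  structure(
    list(free_enzyme_M = E,
         free_substrate_M = setNames(Sfree, seq_len(system$max_chain)),
         complexes = cx,
         enzyme_total_M = E0,
         residual_M = sol$residual),
    class = "binding_equilibrium"
  )
}

#' Cleavage fluxes through the productive complexes
#'
#' The cleavage flux for chain length n is `k_plus1(n)` times the summed
#' concentration of its productive Michaelis complexes. Cleaving GlcNAc_n in a
#' mode with left fragment i yields, after hydration, one i-mer and one
#' (n-i)-mer; for the dimer both fragments are monomers.
#'
#' @param state A `binding_equilibrium` from [solve_binding_equilibrium()].
#' @param rates A [rate_constants()].
#'
#' @return A list with `fluxes`, a tibble of `chain_length` and
#'   `flux_M_per_s` (substrate consumption), and `monomer_rate_M_per_s`, the
#'   total GlcNAc production rate once the intermediates are hydrated.
#' @export
cleavage_fluxes <- function(state, rates = rate_constants()) {
  cx <- state$complexes
  nmax <- max(cx$chain_length)
  flux <- numeric(nmax)
  mono <- 0
  pr <- cx[cx$productive, , drop = FALSE]
  if (nrow(pr)) {
    for (row in seq_len(nrow(pr))) {
      n <- pr$chain_length[row]
      i <- pr$left_fragment[row]
      v <- k1_for(rates, n) * pr$conc_M[row]
      flux[n] <- flux[n] + v
      mono <- mono + v * ((i == 1) + ((n - i) == 1))
    }
  }
  list(fluxes = tibble(chain_length = seq_len(nmax), flux_M_per_s = flux),
       monomer_rate_M_per_s = mono)
}

species_cols <- function(max_chain) paste0("glcnac", seq_len(max_chain), "_mM")

new_time_course <- function(time_min, conc_mM, meta = list(),
                            intermediates_mM = NULL, pairs = NULL) {
  conc_mM <- as.matrix(conc_mM)
  colnames(conc_mM) <- species_cols(ncol(conc_mM))
  out <- as_tibble(as.data.frame(cbind(time_min = time_min, conc_mM)))
  attr(out, "meta") <- meta
  attr(out, "intermediates_mM") <- intermediates_mM
  attr(out, "pairs") <- pairs
  class(out) <- c("time_course", class(out))
  out
}

#' @export
print.time_course <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("<time_course> ", nrow(x), " time points, ",
      sum(grepl("^glcnac", names(x))), " species\n", sep = "")
  if (!is.null(meta$enzyme_total_uM)) {
    cat("E0 =", meta$enzyme_total_uM, "uM\n")
  }
  NextMethod()
}

tc_species <- function(tc) {
  nm <- grep("^glcnac[0-9]+_mM$", names(tc), value = TRUE)
  nm[order(as.integer(sub("^glcnac([0-9]+)_mM$", "\\1", nm)))]
}

#' Total GlcNAc units along a trajectory
#'
#' Sums n times the concentration of each GlcNAc_n species at every time
#' point, optionally adding material held in post-cleavage enzyme
#' intermediates (available for simulated courses). For a closed simulated
#' system this total is conserved.
#'
#' @param tc A `time_course`.
#' @param include_intermediates Add enzyme-bound fragment material when the
#'   course carries it (default `TRUE`).
#'
#' @return Numeric vector, mM of GlcNAc units per time point.
#' @export
total_glcnac_units <- function(tc, include_intermediates = TRUE) {
  sp <- tc_species(tc)
  n <- as.integer(sub("^glcnac([0-9]+)_mM$", "\\1", sp))
  tot <- as.matrix(tc[sp]) %*% n
  inter <- attr(tc, "intermediates_mM")
  pairs <- attr(tc, "pairs")
  if (include_intermediates && !is.null(inter) && nrow(pairs) > 0) {
    tot <- tot + inter %*% (pairs[, 1] + pairs[, 2])
  }
  as.numeric(tot)
}

#' Simulate a degradation time course
#'
#' Integrates the mass-action system for sequential exolytic degradation.
#' Substrate pools (free plus Michaelis-complexed chains) change only through
#' cleavage of productive complexes; each cleavage moves a chain into a
#' post-cleavage intermediate that decays at `k_plus2`, releasing both
#' fragments. The rapid binding equilibrium is re-solved at every
#' right-hand-side evaluation, so enzyme sequestration by substrates,
#' intermediates and products is accounted for exactly. With
#' `scheme = "collapsed"` hydration is treated as instantaneous and fragments
#' are released directly on cleavage; because `k_plus2` exceeds every
#' `k_plus1` by orders of magnitude the two schemes agree closely.
#'
#' Internally the integrator works in molar and seconds; all interfaces use
#' mM and minutes.
#'
#' @param system A [kinetic_system()].
#' @param initial Initial concentrations, mM, named by chain length (e.g.
#'   `c("6" = 1.25)`) or an unnamed vector of length `max_chain`.
#' @param times_min Nondecreasing output times, minutes.
#' @param scheme `"explicit"` (post-cleavage intermediate decaying at
#'   `k_plus2`, the default) or `"collapsed"` (instantaneous hydration).
#' @param rtol,atol_mM Integrator tolerances (relative; absolute in mM).
#'
#' @return A `time_course` tibble: `time_min` plus `glcnacN_mM` columns. Each
#'   reported concentration counts free and Michaelis-complexed chains;
#'   material inside post-cleavage intermediates (at most the enzyme
#'   concentration) is carried separately and visible to
#'   [total_glcnac_units()].
#' @export
#' @examples
#' tc <- simulate_time_course(kinetic_system(), c("6" = 1.25),
#'                            times_min = c(5, 30, 180))
#' tc
simulate_time_course <- function(system, initial, times_min,
                                 scheme = c("explicit", "collapsed"),
                                 rtol = 1e-8, atol_mM = 1e-10) {
  scheme <- match.arg(scheme)
  if (length(times_min) == 0 || any(!is.finite(times_min)) || any(times_min < 0)) {
    abort("`times_min` must be finite and non-negative",
          class = "chitokin_invalid_input")
  }
  if (is.unsorted(times_min)) {
    abort("`times_min` must be nondecreasing", class = "chitokin_invalid_input")
  }
  nmax <- system$max_chain
  y_T <- as_total_substrate(initial, nmax) * 1e-3
  tabs <- mode_tables(system)
  pairs <- tabs$pairs
  npair <- nrow(pairs)
  explicit <- scheme == "explicit"
  k2 <- system$rates$k_plus2
  km1 <- system$rates$k_minus1
  k1 <- vapply(seq_len(nmax), function(n) k1_for(system$rates, n), numeric(1))
  E0 <- system$enzyme_total_uM * 1e-6
  # flux routing: one row per (chain length, left fragment) with capacity
  route <- do.call(rbind, lapply(seq_len(nmax), function(n) {
    pk <- tabs$prod_lf[[n]]
    if (!length(pk)) return(NULL)
    i <- as.integer(names(pk))
    cbind(n = n, i = i, j = n - i, K = unname(pk))
  }))
  has_route <- !is.null(route) && nrow(route) > 0
  if (has_route) {
    r_n <- route[, "n"]; r_i <- route[, "i"]; r_j <- route[, "j"]
    r_k1K <- k1[r_n] * route[, "K"]
    # pair index of each route row, precomputed once
    r_pair <- vapply(seq_len(nrow(route)), function(r) {
      which(pairs[, 1] == r_i[r] & pairs[, 2] == r_j[r])
    }, integer(1))
  }
  kap <- tabs$kappa
  p_i <- pairs[, 1]; p_j <- pairs[, 2]; p_n <- p_i + p_j
  cache <- new.env(parent = emptyenv()); cache$E <- E0

  rhs <- function(t, y, p) {
    Tn <- pmax(y[seq_len(nmax)], 0)
    X <- if (explicit && npair) pmax(y[nmax + seq_len(npair)], 0) else numeric(0)
    E_avail <- E0 - sum(X)
    sol <- solve_free_enzyme(kap, Tn, E_avail, cache$E)
    cache$E <- sol$E
    Sfree <- Tn / (1 + kap * sol$E)
    dT <- numeric(nmax)
    dX <- numeric(if (explicit) npair else 0L)
    if (has_route) {
      fl <- r_k1K * sol$E * Sfree[r_n]
      for (r in seq_along(fl)) dT[r_n[r]] <- dT[r_n[r]] - fl[r]
      if (explicit) {
        for (r in seq_along(fl)) dX[r_pair[r]] <- dX[r_pair[r]] + fl[r]
      } else {
        for (r in seq_along(fl)) {
          dT[r_i[r]] <- dT[r_i[r]] + fl[r]
          dT[r_j[r]] <- dT[r_j[r]] + fl[r]
        }
      }
    }
    if (explicit && npair) {
      rel <- k2 * X
      back <- km1 * X
      dX <- dX - rel - back
      for (p_ in seq_len(npair)) {
        dT[p_i[p_]] <- dT[p_i[p_]] + rel[p_]
        dT[p_j[p_]] <- dT[p_j[p_]] + rel[p_]
        dT[p_n[p_]] <- dT[p_n[p_]] + back[p_]
      }
    }
    list(c(dT, dX))
  }

  y0 <- c(y_T, numeric(if (explicit) npair else 0))
  t_out <- unique(c(0, times_min)) * 60
  sol <- tryCatch(
    deSolve::lsoda(y0, t_out, rhs, parms = NULL,
                   rtol = rtol, atol = atol_mM * 1e-3),
    warning = function(w) {
      abort(paste0("stiff integration failed: ", conditionMessage(w)),
            class = "chitokin_numerical_failure")
    }
  )
  keep <- match(round(times_min * 60, 9), round(sol[, 1], 9))
  conc <- sol[keep, 1 + seq_len(nmax), drop = FALSE] * 1e3
  conc[conc < 0 & conc > -atol_mM * 10] <- 0
  inter <- if (explicit && npair) {
    sol[keep, 1 + nmax + seq_len(npair), drop = FALSE] * 1e3
  } else NULL
  new_time_course(
    time_min = times_min,
    conc_mM = conc,
    meta = list(enzyme_total_uM = system$enzyme_total_uM,
                temperature_K = system$temperature$kelvin,
                s0_mM = setNames(y_T * 1e3, seq_len(nmax)),
                scheme = scheme),
    intermediates_mM = inter,
    pairs = pairs
  )
}

#' Initial hydrolysis rate of a single substrate
#'
#' Substrate-consumption flux at time zero for GlcNAc_n alone, from the
#' rapid binding equilibrium and the productive-complex cleavage flux.
#' A monomer cannot span the scissile bond, so its rate is zero.
#'
#' @param system A [kinetic_system()].
#' @param n Chain length.
#' @param S0_mM Initial substrate concentration, mM.
#'
#' @return Consumption rate, M s^-1.
#' @export
#' @examples
#' initial_hydrolysis_rate(kinetic_system(), 4, 1.25)
initial_hydrolysis_rate <- function(system, n, S0_mM) {
  if (n < 1) abort("chain length must be >= 1", class = "chitokin_invalid_chain_length")
  if (n == 1) return(0)
  if (S0_mM == 0) return(0)
  st <- solve_binding_equilibrium(system, setNames(S0_mM, n))
  fl <- cleavage_fluxes(st, system$rates)
  fl$fluxes$flux_M_per_s[fl$fluxes$chain_length == n]
}
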