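#' Sum-of-squares cost between two time courses
#'
#' The fitting cost is the double sum, over species n and time points i, of
#' squared differences between calculated and measured concentrations,
#' `F = sum_i sum_n (c_{n,i} - e_{n,i})^2`, in mM^2. Missing experimental
#' values (empty cells) are skipped. Both courses must sit on the same time
#' grid; calculated courses are normally produced by requesting the
#' experimental times from the integrator, so no interpolation is needed.
#'
#' @param calculated,experimental `time_course` objects (or data frames with
#'   a `time_min` column and `glcnacN_mM` columns).
#' @param species Optional integer vector restricting the sum to these chain
#'   lengths; default all species shared by the two courses.
#'
#' @return The cost F, mM^2.
#' @export
time_course_cost <- function(calculated, experimental, species = NULL) {
  if (nrow(calculated) != nrow(experimental) ||
      max(abs(calculated$time_min - experimental$time_min)) > 1e-9) {
    abort("time grids of the two courses do not match",
          class = "chitokin_grid_mismatch")
  }
  sp <- intersect(tc_species(calculated), tc_species(experimental))
  if (!is.null(species)) {
    sp <- intersect(sp, paste0("glcnac", species, "_mM"))
  }
  if (length(sp) == 0) {
    abort("the two courses share no species columns",
          class = "chitokin_grid_mismatch")
  }
  d <- as.matrix(calculated[sp]) - as.matrix(experimental[sp])
  sum(d^2, na.rm = TRUE)
}

#' Specify a subsite fitting problem
#'
#' Declares which subsite free energies are optimized and which are pinned.
#' By convention subsite -2 stays fixed at its large positive value (+7.0
#' kcal/mol, enforcing exo action) while the energies from -1 to +4 are free;
#' the cleavage constants `k_plus1` and the hydration constant `k_plus2` are
#' never varied.
#'
#' @param free_positions Cleft positions to optimize (default -1, +1, +2,
#'   +3, +4).
#' @param fixed_energies Named vector of pinned energies (kcal/mol); must
#'   pin -2 unless it is freed. Cleft positions neither freed nor listed here
#'   keep the energy of the system template passed to
#'   [fit_subsite_energies()].
#' @param start Named starting values for the free positions; unlisted free
#'   positions start at 0 kcal/mol.
#' @param lower,upper Box bounds on every free energy, kcal/mol.
#' @param ftol Relative convergence tolerance on the cost F.
#' @param ptol Convergence tolerance on the parameter step, kcal/mol.
#' @param max_iter Maximum Powell iterations (direction-set cycles).
#' @param max_step Trust-region half-width of each line search, kcal/mol.
#'   Caps how far one line minimization may travel: beyond a few kcal/mol a
#'   single subsite can saturate the enzyme, flattening the cost surface into
#'   a plateau that would otherwise trap the search.
#' @param species Optional chain lengths entering the cost; default all.
#'
#' @return An object of class `subsite_fit_spec`.
#' @export
subsite_fit_spec <- function(free_positions = c(-1L, 1L, 2L, 3L, 4L),
                             fixed_energies = c(`-2` = 7.0),
                             start = NULL,
                             lower = -20, upper = 20,
                             ftol = 1e-10, ptol = 1e-4,
                             max_iter = 200, max_step = 2,
                             species = NULL) {
  free_positions <- as.integer(free_positions)
  if (any(free_positions %in% as.integer(names(fixed_energies)))) {
    abort("a position cannot be both free and fixed",
          class = "chitokin_invalid_fit_spec")
  }
  st <- setNames(numeric(length(free_positions)), as.character(free_positions))
  if (!is.null(start)) {
    st[names(start)] <- start
  }
  structure(
    list(free_positions = free_positions, fixed_energies = fixed_energies,
         start = st, lower = lower, upper = upper,
         ftol = ftol, ptol = ptol, max_iter = max_iter, max_step = max_step,
         species = species),
    class = "subsite_fit_spec"
  )
}

# Powell direction-set minimization with line searches by Brent's method
# (stats::optimize) and the standard direction-replacement test. Derivative
# free. Each line search is confined to a trust region of max_step around the
# current point: the cost surface develops long flat plateaus once a binding
# energy is strong enough to saturate the enzyme, and an uncapped search can
# overshoot into such a plateau and strand the whole minimization there.
powell_minimize <- function(fn, par, lower, upper,
                            ftol = 1e-10, ptol = 1e-4, max_iter = 200,
                            max_step = 2) {
  np <- length(par)
  dirs <- diag(np)
  evals <- 0L
  # a large finite penalty for failed simulations keeps Brent's method
  # well-behaved (Inf/NaN would be silently replaced and can fake a plateau)
  f_big <- 1e10
  f_of <- function(p) {
    evals <<- evals + 1L
    val <- tryCatch(fn(p), error = function(e) f_big)
    if (!is.finite(val)) f_big else min(val, f_big)
  }
  line_min <- function(p, d, f_here) {
    # admissible step range keeping p + a*d inside the box
    amin <- -Inf; amax <- Inf
    for (k in seq_len(np)) {
      if (d[k] > 0) {
        amax <- min(amax, (upper - p[k]) / d[k])
        amin <- max(amin, (lower - p[k]) / d[k])
      } else if (d[k] < 0) {
        amax <- min(amax, (lower - p[k]) / d[k])
        amin <- max(amin, (upper - p[k]) / d[k])
      }
    }
    amin <- max(amin, -max_step)
    amax <- min(amax, max_step)
    if (amax - amin < 1e-12) return(list(par = p, f = f_here))
    g <- function(a) f_of(p + a * d)
    cand <- rbind(c(0, f_here))
    # probe one unit step each way (clipped to the box)
    lo <- max(amin, -1); hi <- min(amax, 1)
    glo <- if (lo < 0) g(lo) else f_here
    ghi <- if (hi > 0) g(hi) else f_here
    cand <- rbind(cand, c(lo, glo), c(hi, ghi))
    if (glo < f_here || ghi < f_here) {
      # walk downhill, doubling the step, until the function turns back up or
      # the box limit is reached; the true minimum is then bracketed
      sgn <- if (glo < ghi) -1 else 1
      a_prev <- 0
      a_cur <- if (sgn < 0) lo else hi
      f_cur <- min(glo, ghi)
      repeat {
        a_next <- 2 * a_cur
        if (sgn < 0) a_next <- max(a_next, amin) else a_next <- min(a_next, amax)
        if (abs(a_next - a_cur) < 1e-12) break
        f_next <- g(a_next)
        cand <- rbind(cand, c(a_next, f_next))
        if (f_next >= f_cur) break
        a_prev <- a_cur; a_cur <- a_next; f_cur <- f_next
      }
      # the last probed point closed the bracket around the best point seen
      a_last <- cand[nrow(cand), 1]
      lo <- min(a_prev, a_last)
      hi <- max(a_prev, a_last)
    }
    # line-search precision an order below the parameter tolerance; tighter
    # would spend evaluations on digits the convergence test ignores
    opt <- optimize(g, c(lo, hi), tol = max(1e-7, ptol / 10))
    cand <- rbind(cand, c(opt$minimum, opt$objective))
    best <- cand[which.min(cand[, 2]), ]
    list(par = p + best[1] * d, f = best[2])
  }
  f <- f_of(par)
  trace <- list(list(iteration = 0L, F = f, par = par))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p0 <- par; f0 <- f
    biggest <- 0; ibig <- 1L
    for (i in seq_len(np)) {
      res <- line_min(par, dirs[, i], f)
      if (f - res$f > biggest) { biggest <- f - res$f; ibig <- i }
      par <- res$par; f <- res$f
    }
    trace[[length(trace) + 1L]] <- list(iteration = iter, F = f, par = par)
    step <- max(abs(par - p0))
    if (2 * (f0 - f) <= ftol * (abs(f0) + abs(f) + 1e-30) || step < ptol) {
      converged <- TRUE
      break
    }
    # Powell's test for replacing the direction of largest decrease
    pe <- 2 * par - p0
    pe <- pmin(pmax(pe, lower), upper)
    fe <- f_of(pe)
    if (fe < f0) {
      t <- 2 * (f0 - 2 * f + fe) * (f0 - f - biggest)^2 -
        biggest * (f0 - fe)^2
      if (t < 0) {
        dnew <- par - p0
        nrm <- sqrt(sum(dnew^2))
        if (nrm > 0) {
          dnew <- dnew / nrm
          res <- line_min(par, dnew, f)
          par <- res$par; f <- res$f
          dirs[, ibig] <- dirs[, np]
          dirs[, np] <- dnew
        }
      }
    }
  }
  list(par = par, f = f, iterations = iter, converged = converged,
       n_evals = evals, trace = trace)
}

resolve_energies <- function(template_cleft, spec, free_values) {
  e <- template_cleft$energies
  fx <- spec$fixed_energies
  if (length(fx)) e[names(fx)] <- fx
  e[as.character(spec$free_positions)] <- free_values
  e
}

infer_initial <- function(experimental, initial) {
  if (!is.null(initial)) return(initial)
  meta <- attr(experimental, "meta")
  if (!is.null(meta$s0_mM)) return(meta$s0_mM)
  abort(paste0("`initial` not given and the experimental course carries no ",
               "initial-composition metadata"),
        class = "chitokin_invalid_input")
}

#' Fit subsite binding free energies to a time course
#'
#' Minimizes the sum-of-squares cost between a measured degradation time
#' course and the course simulated from candidate subsite energies, using
#' derivative-free Powell direction-set minimization. The cleavage constants
#' (`k_plus1` per substrate), the hydration constant `k_plus2` and every
#' pinned subsite energy (by default the +7.0 kcal/mol at subsite -2) are
#' held fixed throughout. Several courses may be fitted jointly by passing a
#' list; their costs are summed.
#'
#' @param experimental A `time_course`, or a list of them for a joint fit.
#' @param system A [kinetic_system()] template supplying rate constants,
#'   temperature, enzyme concentration and any subsite energies not otherwise
#'   specified.
#' @param spec A [subsite_fit_spec()].
#' @param initial Initial composition (mM, named by chain length) matching
#'   `experimental`; a list when `experimental` is a list. Defaults to the
#'   metadata carried by simulated/synthetic courses.
#' @param scheme Integration scheme passed to [simulate_time_course()].
#'
#' @return An object of class `subsite_fit`: fitted energies, final cost F
#'   (mM^2), iteration count, convergence flag and the per-iteration
#'   trajectory. Simulation failures during a trial point are treated as
#'   infinite cost, never as errors.
#' @export
fit_subsite_energies <- function(experimental, system = kinetic_system(),
                                 spec = subsite_fit_spec(), initial = NULL,
                                 scheme = c("explicit", "collapsed")) {
  scheme <- match.arg(scheme)
  courses <- if (is.data.frame(experimental)) list(experimental) else experimental
  if (length(courses) == 0 || any(!vapply(courses, is.data.frame, logical(1)))) {
    abort("`experimental` must be a time course or a list of time courses",
          class = "chitokin_invalid_input")
  }
  if (any(vapply(courses, nrow, integer(1)) < 2)) {
    abort("each experimental course needs at least 2 time points",
          class = "chitokin_invalid_input")
  }
  inits <- if (is.null(initial)) {
    lapply(courses, infer_initial, initial = NULL)
  } else if (is.list(initial)) initial else list(initial)
  bad <- setdiff(c(spec$free_positions, as.integer(names(spec$fixed_energies))),
                 system$cleft$positions)
  if (length(bad)) {
    abort(paste0("positions not in the cleft: ", toString(bad)),
          class = "chitokin_invalid_fit_spec")
  }

  objective <- function(free_values) {
    e <- resolve_energies(system$cleft, spec, free_values)
    sys_i <- system
    sys_i$cleft <- subsite_cleft(system$cleft$positions, e)
    total <- 0
    for (k in seq_along(courses)) {
      calc <- simulate_time_course(sys_i, inits[[k]], courses[[k]]$time_min,
                                   scheme = scheme)
      total <- total + time_course_cost(calc, courses[[k]],
                                        species = spec$species)
    }
    total
  }

  res <- powell_minimize(objective, spec$start,
                         lower = spec$lower, upper = spec$upper,
                         ftol = spec$ftol, ptol = spec$ptol,
                         max_iter = spec$max_iter,
                         max_step = spec$max_step %||% 2)
  fitted <- resolve_energies(system$cleft, spec, res$par)
  traj <- tibble(
    iteration = map_int(res$trace, "iteration"),
    F = map_dbl(res$trace, "F"),
    par = map(res$trace, function(x) setNames(x$par,
                                              as.character(spec$free_positions)))
  )
  structure(
    list(fitted_energies = fitted,
         free_positions = spec$free_positions,
         final_cost_F = res$f,
         iterations = res$iterations,
         n_evals = res$n_evals,
         converged = res$converged,
         trajectory = traj,
         spec = spec,
         system = system),
    class = "subsite_fit"
  )
}

#' @export
print.subsite_fit <- function(x, ...) {
  cat("<subsite_fit> F =", format(x$final_cost_F, digits = 6),
      "mM^2 after", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$fitted_energies)
  invisible(x)
}

#' One-dimensional cost profile of a subsite energy
#'
#' Evaluates the fitting cost along a grid of values for one subsite energy,
#' every other parameter held fixed — a cheap identifiability diagnostic: the
#' profile minimum should bracket the fitted value, and a flat profile flags
#' a subsite that no populated binding mode occupies.
#'
#' @inheritParams fit_subsite_energies
#' @param position The cleft position profiled.
#' @param grid Energies (kcal/mol) at which to evaluate the cost.
#' @param scheme Integration scheme passed to [simulate_time_course()].
#'
#' @return A tibble with columns `energy` and `F`.
#' @export
profile_cost <- function(experimental, system = kinetic_system(),
                         position, grid, initial = NULL,
                         scheme = c("explicit", "collapsed")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(grid))) {
    abort("`grid` must be finite", class = "chitokin_invalid_input")
  }
  init <- infer_initial(experimental, initial)
  F <- map_dbl(grid, function(g) {
    e <- system$cleft$energies
    e[as.character(position)] <- g
    sys_i <- system
    sys_i$cleft <- subsite_cleft(system$cleft$positions, e)
    tryCatch({
      calc <- simulate_time_course(sys_i, init, experimental$time_min,
                                   scheme = scheme)
      time_course_cost(calc, experimental)
    }, error = function(e) Inf)
  })
  tibble(energy = grid, F = F)
}

#' @method tidy subsite_fit
#' @export
tidy.subsite_fit <- function(x, ...) {
  pos <- as.integer(names(x$fitted_energies))
  tibble(
    position = pos,
    estimate = unname(x$fitted_energies),
    fixed = !(pos %in% x$free_positions)
  )
}

#' @method glance subsite_fit
#' @export
glance.subsite_fit <- function(x, ...) {
  tibble(final_cost_F = x$final_cost_F,
         iterations = x$iterations,
         n_evals = x$n_evals,
         converged = x$converged)
}
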