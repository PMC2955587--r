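#' Define a subsite binding cleft
#'
#' An exo-glycosidase cleft is modelled as an ordered run of sugar-binding
#' subsites labelled with signed integers. Negative subsites hold the fragment
#' released on cleavage, positive subsites the leaving-side fragment, and the
#' glycosidic bond is cleaved between subsites -1 and +1; position 0 does not
#' exist in this nomenclature. Each subsite carries an additive binding free
#' energy change in kcal/mol.
#'
#' @param positions Integer vector of strictly increasing subsite labels,
#'   excluding 0. Default is the six-subsite (-2)(-1)(+1)(+2)(+3)(+4) cleft of
#'   an exolytic GH-20 N-acetylglucosaminidase.
#' @param energies Numeric vector of binding free energy changes (kcal/mol),
#'   one per position. May be named by position; unnamed vectors are matched
#'   by order.
#'
#' @return An object of class `subsite_cleft`: a list with integer `positions`
#'   and a numeric `energies` vector named by position.
#' @seealso [cleft_vhnag2()] for the fitted VhNag2 preset,
#'   [enumerate_binding_modes()] for placements of a chain on the cleft.
#' @export
#' @examples
#' subsite_cleft(energies = c(7, -4.5, 0, -1.1, -0.1, 0.9))
subsite_cleft <- function(positions = c(-2L, -1L, 1L, 2L, 3L, 4L),
                          energies = numeric(length(positions))) {
  if (length(positions) == 0) {
    abort("a cleft needs at least one subsite", class = "chitokin_invalid_cleft")
  }
  positions <- as.integer(positions)
  if (anyNA(positions) || any(positions == 0L)) {
    abort("subsite labels must be non-zero integers (position 0 does not exist)",
          class = "chitokin_invalid_cleft")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("subsite labels must be strictly increasing",
          class = "chitokin_invalid_cleft")
  }
  if (!is.null(names(energies)) && any(nzchar(names(energies)))) {
    missing <- setdiff(as.character(positions), names(energies))
    if (length(missing)) {
      abort(paste0("no energy given for subsite(s) ", toString(missing)),
            class = "chitokin_invalid_cleft")
    }
    energies <- energies[as.character(positions)]
  } else if (length(energies) != length(positions)) {
    abort("`energies` must have one value per position",
          class = "chitokin_invalid_cleft")
  }
  energies <- as.numeric(energies)
  if (any(!is.finite(energies))) {
    abort("all subsite energies must be finite", class = "chitokin_invalid_cleft")
  }
  structure(
    list(positions = positions,
         energies = setNames(energies, as.character(positions))),
    class = "subsite_cleft"
  )
}

#' @export
print.subsite_cleft <- function(x, ...) {
  cat("<subsite_cleft> ", length(x$positions), " subsites\n", sep = "")
  print(x$energies)
  invisible(x)
}

#' Fitted VhNag2 subsite cleft
#'
#' The (-2)(-1)(+1)(+2)(+3)(+4) cleft of the Vibrio harveyi 650
#' beta-N-acetylglucosaminidase VhNag2 with the published fitted binding free
#' energy changes: +7.0 (binding at -2 effectively prohibited, enforcing exo
#' action), -4.5, 0.0, -1.1, -0.1, and the moderately unfavourable +0.9
#' kcal/mol at +4.
#'
#' @return A [subsite_cleft()].
#' @export
#' @examples
#' cleft_vhnag2()
cleft_vhnag2 <- function() {
  subsite_cleft(
    positions = c(-2L, -1L, 1L, 2L, 3L, 4L),
    energies = c(`-2` = 7.0, `-1` = -4.5, `1` = 0.0,
                 `2` = -1.1, `3` = -0.1, `4` = 0.9)
  )
}

#' Reaction temperature
#'
#' @param celsius Temperature in degrees Celsius; default 30, the time-course
#'   incubation temperature.
#' @param kelvin Absolute temperature; overrides `celsius` when given.
#'
#' @return An object of class `rxn_temperature` with fields `kelvin` and
#'   `gas_constant` (kcal mol^-1 K^-1).
#' @export
#' @examples
#' rxn_temperature(30)
rxn_temperature <- function(celsius = 30, kelvin = NULL) {
  k <- if (is.null(kelvin)) celsius + 273.15 else kelvin
  if (!is.finite(k) || k <= 0) {
    abort("temperature must be a positive absolute temperature",
          class = "chitokin_invalid_temperature")
  }
  structure(list(kelvin = k, gas_constant = R_KCAL), class = "rxn_temperature")
}

# consecutive residue positions along the subsite axis, skipping 0
axis_positions <- function(register, n) {
  p <- seq.int(register, register + n)      # one spare slot for the 0 skip
  p <- p[p != 0L]
  p[seq_len(n)]
}

#' Enumerate binding modes of a chitooligosaccharide on a cleft
#'
#' A binding mode (register) is one placement of a GlcNAc_n chain along the
#' subsite axis, identified by the axis position of its non-reducing-end
#' residue. Every register whose occupancy intersects the cleft is returned
#' exactly once. Residues overhanging either cleft edge are allowed and simply
#' occupy no subsite. A mode is productive when it spans both -1 and +1 (the
#' scissile bond); cleavage of a productive mode releases the `left_fragment`
#' residues sitting at positions <= -1 from the non-reducing side.
#'
#' @param n Chain length (degree of polymerisation), >= 1.
#' @param cleft A [subsite_cleft()].
#' @param include_overhangs Keep modes whose residues extend beyond a cleft
#'   edge (default `TRUE`). When `FALSE`, only placements fully contained in
#'   the cleft are returned.
#'
#' @return A tibble with one row per mode: `chain_length`, `register`,
#'   `occupied` (list of occupied cleft positions), `n_occupied`, `productive`,
#'   `left_fragment` (residues on the non-reducing side of the bond; `NA` for
#'   non-productive modes).
#' @export
#' @examples
#' enumerate_binding_modes(6, cleft_vhnag2())
enumerate_binding_modes <- function(n, cleft = cleft_vhnag2(),
                                    include_overhangs = TRUE) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != as.integer(n)) {
    abort("chain length `n` must be a single integer >= 1",
          class = "chitokin_invalid_chain_length")
  }
  n <- as.integer(n)
  lo <- min(cleft$positions)
  hi <- max(cleft$positions)
  candidates <- setdiff(seq.int(lo - n - 1L, hi), 0L)
  rows <- list()
  for (r in candidates) {
    occ_axis <- axis_positions(r, n)
    occ <- occ_axis[occ_axis %in% cleft$positions]
    if (length(occ) == 0) next
    if (!include_overhangs && length(occ) < n) next
    productive <- all(c(-1L, 1L) %in% occ)
    rows[[length(rows) + 1L]] <- tibble(
      chain_length = n,
      register = r,
      occupied = list(occ),
      n_occupied = length(occ),
      productive = productive,
      left_fragment = if (productive) sum(occ_axis <= -1L) else NA_integer_
    )
  }
  modes <- bind_rows(rows)
  arrange(modes, .data$register)
}

#' Binding free energy of a mode
#'
#' Sums the per-subsite binding free energies over the cleft positions a mode
#' occupies, assuming additivity. Overhanging residues contribute zero.
#'
#' @param modes A tibble from [enumerate_binding_modes()] (or any tibble with
#'   an `occupied` list column of cleft positions).
#' @param cleft The [subsite_cleft()] supplying the energies.
#'
#' @return Numeric vector of free energies (kcal/mol), one per mode.
#' @export
#' @examples
#' m <- enumerate_binding_modes(4, cleft_vhnag2())
#' mode_free_energy(m, cleft_vhnag2())
mode_free_energy <- function(modes, cleft) {
  occ <- if (is.data.frame(modes)) modes$occupied else list(modes$occupied)
  map_dbl(occ, function(p) {
    bad <- setdiff(p, cleft$positions)
    if (length(bad)) {
      abort(paste0("mode occupies positions outside the cleft: ", toString(bad)),
            class = "chitokin_invalid_mode")
    }
    sum(cleft$energies[as.character(p)])
  })
}

#' Association constant from a binding free energy
#'
#' Converts a binding free energy change into an association constant at the
#' 1 M standard state, K = exp(-dG / RT).
#'
#' @param dG Binding free energy change, kcal/mol (vectorised).
#' @param temperature A [rxn_temperature()]; default 30 degrees C.
#'
#' @return Association constants, M^-1.
#' @export
#' @examples
#' association_constant(-5.7)            # ~1.3e4 M^-1
#' association_constant(7.0)             # effectively no binding
association_constant <- function(dG, temperature = rxn_temperature()) {
  if (any(!is.finite(dG))) {
    abort("binding free energies must be finite", class = "chitokin_invalid_energy")
  }
  exp(-dG / (temperature$gas_constant * temperature$kelvin))
}
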