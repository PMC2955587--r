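# shared fixtures, built lazily and cached for the whole run
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# noiseless hexamer course on the short (180 min) grid
hexamer_course_short <- function() {
  fixture("hex_short", function() {
    generate_time_course(kinetic_system(), experiment_design(), noise = NULL)
  })
}

# same course generated with the collapsed (instant-hydration) scheme, for
# tests that also fit with the collapsed scheme
hexamer_course_short_collapsed <- function() {
  fixture("hex_short_collapsed", function() {
    generate_time_course(kinetic_system(), experiment_design(), noise = NULL,
                         scheme = "collapsed")
  })
}

# brute-force binding-mode oracle: slide the chain register by register and
# test cleft overlap directly, independently of the production enumeration
oracle_modes <- function(n, positions = c(-2L, -1L, 1L, 2L, 3L, 4L)) {
  res <- list()
  for (r in seq.int(min(positions) - n - 2L, max(positions) + 1L)) {
    if (r == 0L) next
    axis <- integer(0)
    p <- r
    while (length(axis) < n) {
      if (p != 0L) axis <- c(axis, p)
      p <- p + 1L
    }
    occ <- axis[axis %in% positions]
    if (length(occ) == 0) next
    res[[length(res) + 1L]] <- list(
      register = r,
      occupied = occ,
      productive = all(c(-1L, 1L) %in% axis) &&
        all(c(-1L, 1L) %in% positions) && all(c(-1L, 1L) %in% occ),
      left_fragment = sum(axis <= -1L)
    )
  }
  res
}

# fresh path in the session temp dir for IO round-trip tests
temp_path <- function(name) {
  file.path(tempdir(), paste0(format(Sys.time(), "%H%M%OS3"), "-", name))
}
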