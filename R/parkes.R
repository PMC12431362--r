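# Parkes (consensus) error grid. Zone boundaries are piecewise-linear
# polylines in mg/dL reference x prediction space, as published in the
# technical clarification of the consensus grid; zones grade clinical risk
# A (none) through E (dangerous). The type-1 variant is the default.

# Boundary vertex lists. "upper" boundaries separate, in order, A|B, B|C,
# C|D, D|E above the identity line; "lower" boundaries A|B, B|C, C|D below
# it (no E region below for either variant).
parkes_vertices <- function(variant = c("type1", "type2")) {
  variant <- match.arg(variant)
  if (variant == "type1") {
    list(
      upper = list(
        ab = cbind(c(0, 30, 140, 280, 430), c(50, 50, 170, 380, 550)),
        bc = cbind(c(0, 30, 50, 70, 260), c(60, 60, 80, 110, 550)),
        cd = cbind(c(0, 25, 50, 80, 125), c(100, 100, 125, 215, 550)),
        de = cbind(c(0, 35, 50), c(150, 155, 550))
      ),
      lower = list(
        ab = cbind(c(50, 50, 170, 385, 550), c(0, 30, 145, 300, 450)),
        bc = cbind(c(120, 120, 260, 550), c(0, 30, 130, 250)),
        cd = cbind(c(250, 250, 550), c(0, 40, 150))
      )
    )
  } else {
    list(
      upper = list(
        ab = cbind(c(0, 30, 230, 440), c(50, 50, 330, 550)),
        bc = cbind(c(0, 30, 280), c(60, 60, 550)),
        cd = cbind(c(0, 25, 35, 125), c(80, 80, 90, 550)),
        de = cbind(c(0, 35, 50), c(200, 200, 550))
      ),
      lower = list(
        ab = cbind(c(50, 50, 90, 330, 550), c(0, 30, 80, 230, 450)),
        bc = cbind(c(90, 260, 550), c(0, 130, 250)),
        cd = cbind(c(250, 250, 410, 550), c(0, 40, 110, 160))
      )
    )
  }
}

#' Parkes consensus error-grid boundaries
#'
#' Returns the zone boundary polylines of the consensus (Parkes) error grid
#' in mg/dL reference x prediction coordinates. `upper` boundaries separate
#' zones A|B, B|C, C|D, D|E above the identity line; `lower` boundaries
#' A|B, B|C, C|D below it. The grid is defined on the 0-550 mg/dL square.
#'
#' @param variant `"type1"` (default) or `"type2"` diabetes variant.
#' @return List with elements `upper` and `lower`, each a named list of
#'   two-column vertex matrices, plus attribute `limit` (550).
#' @export
parkes_grid <- function(variant = c("type1", "type2")) {
  v <- parkes_vertices(variant)
  attr(v, "limit") <- 550
  v
}

# Piecewise-linear boundary evaluation with strictly-increasing x (vertical
# segments are resolved by a 1e-9 nudge, which keeps on-the-line points in
# the less severe zone) and rule-2 extension beyond the vertex range.
boundary_fun <- function(verts) {
  x <- verts[, 1]
  dup <- duplicated(x)
  if (any(dup)) x[dup] <- x[dup] + 1e-9 * seq_len(sum(dup))
  function(at) approx(x, verts[, 2], xout = at, rule = 2)$y
}

#' Assign Parkes error-grid zones
#'
#' Converts reference/predicted glucose to mg/dL (x 18.016), clips to the
#' grid square (0-550 mg/dL), and assigns each point a zone A-E by counting
#' the boundary polylines it lies strictly beyond. Points exactly on a
#' boundary are assigned the less severe zone; the identity line always
#' lies in zone A, and the zones partition the grid.
#'
#' @param reference Reference glucose, mmol/L (> 0).
#' @param predicted Predicted glucose, mmol/L (> 0).
#' @param variant Grid variant, `"type1"` or `"type2"`.
#' @return Character vector of zone labels (`"A"`-`"E"`).
#' @examples
#' parkes_zone(c(5, 5, 20), c(5, 9, 3))
#' @export
parkes_zone <- function(reference, predicted, variant = c("type1", "type2")) {
  if (length(reference) != length(predicted)) {
    stop_nibgm("reference and predicted must have equal length",
               "nibgm_metric_error")
  }
  if (any(reference <= 0) || any(predicted <= 0)) {
    stop_nibgm("glucose values must be strictly positive",
               "nibgm_metric_error")
  }
  v <- parkes_vertices(variant)
  x <- pmin(reference * MGDL_PER_MMOL, 550)
  y <- pmin(predicted * MGDL_PER_MMOL, 550)
  sev <- integer(length(x))
  k <- 0L
  for (b in v$upper) {
    k <- k + 1L
    above <- y > boundary_fun(b)(x)
    sev[above] <- pmax(sev[above], k)
  }
  k <- 0L
  for (b in v$lower) {
    k <- k + 1L
    below <- y < boundary_fun(b)(x)
    sev[below] <- pmax(sev[below], k)
  }
  c("A", "B", "C", "D", "E")[sev + 1L]
}
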