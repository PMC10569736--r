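# Icosahedral capsid geometry: exact radii, internal volume and DNA packing
# density. All lengths in nm, volumes in nm^3, densities in bp/nm^3.

# radius-to-edge ratios of the regular icosahedron (radius = ratio * edge)
.icosa_ratio <- c(
  circumscribed = sqrt(10 + 2 * sqrt(5)) / 4,  # through vertices, ~0.95106
  midsphere     = (1 + sqrt(5)) / 4,           # through edge midpoints, ~0.80902
  inscribed     = sqrt(3) * (3 + sqrt(5)) / 12 # through face centres, ~0.75576
)

#' Volume of a regular icosahedron from its circumradius
#'
#' Computes the volume of a regular icosahedron whose vertices lie on a sphere
#' of radius `circumradius`. The edge length is \eqn{a = 4R/\sqrt{10+2\sqrt 5}}
#' and the volume \eqn{V = (5/12)(3+\sqrt 5)\,a^3}, so the volume scales as
#' \eqn{R^3}.
#'
#' @param circumradius Non-negative numeric vector of circumscribed radii (nm).
#' @return Numeric vector of volumes (nm^3).
#' @examples
#' icosahedron_volume(1)    # ~2.5362
#' icosahedron_volume(47)   # internal volume of a capsid with 94 nm diameter, no shell
#' @export
icosahedron_volume <- function(circumradius) {
  if (!is.numeric(circumradius) || anyNA(circumradius)) {
    stop("'circumradius' must be numeric and non-missing")
  }
  if (any(circumradius < 0)) {
    stop("'circumradius' must be >= 0")
  }
  a <- 4 * circumradius / sqrt(10 + 2 * sqrt(5))
  (5 / 12) * (3 + sqrt(5)) * a^3
}

#' Convert a length between icosahedral radius conventions
#'
#' A polyhedral capsid can be sized by the sphere through its vertices
#' (circumscribed), through its edge midpoints (midsphere) or through its face
#' centres (inscribed). Electron-microscopy protocols differ in which of these
#' a reported "diameter" refers to; this converts between them using the exact
#' closed-form radii of the regular icosahedron. The ratios apply equally to
#' radii and diameters.
#'
#' @param value Non-negative numeric vector (radius or diameter, any unit).
#' @param from,to Radius convention: one of `"circumscribed"`, `"midsphere"`,
#'   `"inscribed"`.
#' @return Converted lengths, same unit as `value`.
#' @examples
#' ## a 77 nm inscribed diameter corresponds to ~96.9 nm across the vertices
#' radius_convert(77, "inscribed", "circumscribed")
#' @export
radius_convert <- function(value, from = c("circumscribed", "midsphere", "inscribed"),
                           to = c("circumscribed", "midsphere", "inscribed")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (!is.numeric(value) || anyNA(value)) stop("'value' must be numeric and non-missing")
  if (any(value < 0)) stop("'value' must be >= 0")
  value * .icosa_ratio[[to]] / .icosa_ratio[[from]]
}

#' Construct a capsid measurement record
#'
#' One phage's TEM-derived capsid size: the diameter of the circle
#' circumscribing the projected capsid, optionally with its standard deviation,
#' the tail length, and the number of virions averaged.
#'
#' @param phage_id Character scalar identifier.
#' @param diameter_nm Positive circumscribed-circle diameter (nm).
#' @param diameter_sd_nm Optional non-negative SD of the diameter (nm).
#' @param tail_nm Optional tail length (nm).
#' @param n_virions Optional count of virions measured.
#' @return An object of class `capsid_measurement`.
#' @examples
#' capsid_measurement("Bc01", 94, diameter_sd_nm = 3, tail_nm = 34, n_virions = 5)
#' @export
capsid_measurement <- function(phage_id, diameter_nm, diameter_sd_nm = NA_real_,
                               tail_nm = NA_real_, n_virions = NA_integer_) {
  stopifnot(is.character(phage_id), length(phage_id) == 1L)
  diameter_nm <- as.numeric(diameter_nm)
  if (length(diameter_nm) != 1L || is.na(diameter_nm) || diameter_nm <= 0) {
    stop("'diameter_nm' must be a single positive number")
  }
  if (!is.na(diameter_sd_nm) && diameter_sd_nm < 0) stop("'diameter_sd_nm' must be >= 0")
  structure(
    list(phage_id = phage_id, diameter_nm = diameter_nm,
         diameter_sd_nm = as.numeric(diameter_sd_nm), tail_nm = as.numeric(tail_nm),
         n_virions = as.integer(n_virions)),
    class = "capsid_measurement"
  )
}

#' @export
print.capsid_measurement <- function(x, ...) {
  sd_txt <- if (is.na(x$diameter_sd_nm)) "" else sprintf(" ± %g", x$diameter_sd_nm)
  cat(sprintf("Capsid measurement '%s': diameter %g%s nm", x$phage_id, x$diameter_nm, sd_txt))
  if (!is.na(x$tail_nm)) cat(sprintf(", tail %g nm", x$tail_nm))
  if (!is.na(x$n_virions)) cat(sprintf(" (n = %d virions)", x$n_virions))
  cat("\n")
  invisible(x)
}

#' Define an icosahedral capsid shell model
#'
#' The internal DNA-holding cavity is modelled as an icosahedron concentric
#' with the measured capsid, obtained by subtracting one uniform shell
#' thickness from the measured (circumscribed) radius.
#'
#' @param shell_thickness_nm Non-negative protein-shell thickness (nm).
#' @param radius_convention Convention of the *measured* diameter; converted to
#'   circumscribed internally. TEM protocols that circumscribe the projected
#'   capsid yield `"circumscribed"` (the default).
#' @return An object of class `icosahedral_model`.
#' @export
icosahedral_model <- function(shell_thickness_nm = 0,
                              radius_convention = c("circumscribed", "midsphere", "inscribed")) {
  radius_convention <- match.arg(radius_convention)
  shell_thickness_nm <- as.numeric(shell_thickness_nm)
  if (length(shell_thickness_nm) != 1L || is.na(shell_thickness_nm) || shell_thickness_nm < 0) {
    stop("'shell_thickness_nm' must be a single number >= 0")
  }
  structure(list(shell_thickness_nm = shell_thickness_nm,
                 radius_convention = radius_convention),
            class = "icosahedral_model")
}

#' @export
print.icosahedral_model <- function(x, ...) {
  cat(sprintf("Icosahedral capsid model: shell thickness %g nm, %s measurement convention\n",
              x$shell_thickness_nm, x$radius_convention))
  invisible(x)
}

#' Genome packing density inside an icosahedral capsid
#'
#' Converts the measured diameter to the circumscribed convention, subtracts
#' the shell thickness from the radius, computes the internal icosahedral
#' volume and divides the genome length by it. When the measurement carries a
#' diameter SD, a density interval is propagated by evaluating at
#' D - SD and D + SD (larger capsid, lower density).
#'
#' @param m A [capsid_measurement()].
#' @param model An [icosahedral_model()].
#' @param genome_length Genome length in bp (>= 0).
#' @return An object of class `packing_result` with elements `phage_id`,
#'   `internal_circumradius`, `internal_volume`, `density`, `genome_length`,
#'   and (when the SD is known) `density_interval`.
#' @examples
#' m <- capsid_measurement("Bc01", 94, 3)
#' packing_density(m, icosahedral_model(5.09), 100841)
#' @export
packing_density <- function(m, model, genome_length) {
  stopifnot(inherits(m, "capsid_measurement"), inherits(model, "icosahedral_model"))
  genome_length <- as.numeric(genome_length)
  if (length(genome_length) != 1L || is.na(genome_length) || genome_length < 0) {
    stop("'genome_length' must be a single number >= 0")
  }
  d_circ <- radius_convert(m$diameter_nm, model$radius_convention, "circumscribed")
  r_int <- d_circ / 2 - model$shell_thickness_nm
  if (r_int <= 0) {
    stop(sprintf("invalid geometry: shell thickness (%g nm) >= measured radius (%g nm)",
                 model$shell_thickness_nm, d_circ / 2))
  }
  vol <- icosahedron_volume(r_int)
  res <- list(
    phage_id = m$phage_id,
    internal_circumradius = r_int,
    internal_volume = vol,
    density = genome_length / vol,
    genome_length = genome_length
  )
  if (!is.na(m$diameter_sd_nm) && m$diameter_sd_nm > 0) {
    dd <- radius_convert(m$diameter_nm + c(1, -1) * m$diameter_sd_nm,
                         model$radius_convention, "circumscribed")
    rr <- dd / 2 - model$shell_thickness_nm
    if (all(rr > 0)) {
      res$density_interval <- genome_length / icosahedron_volume(rr)  # (low, high)
    }
  }
  structure(res, class = "packing_result")
}

#' @export
print.packing_result <- function(x, digits = 4, ...) {
  cat(sprintf("Packing density for '%s'\n", x$phage_id))
  cat(sprintf("  internal circumradius: %s nm\n", format(x$internal_circumradius, digits = digits)))
  cat(sprintf("  internal volume:       %s nm^3\n", format(x$internal_volume, digits = digits)))
  cat(sprintf("  genome length:         %d bp\n", as.integer(x$genome_length)))
  cat(sprintf("  density:               %s bp/nm^3\n", format(x$density, digits = digits)))
  if (!is.null(x$density_interval)) {
    cat(sprintf("  density at D +/- SD:   [%s, %s] bp/nm^3\n",
                format(x$density_interval[1], digits = digits),
                format(x$density_interval[2], digits = digits)))
  }
  invisible(x)
}

#' Calibrate the capsid shell thickness from an anchor phage
#'
#' Finds the unique shell thickness at which the icosahedral model reproduces a
#' stated packing density for an anchor measurement, by 1-D root finding.
#' Density is strictly increasing in the thickness (a thicker shell leaves a
#' smaller cavity), so the root is unique when it is bracketed.
#'
#' @param anchor A [capsid_measurement()] for the anchor phage.
#' @param genome_length Anchor genome length (bp).
#' @param target_density Target density (bp/nm^3).
#' @param bounds Length-2 numeric search interval for the thickness (nm).
#' @param radius_convention Convention of the anchor measurement.
#' @param tol Root-finding tolerance (nm).
#' @return Calibrated thickness (nm).
#' @examples
#' t_cal <- calibrate_thickness(capsid_measurement("Bc01", 94), 100841, 0.54)
#' round(t_cal, 2)  # ~5 nm
#' @export
calibrate_thickness <- function(anchor, genome_length, target_density,
                                bounds = c(0, 10),
                                radius_convention = "circumscribed",
                                tol = 1e-6) {
  stopifnot(inherits(anchor, "capsid_measurement"), length(bounds) == 2L,
            bounds[1] >= 0, bounds[2] > bounds[1])
  f <- function(t) {
    packing_density(anchor, icosahedral_model(t, radius_convention), genome_length)$density -
      target_density
  }
  f_lo <- f(bounds[1])
  ## density at the upper bound may be undefined if the shell swallows the capsid
  f_hi <- tryCatch(f(bounds[2]), error = function(e) Inf)
  if (abs(f_lo) <= .Machine$double.eps^0.5) return(bounds[1])
  if (f_lo > 0 || f_hi < 0) {
    stop(sprintf("calibration failure: no thickness in [%g, %g] nm reproduces %g bp/nm^3",
                 bounds[1], bounds[2], target_density))
  }
  uniroot(f, interval = bounds, tol = tol)$root
}
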