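#' Volume of a rod-shaped cell
#'
#' Computes the volume of a rod (cylinder with hemispherical caps) from its
#' length and width: \code{V = (w^2 * pi / 4) * (l - w) + pi * w^3 / 6}.
#' For \code{l == w} this degenerates to the volume of a sphere.
#'
#' @param length cell length, micrometres.
#' @param width cell width, micrometres; must satisfy
#'   \code{0 < width <= length}.
#' @return volume in cubic micrometres.
#' @export
rod_cell_volume <- function(length, width) {
  if (any(width <= 0) || any(width > length)) {
    stop("cell geometry requires 0 < width <= length", call. = FALSE)
  }
  (width^2 * pi / 4) * (length - width) + pi * width^3 / 6
}

#' Cell dry weight from cell volume
#'
#' Allometric dry-weight estimate \code{DW = 435 * V^0.86}. With V in
#' cubic micrometres the result is in femtograms, but only dry-weight ratios
#' are consumed downstream, so the absolute unit cancels.
#'
#' @param volume cell volume (> 0), cubic micrometres.
#' @return dry weight (consistent arbitrary unit).
#' @export
dry_weight_from_volume <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive", call. = FALSE)
  435 * volume^0.86
}

#' Species biomass fractions from cell geometry and counts
#'
#' Converts per-species cell geometries and relative cell counts into biomass
#' fractions: each species' accumulated dry weight is
#' \code{count * DW(volume(geometry))}, and fractions are the normalised
#' accumulated dry weights.
#'
#' @param geometries named list of \code{list(length=, width=)} per species
#'   tag (micrometres).
#' @param counts named numeric vector of relative cell counts (> 0), same
#'   names as \code{geometries}.
#' @return object of class \code{species_abundance}: list with
#'   \code{fractions} (named, sums to 1) and \code{provenance} (cell counts,
#'   volumes, dry weights).
#' @export
biomass_fractions <- function(geometries, counts) {
  if (!setequal(names(geometries), names(counts))) {
    stop("geometries and counts must cover the same species tags",
         call. = FALSE)
  }
  counts <- counts[names(geometries)]
  if (any(counts <= 0)) stop("cell counts must be > 0", call. = FALSE)
  vols <- vapply(geometries, function(g) rod_cell_volume(g$length, g$width),
                 numeric(1))
  dws <- dry_weight_from_volume(vols)
  acc <- counts * dws
  species_abundance(acc / sum(acc),
                    provenance = list(cell_counts = counts, volumes = vols,
                                      dry_weights = dws))
}

#' Construct a species-abundance object from known fractions
#'
#' Alternative constructor for externally supplied biomass fractions (e.g.
#' from sequencing-based abundance estimates).
#'
#' @param fractions named numeric vector of biomass fractions; must lie in
#'   \[0, 1\] and sum to 1 within 1e-9 (they are renormalised to machine
#'   precision).
#' @param provenance optional list describing how the fractions were obtained.
#' @return object of class \code{species_abundance}.
#' @export
species_abundance <- function(fractions, provenance = list()) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  fractions <- fractions / sum(fractions)
  structure(list(fractions = fractions, provenance = provenance),
            class = "species_abundance")
}

#' @export
print.species_abundance <- function(x, ...) {
  cat("<species_abundance>\n")
  for (tag in names(x$fractions)) {
    cat(sprintf("  %-10s %.3f\n", tag, x$fractions[[tag]]))
  }
  invisible(x)
}
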