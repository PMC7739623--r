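# Packaged anthropometric constants for the planar link model.
#
# Mass fractions, COM ratios (measured from the proximal joint) and radii of
# gyration (as fractions of segment length, transverse axis through the
# segment COM) follow the classical cadaver-based regression tables used
# throughout gait analysis (Dempster/Winter lineage). Left and right limbs
# are lumped: the model is sagittal-plane symmetric, so both shanks form one
# "shank" segment and both thighs one "thigh" segment, with the head, arms
# and trunk combined into a single HAT segment.

.anthro_fractions <- data.frame(
  segment    = c("hat", "thigh", "shank", "foot_l", "foot_r"),
  mass_frac  = c(0.678, 0.200, 0.093, 0.0145, 0.0145),
  com_ratio  = c(0.626, 0.433, 0.433, 0.50, 0.50),
  r_gyr_t_frac = c(0.496, 0.323, 0.302, 0.475, 0.475),
  r_gyr_l_frac = c(0.25, 0.12, 0.10, 0.15, 0.15),
  stringsAsFactors = FALSE
)

#' Default body segment parameter table
#'
#' Builds the per-segment parameter table (masses, COM ratios, absolute
#' radii of gyration) for the planar link model from a participant's total
#' mass and the segment lengths. Radii of gyration are converted from
#' length fractions to metres here so downstream code never needs the
#' lengths again.
#'
#' @param body_mass total body mass (kg).
#' @param lengths named numeric vector with elements `hat`, `thigh`,
#'   `shank`, `foot` (segment lengths in m).
#' @return data.frame with columns `segment`, `mass`, `com_ratio`,
#'   `r_gyr_t`, `r_gyr_l`.
#' @export
default_body_params <- function(body_mass, lengths) {
  stopifnot(body_mass > 0,
            all(c("hat", "thigh", "shank", "foot") %in% names(lengths)))
  tab <- .anthro_fractions
  len <- c(hat = unname(lengths["hat"]), thigh = unname(lengths["thigh"]),
           shank = unname(lengths["shank"]),
           foot_l = unname(lengths["foot"]), foot_r = unname(lengths["foot"]))
  tab$mass <- tab$mass_frac * body_mass
  tab$length <- len[tab$segment]
  tab$r_gyr_t <- tab$r_gyr_t_frac * tab$length
  tab$r_gyr_l <- tab$r_gyr_l_frac * tab$length
  tab[, c("segment", "mass", "com_ratio", "r_gyr_t", "r_gyr_l", "length")]
}
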