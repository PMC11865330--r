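# Coerce a SIP profile to a data.frame with density and copies columns,
# ordered by density; accepts the long simulation table filtered to one
# (treatment, guild, replicate).
as_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("density", "copies") %in% names(profile)))
  profile <- profile[order(profile$density), , drop = FALSE]
  if (any(duplicated(profile$density))) {
    stop("densities must be strictly monotone across fractions",
         call. = FALSE)
  }
  if (any(profile$copies < 0)) stop("copies must be >= 0", call. = FALSE)
  profile
}

#' Extract one SIP profile from a long fraction table
#'
#' @param sip Long data.frame as produced by [generate_sip_profiles()].
#' @param treatment,guild Selection values.
#' @param replicate Replicate number (default 1).
#' @return data.frame of ordered fractions for that profile.
#' @export
sip_profile <- function(sip, treatment, guild, replicate = 1) {
  sel <- sip$treatment == treatment & sip$guild == guild &
    sip$replicate == replicate
  if (!any(sel)) stop("no matching profile", call. = FALSE)
  as_profile(sip[sel, , drop = FALSE])
}

#' Normalise a density-fraction profile
#'
#' Converts per-fraction copy numbers to shares summing to 1 and reports
#' the total (used to check that labelled and control incubations carry
#' comparable overall copy numbers).
#'
#' @param profile data.frame with `density` and `copies` columns.
#' @return List: `profile` (input plus a `share` column), `total`.
#' @export
normalize_profile <- function(profile) {
  profile <- as_profile(profile)
  total <- sum(profile$copies)
  if (total <= 0) stop("degenerate profile: zero total copies", call. = FALSE)
  profile$share <- profile$copies / total
  list(profile = profile, total = total)
}

#' Weighted mean buoyant density of a profile
#'
#' `sum(share_f * density_f)`; always lies within the profile's density
#' range.
#'
#' @param profile data.frame with `density` and `copies` columns.
#' @return Weighted mean density in g/mL.
#' @export
weighted_mean_density <- function(profile) {
  np <- normalize_profile(profile)
  sum(np$profile$share * np$profile$density)
}

#' Detect an isotope-labelling density shift
#'
#' Compares the weighted mean density of a labelled profile with its
#' unlabelled control (interpolating the control onto the labelled density
#' grid when the grids differ); the profile counts as labelled when the
#' shift toward heavier density reaches `min_shift`.
#'
#' @param labeled,control Profiles (data.frames with `density`, `copies`).
#' @param min_shift Minimum density shift in g/mL (default 0.005).
#' @return List: `shift` (g/mL, labelled minus control), `is_labeled`,
#'   `wmd_labeled`, `wmd_control`.
#' @export
detect_label_shift <- function(labeled, control, min_shift = 0.005) {
  labeled <- as_profile(labeled)
  control <- as_profile(control)
  if (!isTRUE(all.equal(labeled$density, control$density))) {
    rng <- range(control$density)
    if (min(labeled$density) < rng[1] - 1e-9 ||
        max(labeled$density) > rng[2] + 1e-9) {
      stop("density grids differ beyond the interpolation range",
           call. = FALSE)
    }
    control <- data.frame(
      density = labeled$density,
      copies = stats::approx(control$density, control$copies,
                             xout = labeled$density)$y)
  }
  wl <- weighted_mean_density(labeled)
  wc <- weighted_mean_density(control)
  shift <- wl - wc
  list(shift = shift, is_labeled = shift >= min_shift,
       wmd_labeled = wl, wmd_control = wc)
}

#' Guild composition of the heavy density window
#'
#' Sums each guild's copies over a heavy-density window and normalises the
#' totals to shares across guilds (the "who is active" readout of a SIP
#' experiment).
#'
#' @param sip Long fraction table with `guild`, `density`, `copies`
#'   columns (e.g. the 13C rows of [generate_sip_profiles()]).
#' @param heavy_window Length-2 density interval in g/mL, default
#'   `c(1.72, 1.75)`.
#' @return data.frame: `guild`, `copies`, `share` (summing to 1).
#' @export
heavy_fraction_composition <- function(sip, heavy_window = c(1.72, 1.75)) {
  stopifnot(all(c("guild", "density", "copies") %in% names(sip)))
  if (length(heavy_window) != 2 || heavy_window[1] >= heavy_window[2]) {
    stop("heavy_window must be an increasing density interval", call. = FALSE)
  }
  inw <- sip$density >= heavy_window[1] & sip$density <= heavy_window[2]
  if (!any(inw)) stop("heavy window contains no fractions", call. = FALSE)
  tot <- tapply(sip$copies[inw], sip$guild[inw], sum)
  tot[is.na(tot)] <- 0
  out <- data.frame(guild = names(tot), copies = as.numeric(tot),
                    stringsAsFactors = FALSE)
  out$share <- out$copies / sum(out$copies)
  out
}
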