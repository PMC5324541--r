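#' Chaff proportion of reproductive mass
#'
#' The fraction of reproductive biomass that is chaff or pod material rather
#' than grain, c = chaff / (chaff + grain).
#'
#' @param mass_chaff chaff (or pod) dry mass, g; non-negative.
#' @param mass_grain grain dry mass, g.
#' @param percent return the value multiplied by 100.
#' @return chaff proportion in \[0, 1) (or percent).
#' @export
chaffFraction <- function(mass_chaff, mass_grain, percent = FALSE) {
  if (any(mass_chaff < 0, na.rm = TRUE)) stop("mass_chaff must be non-negative")
  denom <- mass_chaff + mass_grain
  if (any(!is.na(denom) & denom <= 0)) {
    stop("chaff proportion undefined: chaff + grain is zero")
  }
  out <- mass_chaff / denom
  if (percent) out * 100 else out
}

#' Relative reduction of a trait in crops, as percent of the progenitor value
#'
#' Expresses a crop-versus-progenitor difference the way domestication effects
#' on proportions are usually quoted: 100 * (progenitor - crop) / progenitor.
#' For chaff percentages of 39.0 (progenitor) and 24.2 (crop) this gives a 38
#' percent reduction (to the nearest integer).
#'
#' @param progenitor progenitor value (nonzero).
#' @param crop crop value, same units.
#' @return percent reduction; negative when the crop value is larger.
#' @export
relativeReduction <- function(progenitor, crop) {
  if (any(progenitor == 0, na.rm = TRUE)) stop("progenitor value must be nonzero")
  100 * (progenitor - crop) / progenitor
}

#' Average relative growth rate over the whole growth period
#'
#' lambda = ln(Md / Ms) / d: the constant exponential rate that would carry a
#' plant from its sown seed mass Ms to its final above-ground mass Md in d
#' days. Valid as an average even when growth is not exponential; it measures
#' the efficiency with which seed mass is converted into final plant mass, and
#' is size-uncorrected by construction (see [rgrAtSize()] for the
#' size-corrected alternative).
#'
#' @param ms_sown sown individual seed mass, g; positive.
#' @param md final above-ground dry mass, g; positive.
#' @param d growth duration, days; positive.
#' @return average RGR in g g^-1 day^-1. A final mass below the seed mass
#'   yields a negative rate, which is admitted with a warning rather than
#'   rejected.
#' @export
averageRGR <- function(ms_sown, md, d) {
  if (any(ms_sown <= 0, na.rm = TRUE)) stop("ms_sown must be positive")
  if (any(md <= 0, na.rm = TRUE)) stop("md must be positive")
  if (any(d <= 0, na.rm = TRUE)) stop("d must be positive")
  out <- log(md / ms_sown) / d
  if (any(out < 0, na.rm = TRUE)) {
    warning("negative average RGR: final mass below sown seed mass for ",
            sum(out < 0, na.rm = TRUE), " plant(s)")
  }
  out
}

#' Seed yield from the growth/allocation decomposition
#'
#' Y = Ms * exp(lambda * d) * Ar * (1 - c): sown seed mass grown at the
#' average rate lambda for d days gives final mass, of which a fraction Ar is
#' reproductive and a fraction (1 - c) of that is grain. When lambda is the
#' average RGR computed from the same plant's Ms and Md, this collapses to the
#' exact identity Y = Md * Ar * (1 - c).
#'
#' @param ms_sown sown individual seed mass, g.
#' @param lambda average RGR, g g^-1 day^-1.
#' @param d growth duration, days.
#' @param ar reproductive allocation, fraction in \[0, 1\].
#' @param c chaff proportion, fraction in \[0, 1\].
#' @return total seed yield, g.
#' @export
yieldGrowth <- function(ms_sown, lambda, d, ar, c) {
  if (any(ar < 0 | ar > 1, na.rm = TRUE)) stop("ar must lie in [0, 1]")
  if (any(c < 0 | c > 1, na.rm = TRUE)) stop("c must lie in [0, 1]")
  ms_sown * exp(lambda * d) * ar * (1 - c)
}

#' Seed yield from the packaging decomposition
#'
#' Y = Ms * Ns * Ni for cereals (seed mass at harvest times seeds per
#' infructescence times infructescences per plant), or Y = Ms * N with the
#' total seed count N for pulses, whose pods were not counted individually.
#'
#' @param ms_harvest individual seed mass at final harvest, g; positive.
#' @param ns seeds per infructescence (cereals). Either supply \code{ns} and
#'   \code{ni}, or \code{n_total} alone.
#' @param ni infructescences per plant (cereals).
#' @param n_total total seeds per plant (pulse variant).
#' @return total seed yield, g.
#' @export
yieldPackaging <- function(ms_harvest, ns = NULL, ni = NULL, n_total = NULL) {
  if (any(ms_harvest <= 0, na.rm = TRUE)) stop("ms_harvest must be positive")
  if (!is.null(n_total)) {
    if (!is.null(ns) || !is.null(ni)) {
      stop("supply either ns and ni, or n_total, not both")
    }
    return(ms_harvest * n_total)
  }
  if (is.null(ns) || is.null(ni)) stop("supply both ns and ni, or n_total")
  if (any(ns < 0, na.rm = TRUE) || any(ni < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  ms_harvest * ns * ni
}

#' Derive all yield components from plant records
#'
#' Computes, per plant, the full component vector of both yield
#' decompositions: reproductive allocation Ar = reproductive/total biomass,
#' chaff proportion c, average RGR, both yield reconstructions, harvest index
#' and seeds per gram of biomass. Seed masses are converted from mg (as
#' stored) to g here, once. Per-infructescence fields stay \code{NA} for
#' records without packaging counts (pulses); their packaging yield uses the
#' total seed count.
#'
#' @param records a \code{plant_records} table (see [plantRecords()]).
#' @param culm_in_chaff if \code{TRUE} (default), the recorded chaff mass is
#'   taken to contain the culm, so reproductive mass = chaff + grain exactly
#'   and the identities Y = Md * Ar * (1 - c) hold without residue. If
#'   \code{FALSE}, c is computed from chaff and grain only, excluding any culm
#'   mass present in \code{mass_reproductive}; the growth-route reconstruction then
#'   overstates yield by the culm share.
#' @return data frame of class \code{yield_components}, one row per record:
#'   \code{species}, \code{status}, \code{family}, \code{Ms_sown},
#'   \code{Ms_harvest} (g), \code{lambda_bar}, \code{d}, \code{Ar}, \code{c},
#'   \code{Ns}, \code{Ni}, \code{N_total}, \code{Y}, \code{Md},
#'   \code{Y_growth}, \code{Y_packaging}, \code{harvest_index}, \code{seeds_per_g}.
#' @export
deriveComponents <- function(records, culm_in_chaff = TRUE) {
  df <- as.data.frame(records)
  ms_sown <- df$seed_mass_sown / 1000     # mg -> g
  ms_harv <- df$seed_mass_harvest / 1000
  md <- df$biomass_total
  ar <- df$mass_reproductive / df$biomass_total
  cc <- if (culm_in_chaff) {
    df$mass_chaff / df$mass_reproductive
  } else {
    chaffFraction(df$mass_chaff, df$mass_grain)
  }
  lam <- withCallingHandlers(
    averageRGR(ms_sown, md, df$duration_days),
    warning = function(w) {
      warning("deriveComponents: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  y1 <- yieldGrowth(ms_sown, lam, df$duration_days, ar, cc)
  has_pack <- !is.na(df$n_seeds_per_infructescence) & !is.na(df$n_infructescences)
  y2 <- ifelse(has_pack,
               ms_harv * df$n_seeds_per_infructescence * df$n_infructescences,
               ms_harv * df$n_seeds_total)
  out <- data.frame(
    species = df$species, status = df$status, family = df$family,
    accession = df$accession, experiment = df$experiment, block = df$block,
    Ms_sown = ms_sown, Ms_harvest = ms_harv,
    lambda_bar = lam, d = df$duration_days, Ar = ar, c = cc,
    Ns = df$n_seeds_per_infructescence, Ni = df$n_infructescences,
    N_total = df$n_seeds_total,
    Y = df$mass_grain, Md = md,
    Y_growth = y1, Y_packaging = y2,
    harvest_index = df$mass_grain / md,
    seeds_per_g = df$n_seeds_total / md,
    stringsAsFactors = FALSE)
  bad <- which(!is.na(out$harvest_index) &
                 (out$harvest_index < -.Machine$double.eps |
                    out$harvest_index > 1 + 1e-8))
  if (length(bad) > 0L) {
    stop("harvest index outside [0, 1] for record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  class(out) <- c("yield_components", "data.frame")
  out
}
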