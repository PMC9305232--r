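#' Fit qPCR copy-number to dry-biomass calibrations
#'
#' Fits, per fungal strain, an ordinary least-squares linear regression of
#' dry biomass (mg) on qPCR copy number, as used to convert field copy
#' numbers into fungal biomass. The calibration samples typically span
#' 0.5-5 mg of dry fungal material.
#'
#' @param samples data.frame with columns `strain`, `copy_number`,
#'   `biomass_mg` (strain optional when `per_strain = FALSE`).
#' @param per_strain fit one model per strain (default TRUE when a strain
#'   column is present).
#' @param through_origin force a zero intercept. Default FALSE (free
#'   intercept).
#' @return a data.frame of class `calibration_models` with one row per
#'   fitted strain: `strain`, `slope` (mg per copy), `intercept` (mg),
#'   `r_squared`, `n_samples`. Strains that cannot be fitted (< 2 samples
#'   or zero-variance copy numbers) are reported in `attr(, "unfittable")`
#'   (with a warning) while the remaining strains are still fitted.
#' @export
fit_calibration <- function(samples, per_strain = "strain" %in% names(samples),
                            through_origin = FALSE) {
  req <- c("copy_number", "biomass_mg")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(samples$copy_number < 0, na.rm = TRUE))
    stop("`copy_number` must be non-negative")
  if (any(samples$biomass_mg <= 0, na.rm = TRUE))
    stop("`biomass_mg` must be positive for calibration samples")
  if (per_strain && !"strain" %in% names(samples))
    stop("missing column(s): strain")
  groups <- if (per_strain) split(samples, samples$strain)
            else list(all = samples)
  rows <- list(); unfit <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (nrow(g) < 2L) {
      unfit[[nm]] <- "fewer than 2 samples"; next
    }
    if (length(unique(g$copy_number)) < 2L) {
      unfit[[nm]] <- "zero-variance copy numbers"; next
    }
    fit <- if (through_origin)
      stats::lm(biomass_mg ~ 0 + copy_number, data = g)
    else
      stats::lm(biomass_mg ~ copy_number, data = g)
    co <- stats::coef(fit)
    slope <- unname(co[["copy_number"]])
    intercept <- if (through_origin) 0 else unname(co[["(Intercept)"]])
    ss_tot <- sum((g$biomass_mg - mean(g$biomass_mg))^2)
    r2 <- if (ss_tot == 0) NA_real_
          else 1 - sum(stats::residuals(fit)^2) / ss_tot
    rows[[nm]] <- data.frame(strain = nm, slope = slope,
                             intercept = intercept, r_squared = r2,
                             n_samples = nrow(g))
  }
  if (length(unfit))
    warning("unfittable strain(s): ",
            paste(names(unfit), unlist(unfit), sep = ": ", collapse = "; "))
  if (!length(rows))
    stop("no strain could be fitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unfittable") <- unfit
  class(out) <- c("calibration_models", class(out))
  out
}

#' Convert qPCR copy numbers to fungal biomass
#'
#' Applies a fitted calibration, `biomass = slope * copies + intercept`.
#' Negative predictions (possible with a free intercept at low copy
#' numbers) are clamped to 0 and flagged.
#'
#' @param model one row of a `calibration_models` table (or any list with
#'   `slope` and `intercept`).
#' @param copy_number non-negative copy number(s).
#' @return numeric biomass in mg, with attribute `clamped` (logical vector)
#'   marking predictions clamped to zero; a warning is emitted when any are.
#' @export
copies_to_biomass <- function(model, copy_number) {
  if (is.data.frame(model)) {
    if (nrow(model) != 1L)
      stop("`model` must be a single calibration (one row); got ",
           nrow(model))
    model <- as.list(model)
  }
  if (is.null(model$slope) || is.null(model$intercept))
    stop("`model` must carry `slope` and `intercept`")
  if (any(copy_number < 0)) stop("`copy_number` must be non-negative")
  pred <- model$slope * copy_number + model$intercept
  clamped <- pred < 0
  if (any(clamped)) {
    warning(sum(clamped), " negative biomass prediction(s) clamped to 0")
    pred[clamped] <- 0
  }
  attr(pred, "clamped") <- clamped
  pred
}

#' Quantum-dot transfer efficiency per unit focal hyphae
#'
#' Network transfer efficiency is the amount of quantum-dot-apatite signal
#' in the total focal root divided by the focal extraradical hyphae: the
#' sum of fungal biomass in the focal compartment and focal-strain fungal
#' biomass in the central compartment. Fluorescence units are relative, so
#' efficiencies compare rates between treatments rather than absolute
#' phosphorus amounts.
#'
#' @param records data.frame with columns `replicate_id`,
#'   `qd_signal_focal_root`, `biomass_focal_comp_mg`,
#'   `biomass_focal_in_central_mg`.
#' @return a list of class `efficiency_result`: `$table` (input rows plus
#'   `efficiency`, fluorescence units per mg) and `$excluded` (replicates
#'   with a zero denominator, reported rather than silently dropped).
#' @export
transfer_efficiency <- function(records) {
  req <- c("replicate_id", "qd_signal_focal_root",
           "biomass_focal_comp_mg", "biomass_focal_in_central_mg")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- req[-1]
  for (nm in num) {
    if (any(records[[nm]] < 0, na.rm = TRUE))
      stop("`", nm, "` must be non-negative")
  }
  denom <- records$biomass_focal_comp_mg + records$biomass_focal_in_central_mg
  ok <- denom > 0
  tab <- records[ok, , drop = FALSE]
  tab$efficiency <- tab$qd_signal_focal_root /
    (tab$biomass_focal_comp_mg + tab$biomass_focal_in_central_mg)
  rownames(tab) <- NULL
  excluded <- records[!ok, , drop = FALSE]
  rownames(excluded) <- NULL
  if (nrow(excluded))
    warning(nrow(excluded),
            " replicate(s) excluded: zero focal-hyphae biomass denominator")
  structure(list(table = tab, excluded = excluded),
            class = "efficiency_result")
}
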