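#' @name calibration
#' @title Phosphate-to-drinking-water calibration equations
#'
#' @description
#' Published rodent calibration equations relate bioapatite phosphate
#' delta18O to local surface (drinking) water delta18O linearly.  Equations
#' are stored exactly in the printed form
#' `d18O_LW = (d18O_PO4 - a) / b`; the forward map `d18O_PO4 = a + b *
#' d18O_LW` is derived algebraically, never stored separately.  The registry
#' ships with three equations:
#'
#' \tabular{llll}{
#'   name \tab a \tab b \tab tissue basis \cr
#'   `luz_kolodny_1985` \tab 17.88 \tab 0.49 \tab bone (laboratory rats) \cr
#'   `longinelli_2003` \tab 23.07 \tab 1.14 \tab bone (wild murids/arvicolids) \cr
#'   `navarro_2004` \tab 20.98 \tab 0.572 \tab tooth (wild arvicolids) \cr
#' }
#'
#' Applying a bone-based equation to tooth data (or vice versa) is allowed
#' but raises a tissue-mismatch warning: the two tissue classes integrate
#' different time windows and a seasonal bias results.
NULL

.calib_env <- new.env(parent = emptyenv())

#' Construct a calibration equation
#'
#' @param name unique registry identifier.
#' @param intercept_a per-mil intercept `a` of `d18O_LW = (d18O_PO4 - a)/b`.
#' @param slope_b dimensionless slope `b`; must be nonzero.
#' @param tissue_basis `"bone"`, `"tooth"` or `"mixed"`.
#' @param taxa character vector of genera the equation was developed on.
#' @param valid_lw_range optional `c(min, max)` per-mil water range within
#'   which the equation was calibrated; results outside it are flagged as
#'   extrapolations.
#' @return an object of class `calibration_equation`.
#' @export
calibration_equation <- function(name, intercept_a, slope_b,
                                 tissue_basis = c("bone", "tooth", "mixed"),
                                 taxa = character(),
                                 valid_lw_range = NULL) {
  tissue_basis <- match.arg(tissue_basis)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(intercept_a), is.numeric(slope_b))
  if (slope_b == 0) {
    rodiso_stop("rodiso_invalid_input", "slope_b must be nonzero")
  }
  if (!is.null(valid_lw_range)) {
    stopifnot(length(valid_lw_range) == 2L,
              valid_lw_range[1] <= valid_lw_range[2])
  }
  structure(list(name = name, intercept_a = intercept_a, slope_b = slope_b,
                 tissue_basis = tissue_basis, taxa = as.character(taxa),
                 valid_lw_range = valid_lw_range),
            class = "calibration_equation")
}

#' @export
print.calibration_equation <- function(x, ...) {
  cat("<calibration_equation> ", x$name, ": d18O_LW = (d18O_PO4 - ",
      x$intercept_a, ")/", x$slope_b, "  [", x$tissue_basis, "]\n", sep = "")
  invisible(x)
}

default_calibrations <- function() {
  list(
    calibration_equation("luz_kolodny_1985", 17.88, 0.49, "bone",
                         taxa = "Rattus",
                         # calibrated on waters enriched relative to NW-European
                         # precipitation; flag inversions below -4 per mil
                         valid_lw_range = c(-4, Inf)),
    calibration_equation("longinelli_2003", 23.07, 1.14, "bone",
                         taxa = c("Apodemus", "Pitymus", "Arvicola",
                                  "Microtus")),
    calibration_equation("navarro_2004", 20.98, 0.572, "tooth",
                         taxa = c("Microtus", "Myodes", "Lemmus"))
  )
}

reset_calibration_registry <- function() {
  .calib_env$registry <- list()
  for (eq in default_calibrations()) .calib_env$registry[[eq$name]] <- eq
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  reset_calibration_registry()
}

#' Calibration registry
#'
#' `calibration_registry()` lists all registered equations;
#' `get_calibration()` fetches one by name; `register_calibration()` adds a
#' user equation (duplicate names are a conflict error unless
#' `overwrite = TRUE`).
#'
#' @return `calibration_registry()`: a data frame with one row per equation;
#'   `get_calibration()`: a `calibration_equation`.
#' @export
calibration_registry <- function() {
  regs <- .calib_env$registry
  data.frame(
    name = vapply(regs, `[[`, "", "name"),
    intercept_a = vapply(regs, `[[`, 0, "intercept_a"),
    slope_b = vapply(regs, `[[`, 0, "slope_b"),
    tissue_basis = vapply(regs, `[[`, "", "tissue_basis"),
    taxa = vapply(regs, function(e) paste(e$taxa, collapse = ";"), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname calibration_registry
#' @param name registry identifier.
#' @export
get_calibration <- function(name) {
  eq <- .calib_env$registry[[name]]
  if (is.null(eq)) {
    rodiso_stop("rodiso_not_found",
                paste0("no calibration equation named '", name,
                       "'; registered: ",
                       paste(names(.calib_env$registry), collapse = ", ")))
  }
  eq
}

#' @rdname calibration_registry
#' @param eq a `calibration_equation`.
#' @param overwrite logical; allow replacing an existing name.
#' @export
register_calibration <- function(eq, overwrite = FALSE) {
  stopifnot(inherits(eq, "calibration_equation"))
  if (!overwrite && eq$name %in% names(.calib_env$registry)) {
    rodiso_stop("rodiso_conflict",
                paste0("calibration '", eq$name, "' already registered"))
  }
  .calib_env$registry[[eq$name]] <- eq
  invisible(eq)
}

resolve_calibration <- function(eq) {
  if (is.character(eq)) get_calibration(eq) else {
    stopifnot(inherits(eq, "calibration_equation"))
    eq
  }
}

#' Apply a calibration equation
#'
#' `to_local_water()` inverts apatite phosphate delta18O to drinking-water
#' delta18O, `(d18O_po4 - a)/b`; `from_local_water()` is the exact algebraic
#' inverse, `a + b * d18O_lw`.
#'
#' @param eq a `calibration_equation` or a registry name.
#' @param d18O_po4,d18O_lw per-mil input value(s).
#' @return per-mil value(s).  `to_local_water()` attaches a logical
#'   `extrapolated` attribute when the equation declares a calibrated water
#'   range and a result falls outside it.
#' @export
#' @examples
#' to_local_water("navarro_2004", 16.8)     # ~ -7.3 per mil
#' from_local_water("luz_kolodny_1985", -7.3)
to_local_water <- function(eq, d18O_po4) {
  eq <- resolve_calibration(eq)
  stopifnot(all(is.finite(d18O_po4)))
  lw <- (d18O_po4 - eq$intercept_a) / eq$slope_b
  if (!is.null(eq$valid_lw_range)) {
    attr(lw, "extrapolated") <-
      lw < eq$valid_lw_range[1] | lw > eq$valid_lw_range[2]
  }
  lw
}

#' @rdname to_local_water
#' @export
from_local_water <- function(eq, d18O_lw) {
  eq <- resolve_calibration(eq)
  stopifnot(all(is.finite(d18O_lw)))
  eq$intercept_a + eq$slope_b * d18O_lw
}

#' Reconstruct drinking-water delta18O from a dataset
#'
#' Averages the phosphate delta18O of the selected tissues (measured
#' `d18O_po4` where present, otherwise `d18O_co3` converted through
#' [co3_to_po4()]) and inverts the calibration equation.  Each record gets
#' equal weight.  A `rodiso_tissue_mismatch` warning is raised when the
#' equation's tissue basis disagrees with the selected tissues (e.g. a
#' bone-based equation applied to incisor data): the two tissue classes
#' record different formation windows, so a seasonal bias is expected.
#'
#' @param records a `specimen_records` data frame.
#' @param eq a `calibration_equation` or registry name.
#' @param offset per-mil carbonate-phosphate offset (or an
#'   [estimate_offset()] result) used for records lacking measured
#'   phosphate.
#' @param tissue character vector of tissues to include (default: all).
#' @return a list of class `water_estimate`: `d18O_lw`, `sd` (propagated:
#'   standard error of the apatite mean combined with the offset SD scaled by
#'   the converted fraction, divided by `|b|`), `n`, `n_converted`,
#'   `equation`, `tissues`, `extrapolated`.
#' @export
reconstruct_water <- function(records, eq, offset = 10.9, tissue = NULL) {
  stopifnot(inherits(records, "specimen_records"))
  eq <- resolve_calibration(eq)
  offset_sd <- if (inherits(offset, "offset_estimate")) offset$sd_offset else
    NA_real_
  offset_mean <- if (inherits(offset, "offset_estimate"))
    offset$mean_offset else offset

  sel <- rep(TRUE, nrow(records))
  if (!is.null(tissue)) sel <- records$tissue %in% tissue
  sel <- sel & (!is.na(records$d18O_po4) | !is.na(records$d18O_co3))
  if (!any(sel)) {
    rodiso_stop("rodiso_empty_selection",
                "no records with oxygen data in the selected tissues")
  }
  r <- records[sel, , drop = FALSE]
  use_po4 <- !is.na(r$d18O_po4)
  po4 <- ifelse(use_po4, r$d18O_po4,
                co3_to_po4(r$d18O_co3, offset_mean))
  tiss_class <- ifelse(r$tissue == "bone", "bone", "tooth")
  if (eq$tissue_basis != "mixed" && any(tiss_class != eq$tissue_basis)) {
    rodiso_warn("rodiso_tissue_mismatch",
                paste0("equation '", eq$name, "' is ", eq$tissue_basis,
                       "-based but selection contains ",
                       paste(unique(tiss_class[tiss_class != eq$tissue_basis]),
                             collapse = ", "),
                       " tissue; reconstructed water may be seasonally biased"))
  }
  m <- mean(po4)
  n <- length(po4)
  f_conv <- mean(!use_po4)
  se_apatite <- if (n > 1) stats::sd(po4) / sqrt(n) else NA_real_
  sd_lw <- if (is.na(se_apatite)) NA_real_ else
    sqrt(se_apatite^2 +
           (if (is.na(offset_sd)) 0 else (f_conv * offset_sd)^2)) /
      abs(eq$slope_b)
  lw <- to_local_water(eq, m)
  structure(list(d18O_lw = as.numeric(lw),
                 sd = sd_lw,
                 n = n,
                 n_converted = sum(!use_po4),
                 equation = eq$name,
                 tissues = sort(unique(r$tissue)),
                 extrapolated = isTRUE(any(attr(lw, "extrapolated")))),
            class = "water_estimate")
}

#' @export
print.water_estimate <- function(x, ...) {
  cat("<water_estimate> d18O_LW = ", round_report(x$d18O_lw),
      if (!is.na(x$sd)) paste0(" +/- ", round_report(x$sd, 2)) else "",
      " per mil (", x$equation, "; n = ", x$n, ", ", x$n_converted,
      " converted from CO3", if (x$extrapolated) "; EXTRAPOLATED" else "",
      ")\n", sep = "")
  invisible(x)
}
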