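#' Delta notation from raw isotope ratios
#'
#' Converts measured heavy/light isotope ratios (18O/16O or 13C/12C) to the
#' per-mil delta notation relative to a reference standard:
#' `delta = (R_sample / R_standard - 1) * 1000`.
#'
#' @param r_sample isotope ratio of the sample (strictly positive).
#' @param r_standard isotope ratio of the reference standard (strictly
#'   positive), e.g. VSMOW for oxygen, VPDB for carbon.
#' @return per-mil delta value(s); vectorized with the usual recycling.
#' @export
#' @examples
#' delta_from_ratios(0.00206556, 0.0020052)  # ~30.1 per mil
delta_from_ratios <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(r_sample <= 0)) {
    rodiso_stop("rodiso_invalid_input", "r_sample must be strictly positive")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    rodiso_stop("rodiso_invalid_input", "r_standard must be strictly positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Carbonate-phosphate oxygen isotope offset of a single sample
#'
#' Sign convention, fixed package-wide: `Delta18O_CO3-PO4 = d18O_co3 -
#' d18O_po4` (positive, around 9-11 per mil in mammal bioapatite).
#'
#' @param co3 delta18O of structural carbonate, per mil vs VSMOW.
#' @param po4 delta18O of phosphate, per mil vs VSMOW.
#' @param id optional record label(s) used in error messages.
#' @return per-mil offset(s).
#' @export
pairwise_offset <- function(co3, po4, id = NULL) {
  bad <- is.na(co3) | is.na(po4)
  if (any(bad)) {
    where <- if (is.null(id)) paste0("position ", which(bad)[1]) else
      id[which(bad)[1]]
    rodiso_stop("rodiso_missing_data",
                paste0("both d18O_co3 and d18O_po4 required; missing in ",
                       where))
  }
  co3 - po4
}

#' Estimate the carbonate-phosphate offset over a dataset
#'
#' Computes per-pair `Delta18O_CO3-PO4` for every record carrying both oxygen
#' values, and its arithmetic mean and sample SD (n-1 denominator).  The SD is
#' absent (`NA`) for a single pair.
#'
#' @param records a `specimen_records` data frame.
#' @param tissue optional character vector of tissues to restrict to.
#' @return an object of class `offset_estimate`: a list with `n_pairs`,
#'   `mean_offset`, `sd_offset` and a `per_pair` data frame
#'   (`specimen_id`, `tissue`, `offset`).
#' @export
#' @examples
#' tab3 <- read_dataset(system.file("extdata", "table3_arvicola.csv",
#'                                  package = "rodiso"))
#' estimate_offset(tab3)                   # overall mean ~10.9 per mil
#' estimate_offset(tab3, tissue = "bone")  # ~10.7 per mil
estimate_offset <- function(records, tissue = NULL) {
  stopifnot(inherits(records, "specimen_records"))
  sel <- !is.na(records$d18O_co3) & !is.na(records$d18O_po4)
  if (!is.null(tissue)) sel <- sel & records$tissue %in% tissue
  if (!any(sel)) {
    rodiso_stop("rodiso_empty_selection",
                "no records with both d18O_co3 and d18O_po4 in selection")
  }
  r <- records[sel, , drop = FALSE]
  off <- pairwise_offset(r$d18O_co3, r$d18O_po4, id = r$specimen_id)
  structure(
    list(n_pairs = length(off),
         mean_offset = mean(off),
         sd_offset = sample_sd(off),
         per_pair = data.frame(specimen_id = r$specimen_id,
                               tissue = r$tissue,
                               offset = off,
                               stringsAsFactors = FALSE)),
    class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  sd_txt <- if (is.na(x$sd_offset)) "" else
    paste0(" +/- ", round_report(x$sd_offset))
  cat("<offset_estimate> Delta18O_CO3-PO4 = ",
      round_report(x$mean_offset), sd_txt,
      " per mil (n = ", x$n_pairs, ")\n", sep = "")
  invisible(x)
}

#' Convert carbonate delta18O to phosphate-equivalent delta18O
#'
#' Subtracts the carbonate-phosphate offset; first-order uncertainty
#' propagation assumes independence of the input and offset uncertainties
#' (only +/-1 sigma values are available, no covariances).
#'
#' @param d18O_co3 per-mil carbonate value(s) vs VSMOW.
#' @param offset per-mil offset, or an [estimate_offset()] result (its mean
#'   and SD are then used).
#' @param input_sd,offset_sd optional 1-sigma uncertainties; when either is
#'   given the result carries an `sd` attribute
#'   `sqrt(input_sd^2 + offset_sd^2)`.
#' @return phosphate-equivalent per-mil value(s).
#' @export
co3_to_po4 <- function(d18O_co3, offset = 10.9, input_sd = NULL,
                       offset_sd = NULL) {
  if (inherits(offset, "offset_estimate")) {
    if (is.null(offset_sd) && !is.na(offset$sd_offset)) {
      offset_sd <- offset$sd_offset
    }
    offset <- offset$mean_offset
  }
  if (!is.finite(offset)) {
    rodiso_stop("rodiso_invalid_input", "offset must be finite")
  }
  out <- d18O_co3 - offset
  if (!is.null(input_sd) || !is.null(offset_sd)) {
    attr(out, "sd") <- sqrt(sum(c(input_sd, offset_sd)^2))
  }
  out
}

#' @rdname co3_to_po4
#' @param d18O_po4 per-mil phosphate value(s); exact inverse of
#'   [co3_to_po4()].
#' @export
po4_to_co3 <- function(d18O_po4, offset = 10.9) {
  if (inherits(offset, "offset_estimate")) offset <- offset$mean_offset
  if (!is.finite(offset)) {
    rodiso_stop("rodiso_invalid_input", "offset must be finite")
  }
  d18O_po4 + offset
}
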