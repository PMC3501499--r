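#' Diet reconstruction model
#'
#' Parameters for carbon-isotope diet reconstruction: the diet-to-bioapatite
#' enrichment (+9.9 per mil for rodent bone) and the C3 / C4 plant
#' end-member means (-27 and -13 per mil vs VPDB) for two-end-member linear
#' mixing.  CAM plants are ignored (minor dietary role for herbivorous
#' mammals).
#'
#' @param enrichment per-mil diet-to-apatite enrichment, in \[0, 20\].
#' @param c3_endmember,c4_endmember per-mil end-member diet values;
#'   `c4_endmember` must exceed `c3_endmember`.
#' @return an object of class `diet_model`.
#' @export
diet_model <- function(enrichment = 9.9, c3_endmember = -27,
                       c4_endmember = -13) {
  stopifnot(is.numeric(enrichment), is.numeric(c3_endmember),
            is.numeric(c4_endmember))
  if (enrichment < 0 || enrichment > 20) {
    rodiso_stop("rodiso_invalid_input", "enrichment must lie in [0, 20]")
  }
  if (c4_endmember <= c3_endmember) {
    rodiso_stop("rodiso_invalid_input",
                "c4_endmember must exceed c3_endmember")
  }
  structure(list(enrichment = enrichment, c3_endmember = c3_endmember,
                 c4_endmember = c4_endmember), class = "diet_model")
}

#' Apatite delta13C to diet delta13C
#'
#' A pure shift: subtracts the diet-to-apatite enrichment.
#'
#' @param d13C_apatite per-mil apatite value(s) vs VPDB.
#' @param model a [diet_model()].
#' @return per-mil diet value(s).
#' @export
#' @examples
#' apatite_to_diet(-9.6)   # -19.5: Rattus-type opportunist
#' apatite_to_diet(-19.7)  # -29.6: pure C3 grazer
apatite_to_diet <- function(d13C_apatite, model = diet_model()) {
  stopifnot(inherits(model, "diet_model"))
  d13C_apatite - model$enrichment
}

#' C4 fraction of a diet by two-end-member mixing
#'
#' `(d13C_diet - c3) / (c4 - c3)`, clipped to \[0, 1\].  Raw values outside
#' \[-0.05, 1.05\] are flagged (attribute `out_of_range`): slightly depleted
#' pure-C3 diets (subcanopy feeding reaches -36 to -32 per mil) should
#' surface rather than clamp silently.
#'
#' @param d13C_diet per-mil diet value(s).
#' @param model a [diet_model()].
#' @return fraction(s) in \[0, 1\] with logical attribute `out_of_range`.
#' @export
c4_fraction <- function(d13C_diet, model = diet_model()) {
  stopifnot(inherits(model, "diet_model"))
  raw <- (d13C_diet - model$c3_endmember) /
    (model$c4_endmember - model$c3_endmember)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "out_of_range") <- raw < -0.05 | raw > 1.05
  out
}

#' Per-group diet summary
#'
#' Applies [apatite_to_diet()] to every record with a delta13C value and
#' aggregates per group with the same mean / sample-SD / range conventions as
#' [summarize_groups()]; the C4 fraction is computed on the group mean diet.
#'
#' @param records a `specimen_records` data frame.
#' @param model a [diet_model()].
#' @param by grouping column(s), default `"species"`.
#' @return data frame with the grouping columns plus `n`, `diet_mean`,
#'   `diet_sd`, `diet_min`, `diet_max`, `c4_fraction`, `flag` (logical
#'   out-of-range flag of the mixing model).  Groups without any delta13C
#'   value are omitted with a message.
#' @export
diet_summary <- function(records, model = diet_model(), by = "species") {
  stopifnot(inherits(records, "specimen_records"))
  has_c <- !is.na(records$d13C)
  keys <- records[, by, drop = FALSE]
  all_groups <- unique(keys)
  kept <- records[has_c, , drop = FALSE]
  if (!nrow(kept)) {
    rodiso_stop("rodiso_empty_selection", "no records with d13C values")
  }
  diet <- apatite_to_diet(kept$d13C, model)
  gkey <- interaction(kept[, by, drop = FALSE], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_along(diet), gkey), function(i) {
    g <- kept[i[1], by, drop = FALSE]
    d <- diet[i]
    mm <- mean(d)
    frac <- c4_fraction(mm, model)
    cbind(g, data.frame(n = length(d), diet_mean = mm,
                        diet_sd = sample_sd(d),
                        diet_min = min(d), diet_max = max(d),
                        c4_fraction = as.numeric(frac),
                        flag = as.logical(attr(frac, "out_of_range"))))
  }))
  if (nrow(all_groups) > length(unique(gkey))) {
    message("diet_summary: ", nrow(all_groups) - length(unique(gkey)),
            " group(s) without d13C values omitted")
  }
  rownames(out) <- NULL
  out[order(out[[by[1]]]), , drop = FALSE]
}
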