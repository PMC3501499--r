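#' Per-group summaries of an isotope variable
#'
#' Mean, sample SD (n-1), min, max and range width per group, mirroring the
#' "+/- 1 sigma and range of variation" layout of community summary tables.
#' Missing values are excluded and counted, never imputed.
#'
#' @param records a `specimen_records` data frame.
#' @param variable one of `"d18O_co3"`, `"d18O_po4"`, `"d13C"`.
#' @param by grouping column(s), default `c("species", "tissue")`.
#' @return data frame with grouping columns plus `n`, `mean`, `sd`, `min`,
#'   `max`, `range_width`, `n_missing`.
#' @export
summarize_groups <- function(records, variable,
                             by = c("species", "tissue")) {
  stopifnot(inherits(records, "specimen_records"))
  if (!variable %in% rodiso_variables) {
    rodiso_stop("rodiso_invalid_input",
                paste0("unknown variable '", variable, "'; must be one of ",
                       paste(rodiso_variables, collapse = ", ")))
  }
  v <- records[[variable]]
  gkey <- interaction(records[, by, drop = FALSE], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_along(v), gkey), function(i) {
    g <- records[i[1], by, drop = FALSE]
    x <- v[i]
    n_miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    cbind(g, data.frame(n = length(x), mean = mean(x), sd = sample_sd(x),
                        min = min(x), max = max(x),
                        range_width = max(x) - min(x), n_missing = n_miss))
  }))
  if (is.null(out)) {
    rodiso_stop("rodiso_empty_selection",
                paste0("no non-missing ", variable, " values"))
  }
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Paired within-individual tissue offsets
#'
#' For every specimen measured in both tissues, the offset
#' `value(tissue_a) - value(tissue_b)` (e.g. incisor minus bone).  Reports
#' the count and proportion of positive offsets and the per-species SD of
#' the offsets — the signature of differing tissue formation windows under
#' seasonal water and mortality bias.
#'
#' @param records a `specimen_records` data frame.
#' @param tissue_a,tissue_b tissue names.
#' @param variable isotope column to compare.
#' @return list of class `paired_offset_report`: `pairs` (data frame
#'   `specimen_id`, `species`, `tissue_a`, `tissue_b`, `offset`),
#'   `n_positive`, `proportion_positive`, `offset_sd_by_species`.
#' @export
paired_tissue_offsets <- function(records, tissue_a, tissue_b, variable) {
  stopifnot(inherits(records, "specimen_records"),
            tissue_a %in% rodiso_tissues, tissue_b %in% rodiso_tissues,
            variable %in% rodiso_variables)
  a <- records[records$tissue == tissue_a & !is.na(records[[variable]]), ]
  b <- records[records$tissue == tissue_b & !is.na(records[[variable]]), ]
  common <- intersect(a$specimen_id, b$specimen_id)
  if (!length(common)) {
    rodiso_stop("rodiso_empty_selection",
                paste0("no specimens with ", variable, " in both ",
                       tissue_a, " and ", tissue_b))
  }
  a <- a[match(common, a$specimen_id), ]
  b <- b[match(common, b$specimen_id), ]
  off <- a[[variable]] - b[[variable]]
  pairs <- data.frame(specimen_id = common, species = a$species,
                      tissue_a = tissue_a, tissue_b = tissue_b,
                      offset = off, stringsAsFactors = FALSE)
  sd_by_sp <- vapply(split(off, a$species), sample_sd, 0)
  structure(list(pairs = pairs,
                 n_positive = sum(off > 0),
                 proportion_positive = mean(off > 0),
                 offset_sd_by_species = sd_by_sp),
            class = "paired_offset_report")
}

#' @export
print.paired_offset_report <- function(x, ...) {
  cat("<paired_offset_report> ", nrow(x$pairs), " pair(s) (",
      x$pairs$tissue_a[1], " - ", x$pairs$tissue_b[1], "): ",
      x$n_positive, " positive (",
      round_report(100 * x$proportion_positive, 0), "%)\n", sep = "")
  invisible(x)
}

#' Intra-jaw isotope ranges per specimen
#'
#' Per-specimen max-minus-min across the available tooth positions (incisor
#' and molars M1-M3), plus the molar-only (M1-M3) range.  Specimens with
#' fewer than two measured teeth are skipped with a message; molar-only
#' range is `NA` with fewer than two molars.
#'
#' @param records a `specimen_records` data frame.
#' @param variable isotope column.
#' @return data frame `specimen_id`, `species`, `n_teeth`, `overall_range`,
#'   `n_molars`, `molar_range`.
#' @export
intra_jaw_ranges <- function(records, variable) {
  stopifnot(inherits(records, "specimen_records"),
            variable %in% rodiso_variables)
  teeth <- records[records$tissue != "bone" & !is.na(records[[variable]]), ]
  res <- lapply(split(seq_len(nrow(teeth)), teeth$specimen_id), function(i) {
    x <- teeth[[variable]][i]
    if (length(x) < 2L) return(NULL)
    mol <- x[teeth$tissue[i] != "incisor"]
    data.frame(specimen_id = teeth$specimen_id[i[1]],
               species = teeth$species[i[1]],
               n_teeth = length(x),
               overall_range = max(x) - min(x),
               n_molars = length(mol),
               molar_range = if (length(mol) >= 2L) max(mol) - min(mol)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, TRUE))
  if (skipped) message("intra_jaw_ranges: ", skipped,
                       " specimen(s) with <2 teeth skipped")
  out <- do.call(rbind, res)
  if (is.null(out)) {
    rodiso_stop("rodiso_empty_selection",
                "no specimen with >=2 measured teeth")
  }
  rownames(out) <- NULL
  out
}

as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(vapply(groups, length, 0L) < 2L)) {
    rodiso_stop("rodiso_invalid_input", "every group needs n >= 2")
  }
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition: `F = MS_between / MS_within`, with
#' the p-value from the F distribution.  Zero pooled within-group variance
#' is a degenerate-variance error, not an infinite F.
#'
#' @param groups list of >= 2 numeric vectors, each with n >= 2.
#' @return list of class `anova_result`: `statistic` (F), `df_between`,
#'   `df_within`, `p_value`, `ss_between`, `ss_within`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5, df (1, 4)
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  ni <- vapply(groups, length, 0L)
  mi <- vapply(groups, mean, 0)
  grand <- sum(ni * mi) / sum(ni)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- sum(ni) - length(groups)
  if (ssw <= 0) {
    rodiso_stop("rodiso_degenerate_variance",
                "zero within-group variance; F undefined")
  }
  f <- (ssb / df1) / (ssw / df2)
  structure(list(statistic = f, df_between = df1, df_within = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range adjusted p-values.
#' Unequal group sizes use the Tukey-Kramer convention
#' `se = sqrt(MSW/2 * (1/n_i + 1/n_j))`.
#'
#' @param groups list of >= 2 numeric vectors (named, or `g1`, `g2`, ...
#'   labels are generated); each n >= 2.
#' @param alpha significance level for the `significant` flag
#'   (0.05 and 0.01 are the conventional choices).
#' @return data frame: `group_a`, `group_b`, `diff`, `se`, `q`,
#'   `p_adjusted`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  ni <- vapply(groups, length, 0L)
  mi <- vapply(groups, mean, 0)
  k <- length(groups)
  df2 <- sum(ni) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df2
  if (msw <= 0) {
    rodiso_stop("rodiso_degenerate_variance",
                "zero within-group variance; Tukey HSD undefined")
  }
  idx <- utils::combn(k, 2)
  res <- apply(idx, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- unname(mi[i] - mi[j])
    se <- unname(sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j])))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    c(diff = d, se = se, q = q, p = p)
  })
  out <- data.frame(group_a = names(groups)[idx[1, ]],
                    group_b = names(groups)[idx[2, ]],
                    diff = res["diff", ], se = res["se", ], q = res["q", ],
                    p_adjusted = res["p", ],
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square approximation for the
#' p-value; the non-parametric complement used when ANOVA normality fails.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list of class `kw_result`: `statistic` (H, tie-corrected), `df`,
#'   `p_value`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))  # H = 2.4
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (length(unique(x)) == 1L) {
    rodiso_stop("rodiso_degenerate_variance",
                "all values identical; H undefined")
  }
  rk <- rank(x)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  ri <- tapply(rk, g, sum)
  ni <- tapply(rk, g, length)
  h <- 12 / (n * (n + 1)) * sum(ri^2 / ni) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  df <- length(groups) - 1L
  structure(list(statistic = h, df = df,
                 p_value = stats::pchisq(h, df, lower.tail = FALSE)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat("Kruskal-Wallis: H(", x$df, ") = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Flag outlying values in a group
#'
#' A value is flagged when its distance from the group median exceeds `k`
#' times the sample SD of the *remaining* values (leave-one-out SD, so a
#' gross outlier cannot mask itself).  Report-only: values are flagged,
#' never removed — exclusion is an explicit caller decision.
#'
#' @param x numeric vector, n >= 3.
#' @param k multiplier (default 3); `Inf` disables the rule.
#' @return logical vector of flags.
#' @export
flag_outliers <- function(x, k = 3) {
  x <- as.numeric(x)
  if (sum(!is.na(x)) < 3L) {
    rodiso_stop("rodiso_invalid_input", "flag_outliers needs n >= 3")
  }
  med <- stats::median(x, na.rm = TRUE)
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return(FALSE)
    s <- sample_sd(x[-i])
    if (is.na(s) || s == 0) return(abs(x[i] - med) > 0)
    abs(x[i] - med) > k * s
  }, TRUE)
}
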