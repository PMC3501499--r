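#' Bootstrap minimum sample size for a population isotope mean
#'
#' Empirical procedure for deciding how many specimens are needed to
#' estimate a population delta18O mean: for every subsample size `n_sub`
#' from 2 to `n - 1`, draw `n_replicates` random subsamples (without
#' replacement within a subsample), count how many subsample means fall
#' within +/- 1 sigma (the full sample's n-1 SD, boundary inclusive) of the
#' full-sample mean, and average that count over `n_repeats` independent
#' evaluations.  An `n_sub` whose averaged count reaches 950 of 1000
#' (99%: 990) is adequate at the 95% (99%) confidence level.
#'
#' Reproducibility: one master `seed` spawns an independent substream per
#' `(n_sub, repeat)` via a fixed integer hash, so counts do not depend on
#' evaluation order.
#'
#' @param values numeric vector of per-mil measurements, n >= 3.
#' @param n_replicates subsamples drawn per evaluation (default 1000).
#' @param n_repeats independent evaluations averaged (default 100).
#' @param sigma_multiplier half-width of the acceptance window in full-sample
#'   SDs (default 1).
#' @param seed master integer seed.
#' @param replace draw subsamples with replacement instead (sensitivity
#'   mode; the standard procedure subsamples distinct specimens).
#' @param group_key optional label carried into the result.
#' @return object of class `bootstrap_result`: `group_key`, `n_full`,
#'   `full_mean`, `full_sd`, `counts` (named numeric, averaged count per
#'   `n_sub` in `2:(n_full-1)`), `n_replicates`, `n_repeats`, `degenerate`,
#'   `min_n_for_95`, `min_n_for_99` (thresholds scaled proportionally when
#'   `n_replicates != 1000`; `NA` when never reached).
#' @export
#' @examples
#' b <- bootstrap_min_sample_size(rnorm(10, 27, 1.2), n_replicates = 200,
#'                                n_repeats = 10, seed = 42)
#' b$counts
bootstrap_min_sample_size <- function(values, n_replicates = 1000L,
                                      n_repeats = 100L,
                                      sigma_multiplier = 1,
                                      seed = 1L, replace = FALSE,
                                      group_key = NULL) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n < 3L) {
    rodiso_stop("rodiso_insufficient_data",
                "bootstrap_min_sample_size needs n >= 3 values")
  }
  stopifnot(n_replicates >= 1L, n_repeats >= 1L, sigma_multiplier >= 0)
  full_mean <- mean(values)
  full_sd <- stats::sd(values)
  sizes <- 2:(n - 1L)
  degenerate <- full_sd == 0
  if (degenerate) {
    # inclusive window of zero width: every subsample mean qualifies
    counts <- stats::setNames(rep(as.numeric(n_replicates), length(sizes)),
                              sizes)
  } else {
    lo <- full_mean - sigma_multiplier * full_sd
    hi <- full_mean + sigma_multiplier * full_sd
    counts <- vapply(sizes, function(k) {
      per_repeat <- vapply(seq_len(n_repeats), function(rep_i) {
        set.seed(substream_seed(seed, k, rep_i))
        means <- vapply(seq_len(n_replicates), function(j) {
          mean(values[sample.int(n, k, replace = replace)])
        }, 0)
        sum(means >= lo & means <= hi)
      }, 0)
      mean(per_repeat)
    }, 0)
    names(counts) <- sizes
  }
  thr95 <- 0.95 * n_replicates
  thr99 <- 0.99 * n_replicates
  min_n <- function(thr) {
    ok <- sizes[counts >= thr]
    if (length(ok)) ok[1] else NA_integer_
  }
  structure(list(group_key = group_key, n_full = n, full_mean = full_mean,
                 full_sd = full_sd, counts = counts,
                 n_replicates = n_replicates, n_repeats = n_repeats,
                 sigma_multiplier = sigma_multiplier,
                 degenerate = degenerate,
                 min_n_for_95 = min_n(thr95), min_n_for_99 = min_n(thr99)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>",
      if (!is.null(x$group_key)) paste0(" [", paste(x$group_key,
                                                    collapse = ", "), "]"),
      " n = ", x$n_full, ", mean = ", round_report(x$full_mean),
      " +/- ", round_report(x$full_sd), "\n", sep = "")
  print(round(x$counts))
  cat("min n_sub: ", x$min_n_for_95, " (95%), ", x$min_n_for_99,
      " (99%)\n", sep = "")
  invisible(x)
}

#' Minimum adequate sample size per group
#'
#' Tabulates, per group, the smallest `n_sub` whose averaged count reaches
#' `confidence * n_replicates`.  Accepts either a list of
#' [bootstrap_min_sample_size()] results or a long-format counts table
#' (columns `group`, `n_sub`, `count`, optional logical `lower_bound` for
#' published ">990"-style cells, which compare with >= semantics: a lower
#' bound of 990 proves any threshold <= 990 and nothing above it).
#'
#' @param results list of `bootstrap_result` objects, or a data frame as
#'   described above.
#' @param confidence fraction in (0, 1), typically 0.95 or 0.99.
#' @param n_replicates replicate count the table is out of (default 1000;
#'   ignored for `bootstrap_result` input, which carries its own).
#' @return data frame `group`, `min_n_sub` (`NA` when the confidence level
#'   is never reached).
#' @export
minimum_n_report <- function(results, confidence = 0.95,
                             n_replicates = 1000L) {
  stopifnot(is.numeric(confidence), confidence > 0, confidence < 1)
  if (is.data.frame(results)) {
    stopifnot(all(c("group", "n_sub", "count") %in% names(results)))
    thr <- confidence * n_replicates
    out <- do.call(rbind, lapply(split(results, results$group), function(g) {
      g <- g[order(g$n_sub), ]
      ok <- g$count >= thr
      data.frame(group = g$group[1],
                 min_n_sub = if (any(ok)) g$n_sub[ok][1] else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stopifnot(all(vapply(results, inherits, TRUE, "bootstrap_result")))
    out <- do.call(rbind, lapply(results, function(b) {
      thr <- confidence * b$n_replicates
      sizes <- as.integer(names(b$counts))
      ok <- sizes[b$counts >= thr]
      data.frame(group = if (is.null(b$group_key)) NA_character_ else
                   paste(b$group_key, collapse = "/"),
                 min_n_sub = if (length(ok)) ok[1] else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Read a published bootstrap-counts table
#'
#' Long-format CSV `group,n_sub,count,lower_bound` where `lower_bound` is
#' `TRUE` for cells published only as a bound (e.g. ">990", stored as 990).
#'
#' @param path CSV path.
#' @return data frame suitable for [minimum_n_report()].
#' @export
read_bootstrap_counts <- function(path) {
  if (!file.exists(path)) {
    rodiso_stop("rodiso_io_error", paste0("file not found: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "n_sub", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    rodiso_stop("rodiso_format_error",
                paste0("malformed header: missing ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (is.null(df$lower_bound)) df$lower_bound <- FALSE
  df$lower_bound <- as.logical(df$lower_bound)
  df$n_sub <- as.integer(df$n_sub)
  df$count <- as.numeric(df$count)
  df
}
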