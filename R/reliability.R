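# Test-retest reliability of microstate metrics: absolute-agreement ICC,
# Fisher-z aggregation, permutation testing, and category labels.

#' Absolute-agreement intraclass correlation (two-way, single measure)
#'
#' ICC(A,1) in McGraw-Wong terms: subjects are random rows, sessions
#' random columns, and systematic session offsets count against agreement
#' (more stringent than the consistency form). From the two-way ANOVA
#' mean squares (MSR rows, MSC columns, MSE residual, k = 2 sessions):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#'
#' @param x numeric matrix or data frame, n subjects x 2 sessions
#'   (n >= 3).
#' @return Scalar ICC, or `NA` (flagged missing) when either session has
#'   zero variance or any value is missing.
#' @export
icc_a1 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("x must have exactly 2 columns (sessions)")
  if (anyNA(x)) return(NA_real_)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects")
  if (stats::sd(x[, 1]) == 0 || stats::sd(x[, 2]) == 0) return(NA_real_)
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Fisher-z mean of correlation-type coefficients
#'
#' Individual coefficients are z-transformed (`atanh`), averaged over the
#' non-missing values, and the average is back-transformed (`tanh`).
#' Values at or beyond +/-1 are clamped to +/-(1 - 1e-6) with a warning.
#'
#' @param iccs numeric vector of coefficients in `(-1, 1)` (NAs dropped).
#' @param warn warn when clamping (default `TRUE`); the permutation null
#'   loop clamps silently.
#' @return Scalar back-transformed mean, `NA` if nothing to average.
#' @export
fisher_mean <- function(iccs, warn = TRUE) {
  v <- iccs[!is.na(iccs)]
  if (!length(v)) return(NA_real_)
  if (any(abs(v) >= 1)) {
    if (warn) warning("coefficient(s) at or beyond +/-1 clamped for z-transform")
    v <- pmin(pmax(v, -1 + 1e-6), 1 - 1e-6)
  }
  tanh(mean(atanh(v)))
}

#' Reliability category of an ICC
#'
#' Below .50 poor; .50 to .75 moderate; .75 to .90 good; .90 and above
#' excellent (boundaries closed on the left: 0.50 is moderate, 0.90 is
#' excellent).
#'
#' @param value numeric ICC (vectorized).
#' @return Character vector of categories.
#' @export
classify_icc <- function(value) {
  cut(value, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Pair two sessions of per-subject microstate metrics
#'
#' @param session_a,session_b lists of `microstate_metrics`, one per
#'   subject, in the same subject order and with the same template set.
#' @param subjects optional subject identifiers.
#' @param pairing_label free-text description of the pairing.
#' @return A `paired_metrics` object.
#' @export
paired_metrics <- function(session_a, session_b, subjects = NULL,
                           pairing_label = "") {
  if (length(session_a) != length(session_b))
    stop("sessions have different subject counts")
  la <- session_a[[1]]$template_labels
  if (!all(vapply(c(session_a, session_b),
                  function(m) identical(m$template_labels, la), logical(1))))
    stop("template labels differ across sessions/subjects")
  if (is.null(subjects)) subjects <- paste0("S", seq_along(session_a))
  structure(list(subjects = subjects, session_a = session_a,
                 session_b = session_b, pairing_label = pairing_label),
            class = "paired_metrics")
}

# n x cells matrix of one metric across subjects; transitions flattened
metric_matrix <- function(metrics_list, metric) {
  if (metric == "transition") {
    t(vapply(metrics_list, function(m) {
      tr <- m$transition
      tr[row(tr) != col(tr)]
    }, numeric(metrics_list[[1]]$k * (metrics_list[[1]]$k - 1L))))
  } else {
    field <- paste0(metric, switch(metric, duration = "_ms",
                                   occurrence = "_hz", coverage = "_pct"))
    t(vapply(metrics_list, function(m) m[[field]],
             numeric(metrics_list[[1]]$k)))
  }
}

transition_cell_names <- function(labels) {
  K <- length(labels)
  idx <- which(row(diag(K)) != col(diag(K)))
  paste0(labels[row(diag(K))[idx]], ">", labels[col(diag(K))[idx]])
}

mean_icc_of <- function(A, B, warn = TRUE) {
  iccs <- vapply(seq_len(ncol(A)), function(j)
    icc_a1(cbind(A[, j], B[, j])), numeric(1))
  fisher_mean(iccs, warn = warn)
}

#' Permutation test of a mean ICC
#'
#' The observed mean ICC (Fisher-z aggregated over templates, or over all
#' cross-type transition cells) is compared to a null distribution
#' obtained by shuffling the subject order of session B while session A
#' stays fixed. One-sided, add-one estimator:
#' `p = (1 + #(null >= observed)) / (1 + reps)`.
#'
#' @param pair a `paired_metrics` object (n >= 5 subjects).
#' @param metric one of `"duration"`, `"occurrence"`, `"coverage"`,
#'   `"transition"`.
#' @param reps number of shuffles (default 1000).
#' @param seed RNG seed.
#' @return List with `observed`, `p`, `reps`.
#' @export
permutation_test <- function(pair, metric = c("duration", "occurrence",
                                              "coverage", "transition"),
                             reps = 1000L, seed = NULL) {
  stopifnot(inherits(pair, "paired_metrics"))
  metric <- match.arg(metric)
  n <- length(pair$subjects)
  if (n < 5L) stop("need at least 5 subjects")
  A <- metric_matrix(pair$session_a, metric)
  B <- metric_matrix(pair$session_b, metric)
  obs <- mean_icc_of(A, B)
  if (is.na(obs)) return(list(observed = NA_real_, p = NA_real_,
                              reps = reps))
  null <- with_seed(seed, vapply(seq_len(reps), function(r)
    mean_icc_of(A, B[sample.int(n), , drop = FALSE], warn = FALSE),
    numeric(1)))
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + reps)
  list(observed = obs, p = p, reps = reps)
}

#' Full reliability report for a session pair
#'
#' Per-template ICCs for duration, occurrence and coverage; per-cell ICCs
#' for the cross-type transitions; Fisher-z mean per metric (transitions
#' pooled over all K(K-1) cells); permutation p per mean; reliability
#' category per mean.
#'
#' @param pair a `paired_metrics` object.
#' @param reps permutation repetitions (default 1000; 0 skips the test).
#' @param seed RNG seed for the permutations.
#' @return A `reliability_report`: list with `icc` (data frame: metric,
#'   cell, icc), `mean_icc`, `p_perm`, `category` (named per metric),
#'   `n_subjects`, `seed`.
#' @export
pair_reliability <- function(pair, reps = 1000L, seed = NULL) {
  stopifnot(inherits(pair, "paired_metrics"))
  metrics <- c("duration", "occurrence", "coverage", "transition")
  labels <- pair$session_a[[1]]$template_labels
  rows <- list()
  mean_icc <- p_perm <- stats::setNames(rep(NA_real_, 4), metrics)
  for (m in metrics) {
    A <- metric_matrix(pair$session_a, m)
    B <- metric_matrix(pair$session_b, m)
    cells <- if (m == "transition") transition_cell_names(labels) else labels
    iccs <- vapply(seq_len(ncol(A)), function(j)
      icc_a1(cbind(A[, j], B[, j])), numeric(1))
    rows[[m]] <- data.frame(metric = m, cell = cells, icc = iccs,
                            stringsAsFactors = FALSE)
    mean_icc[m] <- fisher_mean(iccs)
    if (reps > 0 && length(pair$subjects) >= 5L)
      p_perm[m] <- permutation_test(pair, m, reps = reps, seed = seed)$p
  }
  structure(list(icc = do.call(rbind, c(rows, make.row.names = FALSE)),
                 mean_icc = mean_icc, p_perm = p_perm,
                 category = stats::setNames(classify_icc(mean_icc), metrics),
                 n_subjects = length(pair$subjects),
                 pairing_label = pair$pairing_label, seed = seed),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %s (n = %d)\n",
              x$pairing_label, x$n_subjects))
  df <- data.frame(metric = names(x$mean_icc),
                   mean_icc = round(x$mean_icc, 3),
                   p_perm = signif(x$p_perm, 3),
                   category = x$category)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a reliability report as JSON or TSV
#'
#' @param report a `reliability_report`.
#' @param path output path; `.json` writes the full report,
#'   `.tsv` a per-cell ICC table with the means appended.
#' @return `path`, invisibly.
#' @export
write_reliability_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(pairing = report$pairing_label, n_subjects = report$n_subjects,
           icc = report$icc,
           mean_icc = as.list(report$mean_icc),
           p_perm = as.list(report$p_perm),
           category = as.list(report$category)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (ext == "tsv") {
    tab <- rbind(report$icc,
                 data.frame(metric = names(report$mean_icc), cell = "Mean",
                            icc = unname(report$mean_icc)))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else stop("unsupported report extension: ", ext)
  invisible(path)
}
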