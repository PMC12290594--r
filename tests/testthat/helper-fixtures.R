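# Shared fixture builders (all fixtures are generated in code).

# multichannel sine recording
sine_recording <- function(freq = 10, rate = 250, dur = 10, n_ch = 2,
                           amp = 1) {
  t <- (seq_len(rate * dur) - 1) / rate
  recording(matrix(rep(amp * sin(2 * pi * freq * t), n_ch), n_ch,
                   byrow = TRUE), rate = rate)
}

rand_recording <- function(n_ch = 4, rate = 250, dur = 10, sd = 1,
                           seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_ch * rate * dur, sd = sd), n_ch), rate = rate)
}

# hand-built microstate_metrics (for reliability tests without EEG)
make_metrics <- function(duration, occurrence = duration / 10,
                         coverage = duration / sum(duration) * 100,
                         transition = NULL,
                         labels = LETTERS[seq_along(duration)]) {
  k <- length(duration)
  if (is.null(transition)) {
    transition <- matrix(1 / (k - 1), k, k)
    diag(transition) <- 0
  }
  dimnames(transition) <- list(labels, labels)
  structure(list(duration_ms = stats::setNames(duration, labels),
                 occurrence_hz = stats::setNames(occurrence, labels),
                 coverage_pct = stats::setNames(coverage, labels),
                 transition = transition, k = k, template_labels = labels),
            class = "microstate_metrics")
}

# paired sessions of metric values with known true ICC (metric level):
# value = mu + subject_effect + session_noise
simulate_paired_cohort <- function(n, icc, k = 4, mu = 80, sigma = 20,
                                   seed = 1) {
  set.seed(seed)
  sb <- sqrt(icc) * sigma
  sw <- sqrt(1 - icc) * sigma
  subj <- matrix(rnorm(n * k, sd = sb), n, k)
  a <- mu + subj + matrix(rnorm(n * k, sd = sw), n, k)
  b <- mu + subj + matrix(rnorm(n * k, sd = sw), n, k)
  list(a = lapply(seq_len(n), function(i) make_metrics(a[i, ])),
       b = lapply(seq_len(n), function(i) make_metrics(b[i, ])))
}

# templates object from raw maps
as_templates <- function(maps, labels = as.character(seq_len(nrow(maps)))) {
  structure(list(maps = maps, labels = labels, k = nrow(maps)),
            class = "microstate_templates")
}

# independent ICC(A,1) oracle via stats::aov mean squares
icc_a1_oracle <- function(x) {
  n <- nrow(x)
  d <- data.frame(y = c(x[, 1], x[, 2]),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}
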