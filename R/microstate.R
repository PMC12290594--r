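# Microstate analysis: GFP-peak topographies, deterministic AAHC
# clustering (two-level), template ordering, backfitting with temporal
# smoothing, and the duration/occurrence/coverage/transition metrics.
#
# Polarity convention: microstate semantics are sign-invariant. All
# spatial correlations are taken in absolute value and cluster prototypes
# are dominant eigenvectors of map outer-product sums, so flipping the
# sign of any input map (or the whole recording) changes nothing.

avg_ref_map <- function(m) m - mean(m)

map_gfp <- function(m) {
  m <- avg_ref_map(m)
  sqrt(mean(m^2))  # population SD across channels
}

#' Global field power curve
#'
#' GFP(t) is the population standard deviation across average-referenced
#' EEG channels at each sample; its peaks index moments of high
#' topographic signal-to-noise.
#'
#' @param rec an [recording()] object with at least two EEG channels.
#' @return Numeric vector, one value per sample.
#' @export
gfp_curve <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  eeg <- eeg_channels(rec)
  if (length(eeg) < 2L) stop("need at least 2 EEG channels")
  X <- rec$data[eeg, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  sqrt(colMeans(X^2))
}

#' Extract topographies at GFP peaks
#'
#' Finds strict local maxima of the GFP curve and returns the
#' average-referenced maps at those samples.
#'
#' @param rec an [recording()] object.
#' @param min_separation_ms minimum separation between kept peaks in ms
#'   (0 = keep all); when two peaks are closer, the larger survives.
#' @param max_maps optional cap on the number of returned maps (evenly
#'   spaced subset, deterministic); `Inf` keeps all.
#' @return A `topography_set`: list with `maps` (M x C matrix of
#'   average-referenced maps), `gfp` (per-map GFP), `samples` (peak sample
#'   indices), `source`.
#' @export
gfp_peaks <- function(rec, min_separation_ms = 0, max_maps = Inf) {
  g <- gfp_curve(rec)
  n <- length(g)
  pk <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
  if (!length(pk)) stop("no peaks: GFP curve is monotone or constant")
  if (min_separation_ms > 0) {
    min_sep <- min_separation_ms / 1000 * rec$rate
    keep <- logical(length(pk))
    ord <- order(g[pk], decreasing = TRUE)   # larger peak wins
    taken <- numeric(0)
    for (i in ord) {
      if (!length(taken) || min(abs(taken - pk[i])) >= min_sep) {
        keep[i] <- TRUE
        taken <- c(taken, pk[i])
      }
    }
    pk <- pk[keep]
  }
  if (is.finite(max_maps) && length(pk) > max_maps)
    pk <- pk[unique(as.integer(round(seq(1, length(pk),
                                         length.out = max_maps))))]
  eeg <- eeg_channels(rec)
  maps <- t(rec$data[eeg, pk, drop = FALSE])
  maps <- maps - rowMeans(maps)
  structure(list(maps = maps, gfp = g[pk], samples = pk,
                 source = utils::tail(rec$log, 1)),
            class = "topography_set")
}

# columns-standardized map matrix for fast |corr| via crossprod
std_maps <- function(M) {
  M <- M - rowMeans(M)
  s <- sqrt(rowSums(M^2))
  if (any(s < 1e-300)) stop("zero-variance map")
  M / s
}

#' Spatial correlation between two maps
#'
#' Pearson correlation across channels of the average-referenced maps,
#' in absolute value when polarity is ignored (the microstate default).
#'
#' @param map1,map2 numeric vectors of equal length (one value per
#'   channel).
#' @param ignore_polarity take the absolute value (default `TRUE`).
#' @return Scalar in `[0, 1]` (or `[-1, 1]` when polarity is kept).
#' @export
spatial_corr <- function(map1, map2, ignore_polarity = TRUE) {
  if (length(map1) != length(map2)) stop("maps differ in channel count")
  m1 <- avg_ref_map(map1); m2 <- avg_ref_map(map2)
  if (sum(m1^2) < 1e-300 || sum(m2^2) < 1e-300)
    stop("zero-variance map")
  r <- sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2))
  if (ignore_polarity) abs(r) else r
}

# polarity-safe prototype: dominant eigenvector of sum of outer products
proto_of <- function(maps) {
  if (nrow(maps) == 1L) {
    p <- avg_ref_map(maps[1, ])
  } else {
    M <- maps - rowMeans(maps)
    p <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1]
    p <- avg_ref_map(p)
  }
  p / map_gfp(p)
}

#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' Deterministic, polarity-invariant clustering: starting from singleton
#' clusters, the cluster contributing least global explained variance
#' (GEV, GFP-weighted squared spatial correlation of members to their
#' prototype) is repeatedly dissolved and its members reassigned to the
#' cluster with the highest squared spatial correlation, until `k_target`
#' clusters remain. Prototypes are dominant eigenvectors of the member
#' outer-product sums, scaled to unit GFP.
#'
#' @param topos a `topography_set` from [gfp_peaks()] (or compatible list
#'   with `maps` and `gfp`).
#' @param k_target number of clusters.
#' @return A `microstate_templates`: list with `maps` (k x C unit-GFP
#'   prototypes), `labels` (provisional `"1"`..`"k"`, see
#'   [order_templates()]), `k`, `gev` (per-cluster GEV contribution),
#'   `assignment` (per input map).
#' @export
aahc <- function(topos, k_target) {
  maps <- topos$maps
  gfp <- if (!is.null(topos$gfp)) topos$gfp else rep(1, nrow(maps))
  M <- nrow(maps)
  if (M < k_target) stop("only ", M, " maps for k_target = ", k_target)
  S <- std_maps(maps)                 # standardized rows for fast corr
  denom <- sum(gfp^2)
  assign_v <- seq_len(M)
  protos <- lapply(seq_len(M), function(i) proto_of(maps[i, , drop = FALSE]))
  alive <- rep(TRUE, M)               # cluster ids are original slots
  # member |corr| to own prototype; contribution (gfp*|corr|)^2/denom
  proto_std <- function(p) { p <- p - mean(p); p / sqrt(sum(p^2)) }
  Pstd <- t(vapply(protos, proto_std, numeric(ncol(maps))))
  corr_own <- abs(rowSums(S * Pstd[assign_v, , drop = FALSE]))
  gev <- vapply(seq_len(M), function(c)
    sum((gfp[assign_v == c] * corr_own[assign_v == c])^2) / denom,
    numeric(1))
  n_alive <- M
  while (n_alive > k_target) {
    cand <- which(alive)
    victim <- cand[which.min(gev[cand])]
    freed <- which(assign_v == victim)
    alive[victim] <- FALSE
    n_alive <- n_alive - 1L
    others <- which(alive)
    cc <- abs(S[freed, , drop = FALSE] %*% t(Pstd[others, , drop = FALSE]))
    tgt <- others[max.col(cc^2, ties.method = "first")]
    assign_v[freed] <- tgt
    for (c in unique(tgt)) {
      mem <- which(assign_v == c)
      protos[[c]] <- proto_of(maps[mem, , drop = FALSE])
      Pstd[c, ] <- proto_std(protos[[c]])
      corr_own[mem] <- abs(S[mem, , drop = FALSE] %*% Pstd[c, ])
      gev[c] <- sum((gfp[mem] * corr_own[mem])^2) / denom
    }
  }
  keep <- which(alive)
  ord <- order(gev[keep], decreasing = TRUE)
  keep <- keep[ord]
  out_maps <- t(vapply(protos[keep], identity, numeric(ncol(maps))))
  structure(list(maps = out_maps,
                 labels = as.character(seq_along(keep)),
                 k = length(keep), gev = gev[keep],
                 assignment = match(assign_v, keep)),
            class = "microstate_templates")
}

#' @export
print.microstate_templates <- function(x, ...) {
  cat(sprintf("<microstate_templates> k = %d [%s], %d channels\n",
              x$k, paste(x$labels, collapse = " "), ncol(x$maps)))
  invisible(x)
}

#' Two-level microstate template extraction
#'
#' First level: AAHC per subject at each k in `k_subject_range`, giving
#' each subject's mean maps. Second level: the pooled subject maps are
#' clustered again by AAHC, once per value of `k_group_range`, giving one
#' group template set per group-level k.
#'
#' @param per_subject list of `topography_set`, one per subject (>= 2).
#' @param k_subject_range integer vector of subject-level cluster counts
#'   (default `4:6`).
#' @param k_group_range integer vector of group-level cluster counts
#'   (default `4:6`).
#' @return Named list (`"k=4"`, ...) of `microstate_templates`.
#' @export
two_level_templates <- function(per_subject, k_subject_range = 4:6,
                                k_group_range = 4:6) {
  if (length(per_subject) < 2L) stop("need at least 2 subjects")
  pooled <- do.call(rbind, lapply(per_subject, function(ts) {
    do.call(rbind, lapply(k_subject_range, function(k) aahc(ts, k)$maps))
  }))
  out <- lapply(k_group_range, function(kg)
    aahc(list(maps = pooled, gfp = rep(1, nrow(pooled))), kg))
  names(out) <- paste0("k=", k_group_range)
  out
}

#' Canonical reference maps for template ordering
#'
#' Four analytic dipolar maps built from sensor positions, used only as a
#' stable reference for automated label assignment: A (left-posterior to
#' right-anterior gradient), B (its mirror), C (occipital-frontal), D
#' (fronto-central radial).
#'
#' @param positions channels x 3 matrix of sensor positions (unit sphere,
#'   x right, y anterior, z superior).
#' @return A `microstate_templates` with labels A-D.
#' @export
canonical_templates <- function(positions) {
  positions <- as.matrix(positions)
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  raw <- rbind(A = -x + y, B = x + y, C = -y + 0.3 * z,
               D = z - 0.5 * y^2)
  maps <- t(apply(raw, 1, function(m) {
    m <- avg_ref_map(m); m / map_gfp(m)
  }))
  structure(list(maps = maps, labels = c("A", "B", "C", "D"), k = 4L),
            class = "microstate_templates")
}

#' Order templates against a canonical set
#'
#' Finds the one-to-one assignment of templates to canonical maps that
#' maximizes the total absolute spatial correlation (exhaustive search
#' over assignments; k is small by construction) and relabels the
#' templates with the canonical labels. Surplus templates keep fresh
#' labels (continuing the alphabet) in their original (GEV) order.
#'
#' @param tmpl a `microstate_templates`.
#' @param canonical reference `microstate_templates` (e.g.
#'   [canonical_templates()]).
#' @return `tmpl` with rows reordered by assigned label and `labels` set.
#' @export
order_templates <- function(tmpl, canonical) {
  k <- tmpl$k; ck <- canonical$k
  cc <- abs(std_maps(tmpl$maps) %*% t(std_maps(canonical$maps)))
  n_assign <- min(k, ck)
  # enumerate injective assignments of templates to canonical slots
  best <- NULL; best_val <- -Inf
  rows <- utils::combn(k, n_assign, simplify = FALSE)
  for (r in rows) {
    for (p in perms(n_assign)) {
      cols <- utils::combn(ck, n_assign, simplify = FALSE)
      for (cl in cols) {
        val <- sum(cc[cbind(r, cl[p])])
        if (val > best_val) { best_val <- val; best <- cbind(r, cl[p]) }
      }
    }
  }
  labels <- rep(NA_character_, k)
  labels[best[, 1]] <- canonical$labels[best[, 2]]
  extra <- which(is.na(labels))
  if (length(extra)) {
    pool <- setdiff(LETTERS, canonical$labels)
    labels[extra] <- pool[seq_along(extra)]
  }
  ord <- order(match(labels, c(canonical$labels,
                               setdiff(LETTERS, canonical$labels))))
  tmpl$maps <- tmpl$maps[ord, , drop = FALSE]
  tmpl$labels <- labels[ord]
  if (!is.null(tmpl$gev)) tmpl$gev <- tmpl$gev[ord]
  tmpl
}

perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Backfit microstate templates to a recording
#'
#' Assigns each GFP-peak map to the template with the highest absolute
#' spatial correlation; non-peak samples inherit the label of the nearest
#' peak (ties to the earlier peak). Temporal smoothing then iteratively
#' absorbs segments shorter than `smooth_window_ms` into the neighboring
#' label with the higher mean absolute correlation over the segment, until
#' stable. With the default non-smoothness penalty of 1 this is plain
#' best-neighbor absorption; larger penalties make short segments easier
#' to absorb (a segment survives only if its own mean correlation exceeds
#' the best neighbor's scaled by the penalty).
#'
#' @param rec an average-referenced [recording()] object.
#' @param tmpl ordered `microstate_templates`.
#' @param smooth_window_ms smoothing window in ms (default 20).
#' @param penalty non-smoothness penalty (default 1).
#' @return A `microstate_sequence`: list with `labels` (per-sample integer
#'   template index), `template_labels`, `rate`, `gfp`, `fit` (per-sample
#'   absolute correlation to the assigned template).
#' @export
backfit <- function(rec, tmpl, smooth_window_ms = 20, penalty = 1) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(tmpl, "microstate_templates"))
  g <- gfp_curve(rec)
  eeg <- eeg_channels(rec)
  X <- rec$data[eeg, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  Tstd <- std_maps(tmpl$maps)
  nrm <- sqrt(colSums(X^2))
  nrm[nrm < 1e-300] <- 1
  corr <- abs(Tstd %*% sweep(X, 2, nrm, "/"))    # k x samples
  n <- ncol(X)
  pk <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
  if (!length(pk)) pk <- which.max(g)
  lab_pk <- max.col(t(corr[, pk, drop = FALSE]), ties.method = "first")
  # nearest-peak interpolation, ties to the earlier peak
  idx <- seq_len(n)
  j <- findInterval(idx, pk)
  jl <- pmax(j, 1L)
  jr <- pmin(j + 1L, length(pk))
  use_left <- j >= 1L & (j == length(pk) | (idx - pk[jl]) <= (pk[jr] - idx))
  lab <- ifelse(j == 0L, lab_pk[1L],
                ifelse(use_left, lab_pk[jl], lab_pk[jr]))
  min_len <- max(1L, as.integer(round(smooth_window_ms / 1000 * rec$rate)))
  lab <- smooth_labels(lab, corr, min_len, penalty)
  structure(list(labels = lab, template_labels = tmpl$labels,
                 rate = rec$rate, gfp = g,
                 fit = corr[cbind(lab, seq_len(n))]),
            class = "microstate_sequence")
}

smooth_labels <- function(lab, corr, min_len, penalty) {
  for (iter in seq_len(100L)) {
    r <- rle(lab)
    short <- which(r$lengths < min_len)
    if (!length(short)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (s in short) {
      idx <- starts[s]:ends[s]
      own <- mean(corr[cbind(rep(r$values[s], length(idx)), idx)])
      cand <- integer(0)
      if (s > 1L) cand <- c(cand, r$values[s - 1L])
      if (s < length(r$values)) cand <- c(cand, r$values[s + 1L])
      cand <- setdiff(unique(cand), r$values[s])
      if (!length(cand)) next
      sc <- vapply(cand, function(cl)
        mean(corr[cbind(rep(cl, length(idx)), idx)]), numeric(1))
      if (own < max(sc) * penalty) {
        lab[idx] <- cand[which.max(sc)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Microstate metrics of a label sequence
#'
#' Segments are maximal runs of one template label. Per template:
#' *duration* is the mean segment length in ms; *occurrence* the number
#' of segments per second of assigned time; *coverage* the percentage of
#' assigned time spent in the template; *transition* the K x K matrix of
#' probabilities of moving to each other template given a segment of the
#' type ends (diagonal fixed at 0). Unassigned (`NA`) samples are excluded
#' from all denominators and break transition adjacency.
#'
#' @param seq a `microstate_sequence` from [backfit()].
#' @return A `microstate_metrics`: list with named vectors `duration_ms`,
#'   `occurrence_hz`, `coverage_pct`, matrix `transition`, and `k`,
#'   `template_labels`.
#' @export
ms_metrics <- function(seq) {
  stopifnot(inherits(seq, "microstate_sequence"))
  lab <- seq$labels
  if (!length(lab)) stop("empty sequence")
  K <- length(seq$template_labels)
  r <- rle(lab)
  ok <- !is.na(r$values)
  runs_v <- r$values[ok]; runs_l <- r$lengths[ok]
  tot_s <- sum(runs_l) / seq$rate
  duration <- occurrence <- coverage <- stats::setNames(numeric(K),
                                                        seq$template_labels)
  for (k in seq_len(K)) {
    sel <- runs_v == k
    if (any(sel)) {
      duration[k] <- mean(runs_l[sel]) / seq$rate * 1000
      occurrence[k] <- sum(sel) / tot_s
      coverage[k] <- sum(runs_l[sel]) / sum(runs_l) * 100
    }
  }
  trans <- matrix(0, K, K, dimnames = list(seq$template_labels,
                                           seq$template_labels))
  keep_adj <- ok[-length(ok)] & ok[-1]   # both runs assigned
  from <- r$values[-length(r$values)][keep_adj]
  to <- r$values[-1][keep_adj]
  for (k in seq_len(K)) {
    n_out <- sum(from == k)
    if (n_out > 0)
      for (j in setdiff(seq_len(K), k))
        trans[k, j] <- sum(from == k & to == j) / n_out
  }
  structure(list(duration_ms = duration, occurrence_hz = occurrence,
                 coverage_pct = coverage, transition = trans, k = K,
                 template_labels = seq$template_labels),
            class = "microstate_metrics")
}

#' @export
print.microstate_metrics <- function(x, ...) {
  df <- data.frame(template = x$template_labels,
                   duration_ms = round(x$duration_ms, 1),
                   occurrence_hz = round(x$occurrence_hz, 2),
                   coverage_pct = round(x$coverage_pct, 1))
  print(df, row.names = FALSE)
  invisible(x)
}
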