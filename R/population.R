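#' Percentile thresholds of the pooled control population
#'
#' 10th and 90th percentiles of MCI and volume over all control
#' mitochondria pooled together, computed by linear interpolation between
#' order statistics (the classic "type 7" rule: quantile at
#' `(n - 1) p + 1` with linear interpolation). These thresholds define the
#' simple/complex (MCI) and small/large (volume) classes.
#'
#' @param control_metrics data.frame of control organelles with `mci` and
#'   a volume column (`volume_um3` or `volume`).
#' @param min_n minimum pooled control size (default 10).
#' @return list of class `population_thresholds`: `q10_mci`, `q90_mci`,
#'   `q10_vol`, `q90_vol`.
#' @export
percentile_thresholds <- function(control_metrics, min_n = 10) {
  vol <- control_metrics$volume_um3 %||% control_metrics$volume
  m <- control_metrics$mci
  keep <- is.finite(m) & is.finite(vol)
  m <- m[keep]; vol <- vol[keep]
  if (length(m) < min_n)
    stop("need at least ", min_n, " pooled control mitochondria",
         call. = FALSE)
  th <- list(
    q10_mci = unname(quantile(m, 0.10, type = 7)),
    q90_mci = unname(quantile(m, 0.90, type = 7)),
    q10_vol = unname(quantile(vol, 0.10, type = 7)),
    q90_vol = unname(quantile(vol, 0.90, type = 7)))
  if (th$q10_mci >= th$q90_mci || th$q10_vol >= th$q90_vol)
    stop("degenerate control population: q10 >= q90", call. = FALSE)
  structure(th, class = "population_thresholds")
}

#' Classify mitochondria against control percentiles
#'
#' Simple: MCI strictly below the control 10th percentile. Complex: MCI
#' strictly above the control 90th. Small/large: the same on volume.
#' Strict inequalities keep values tied with a threshold in the middle
#' class, so the control pool itself classifies at most 10% simple.
#'
#' @param metrics data.frame with `mci`, a volume column, and optionally
#'   `subject_id` and `group`.
#' @param thresholds a [percentile_thresholds()].
#' @return `metrics` with added logical columns `simple`, `complex`,
#'   `small`, `large`, plus attributes `by_subject` and `by_group`
#'   (percentage of each class per individual / per group, with the
#'   fold-elevation of simple mitochondria over the 10% control
#'   baseline).
#' @export
classify_population <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "population_thresholds"))
  vol <- metrics$volume_um3 %||% metrics$volume
  metrics$simple <- metrics$mci < thresholds$q10_mci
  metrics$complex <- metrics$mci > thresholds$q90_mci
  metrics$small <- vol < thresholds$q10_vol
  metrics$large <- vol > thresholds$q90_vol
  pct <- function(df) data.frame(
    n = nrow(df),
    pct_simple = 100 * mean(df$simple, na.rm = TRUE),
    pct_complex = 100 * mean(df$complex, na.rm = TRUE),
    pct_small = 100 * mean(df$small, na.rm = TRUE),
    pct_large = 100 * mean(df$large, na.rm = TRUE))
  if (!is.null(metrics$subject_id)) {
    sp <- split(metrics, metrics$subject_id)
    bs <- cbind(subject_id = names(sp),
                do.call(rbind, lapply(sp, pct)))
    rownames(bs) <- NULL
    attr(metrics, "by_subject") <- bs
  }
  if (!is.null(metrics$group)) {
    sp <- split(metrics, metrics$group)
    bg <- cbind(group = names(sp), do.call(rbind, lapply(sp, pct)))
    bg$simple_fold_vs_control <- bg$pct_simple / 10
    rownames(bg) <- NULL
    attr(metrics, "by_group") <- bg
  }
  metrics
}

#' Coefficients of variation at three nested levels
#'
#' Mitochondrial morphology varies between mitochondria of one cell,
#' between cells of one person, and between persons. All CVs are SD/mean
#' on the natural scale:
#' * within-cell: CV across mitochondria of each cell (reported per cell,
#'   with the range);
#' * between-cell: CV of cell means within each person;
#' * between-person: CV of person means.
#'
#' @param values numeric metric per mitochondrion (e.g. volume or MCI).
#' @param subject,cell grouping vectors aligned with `values`.
#' @return list with `within_cell` (per-cell data.frame and `range`),
#'   `between_cell` (per-person data.frame), `between_person` (scalar).
#'   Cells with fewer than 2 mitochondria are excluded with a warning.
#' @export
cv_levels <- function(values, subject, cell) {
  stopifnot(length(values) == length(subject),
            length(values) == length(cell))
  cv <- function(x) sd(x) / mean(x)
  key <- interaction(subject, cell, drop = TRUE)
  sizes <- tapply(values, key, length)
  if (any(sizes < 2)) {
    warning(sum(sizes < 2),
            " single-mitochondrion cell(s) excluded from within-cell CV",
            call. = FALSE)
  }
  keep <- key %in% names(sizes)[sizes >= 2]
  wc <- data.frame(
    subject = tapply(as.character(subject[keep]), key[keep, drop = TRUE],
                     `[`, 1),
    cell = tapply(as.character(cell[keep]), key[keep, drop = TRUE],
                  `[`, 1),
    cv = as.vector(tapply(values[keep], key[keep, drop = TRUE], cv)))
  rownames(wc) <- NULL
  cell_means <- tapply(values, key, mean)
  cell_subj <- tapply(as.character(subject), key, `[`, 1)
  bc <- data.frame(
    subject = unique(cell_subj),
    cv = vapply(unique(cell_subj), function(s) {
      mm <- cell_means[cell_subj == s]
      if (length(mm) < 2) NA_real_ else cv(mm)
    }, numeric(1)))
  rownames(bc) <- NULL
  person_means <- tapply(values, subject, mean)
  bp <- if (length(person_means) < 2) NA_real_ else cv(person_means)
  list(within_cell = wc, within_cell_range = range(wc$cv),
       between_cell = bc, between_person = bp)
}

#' Mitochondrial volume density
#'
#' Percentage of muscle fiber volume occupied by mitochondria, measured
#' over a reference fiber block (conventionally two full sarcomeres).
#'
#' @param mito_volumes per-organelle volumes (any unit).
#' @param fiber_volume fiber reference volume (same unit), > 0.
#' @return percentage.
#' @export
volume_density <- function(mito_volumes, fiber_volume) {
  if (fiber_volume <= 0) stop("fiber volume must be positive",
                              call. = FALSE)
  total <- sum(mito_volumes)
  if (total > fiber_volume)
    stop("mitochondrial volume exceeds fiber volume: inconsistent ",
         "segmentation", call. = FALSE)
  100 * total / fiber_volume
}

#' Distribution shape: skewness and kurtosis
#'
#' Moment-based skewness `g1 = m3 / m2^(3/2)` and Pearson kurtosis
#' `m4 / m2^2` (raw, i.e. non-excess: Gaussian = 3) by default; set
#' `kurtosis = "excess"` to subtract 3.
#'
#' @param values numeric, n >= 4.
#' @param kurtosis `"raw"` or `"excess"`.
#' @return list with `skewness` and `kurtosis`.
#' @export
distribution_moments <- function(values, kurtosis = c("raw", "excess")) {
  kurtosis <- match.arg(kurtosis)
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  k <- m4 / m2^2
  list(skewness = m3 / m2^1.5,
       kurtosis = if (kurtosis == "excess") k - 3 else k)
}

#' Empirical cumulative distribution table
#'
#' @param values numeric.
#' @return data.frame of sorted unique `(value, fraction <= value)` pairs.
#' @export
cumulative_distribution <- function(values) {
  values <- sort(values[is.finite(values)])
  if (length(values) == 0) stop("no finite values", call. = FALSE)
  frac <- seq_along(values) / length(values)
  keep <- !duplicated(values, fromLast = TRUE)
  data.frame(value = values[keep], fraction = frac[keep])
}

#' Per-individual cohort summary features
#'
#' Assembles, for each subject, the morphological feature vector used by
#' the multivariate signature: percentage of simple / complex / small /
#' large mitochondria (vs control percentiles), median MCI, median
#' volume, volume density and nanotunnels per 100 mitochondria.
#'
#' @param metrics per-organelle data.frame with `subject_id`, `group`,
#'   `mci` and a volume column.
#' @param thresholds a [percentile_thresholds()] from the control pool.
#' @param density optional data.frame `subject_id`, `volume_density_pct`.
#' @param nanotunnel_counts optional data.frame `subject_id`,
#'   `n_nanotunnels` (per-100 rates are computed against each subject's
#'   mitochondrion count in `metrics`).
#' @return data.frame, one row per subject, columns `subject_id`,
#'   `group`, the eight features.
#' @export
cohort_summaries <- function(metrics, thresholds, density = NULL,
                             nanotunnel_counts = NULL) {
  cl <- classify_population(metrics, thresholds)
  vol <- cl$volume_um3 %||% cl$volume
  sp <- split(seq_len(nrow(cl)), cl$subject_id)
  out <- do.call(rbind, lapply(names(sp), function(s) {
    i <- sp[[s]]
    data.frame(
      subject_id = s, group = cl$group[i][1],
      pct_simple = 100 * mean(cl$simple[i]),
      pct_complex = 100 * mean(cl$complex[i]),
      pct_small = 100 * mean(cl$small[i]),
      pct_large = 100 * mean(cl$large[i]),
      median_mci = median(cl$mci[i]),
      median_volume = median(vol[i]),
      n_mitochondria = length(i))
  }))
  out$volume_density_pct <- if (!is.null(density))
    density$volume_density_pct[match(out$subject_id,
                                     density$subject_id)] else NA_real_
  out$nanotunnels_per_100 <- if (!is.null(nanotunnel_counts)) {
    n_nt <- nanotunnel_counts$n_nanotunnels[
      match(out$subject_id, nanotunnel_counts$subject_id)]
    nanotunnel_frequency(ifelse(is.na(n_nt), 0, n_nt),
                         out$n_mitochondria)
  } else NA_real_
  rownames(out) <- NULL
  out
}
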