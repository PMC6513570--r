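#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined samples up to `exact_max`
#' observations the null distribution of U is obtained by exact
#' enumeration of all group assignments (valid under ties); above that, a
#' normal approximation with the usual tie correction is used.
#'
#' @param x,y numeric samples, non-empty.
#' @param exact_max largest combined n for exact enumeration (default 20).
#' @return list with `U` (statistic for `x`), `p` (two-sided), `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y, exact_max = 20) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty",
                               call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    # enumerate every way to assign n1 of the pooled ranks to x
    idx <- combn(n1 + n2, n1)
    r1 <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(r[idx], nrow = n1)) - r1
    dev <- abs(Us - n1 * n2 / 2)
    p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Pearson chi-square test on class proportions
#'
#' Contingency test for, e.g., MBI class counts across cohorts.
#'
#' @param counts k x m matrix (or table) of counts.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0))
    stop("zero expected count; pool sparse classes before testing",
         call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected = expected)
}

#' Nested random-intercept variance components
#'
#' Decomposes a per-mitochondrion metric into between-person,
#' between-cell-within-person and residual (within-cell) variance via a
#' linear mixed model with person and cell-nested-in-person random
#' intercepts, fit by REML (lme4). Morphological metrics are strongly
#' right-skewed, so values are log-transformed (natural log) by default
#' and the returned SDs are on the log scale. An optional group label
#' enters as a fixed effect.
#'
#' @param values positive numeric metric per mitochondrion.
#' @param subject,cell grouping vectors.
#' @param group optional fixed-effect labels (2+ levels).
#' @param log_transform log the values first (default TRUE).
#' @return list of class `nested_variance_fit`: `sd_person`, `sd_cell`,
#'   `sd_within`, and when `group` is given `fixed_effect` (named
#'   difference estimates) and `fixed_se`; `method` records the fit.
#' @export
nested_variance_components <- function(values, subject, cell,
                                       group = NULL,
                                       log_transform = TRUE) {
  stopifnot(length(values) == length(subject),
            length(values) == length(cell))
  if (log_transform) {
    if (any(values <= 0))
      stop("values must be positive for log transform", call. = FALSE)
    values <- log(values)
  }
  df <- data.frame(y = values, subject = factor(subject),
                   cell = factor(paste(subject, cell, sep = ":")))
  cells_per_subject <- tapply(as.character(df$cell), df$subject,
                              function(z) length(unique(z)))
  cell_estimable <- any(cells_per_subject > 1)
  form <- if (cell_estimable)
    y ~ (1 | subject) + (1 | cell) else y ~ (1 | subject)
  if (!is.null(group)) {
    df$group <- factor(group)
    form <- update(form, . ~ . + group)
  }
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_sd <- function(g) {
    s <- vc$sdcor[vc$grp == g]
    if (length(s)) s else NA_real_
  }
  out <- list(sd_person = get_sd("subject"),
              sd_cell = if (cell_estimable) get_sd("cell") else
                NA_real_,
              sd_within = get_sd("Residual"),
              method = if (cell_estimable) "REML two-level nested"
              else "REML person-only (single cell per subject)")
  if (!cell_estimable)
    out$note <- "cell-within-person component inestimable"
  if (!is.null(group)) {
    cf <- summary(fit)$coefficients
    rows <- grep("^group", rownames(cf))
    out$fixed_effect <- setNames(cf[rows, "Estimate"],
                                 rownames(cf)[rows])
    out$fixed_se <- setNames(cf[rows, "Std. Error"], rownames(cf)[rows])
  }
  class(out) <- "nested_variance_fit"
  out
}

#' @export
print.nested_variance_fit <- function(x, ...) {
  cat(sprintf(
    "<nested_variance_fit> sd_person = %.3f, sd_cell = %s, sd_within = %.3f (%s)\n",
    x$sd_person,
    if (is.na(x$sd_cell)) "inestimable" else sprintf("%.3f", x$sd_cell),
    x$sd_within, x$method))
  invisible(x)
}
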