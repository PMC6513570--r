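#' Analytic shape specification
#'
#' Implicit solids used to build voxel phantoms with known ground truth:
#' * `sphere`: radius `r` (nm); analytic SA and V.
#' * `capsule`: radius `r`, cylindrical segment length `length` along
#'   `axis`; analytic SA and V.
#' * `nanotunnel_dumbbell`: two spheres of radius `r_body` joined (or,
#'   when `free_ended`, one sphere with a blind protrusion) by a tube of
#'   `tube_diameter` and `tube_length` along `axis`; truth carries the
#'   tube geometry.
#' * `tube_network`: arbitrary union of capsules around the rows of
#'   `segments` (`x1,y1,z1,x2,y2,z2,r`).
#'
#' @param kind shape kind.
#' @param ... geometric parameters (see above), all in nm.
#' @return object of class `shape_spec` with a `truth` list (analytic
#'   surface area / volume where defined).
#' @export
shape_spec <- function(kind = c("sphere", "capsule",
                                "nanotunnel_dumbbell", "tube_network"),
                       ...) {
  kind <- match.arg(kind)
  p <- list(...)
  ax_dir <- function(axis) switch(axis, x = c(1, 0, 0), y = c(0, 1, 0),
                                  z = c(0, 0, 1))
  spec <- switch(kind,
    sphere = {
      r <- p$r
      stopifnot(r > 0)
      list(segments = matrix(c(0, 0, 0, 0, 0, 0, r), 1),
           truth = list(sa = 4 * pi * r^2, v = 4 / 3 * pi * r^3))
    },
    capsule = {
      r <- p$r; L <- p$length; axis <- p$axis %||% "z"
      stopifnot(r > 0, L > 0)
      d <- ax_dir(axis) * L / 2
      list(segments = matrix(c(-d, d, r), 1),
           truth = list(sa = 2 * pi * r * L + 4 * pi * r^2,
                        v = pi * r^2 * L + 4 / 3 * pi * r^3))
    },
    nanotunnel_dumbbell = {
      rb <- p$r_body; Lt <- p$tube_length; dt <- p$tube_diameter
      free <- isTRUE(p$free_ended)
      axis <- p$axis %||% "x"
      stopifnot(rb > 0, Lt > 0, dt > 0, dt / 2 < rb)
      u <- ax_dir(axis)
      # tube runs between the two body surfaces
      c1 <- -u * (rb + Lt / 2)
      c2 <- u * (rb + Lt / 2)
      segs <- rbind(
        c(c1, c1, rb),
        c(-u * Lt / 2, u * Lt / 2, dt / 2))
      if (!free) segs <- rbind(segs, c(c2, c2, rb))
      list(segments = segs,
           truth = list(tube_length = Lt, tube_diameter = dt,
                        r_body = rb,
                        end_status = if (free) "free_ended" else
                          "connecting"))
    },
    tube_network = {
      segs <- as.matrix(p$segments)
      stopifnot(ncol(segs) == 7, all(segs[, 7] > 0))
      list(segments = segs, truth = list())
    })
  structure(list(kind = kind, segments = spec$segments,
                 truth = spec$truth), class = "shape_spec")
}

# distance-to-segment implicit function evaluated on the voxel lattice
segment_mask <- function(seg, xs, ys, zs) {
  A <- seg[1:3]; B <- seg[4:6]; r <- seg[7]
  d <- B - A
  L2 <- sum(d^2)
  px <- xs - A[1]; py <- ys - A[2]; pz <- zs - A[3]
  n <- c(length(xs), length(ys), length(zs))
  sep <- function(a1, a2, a3)
    outer(outer(a1, a2, "+"), a3, "+")
  if (L2 == 0) {
    d2 <- sep(px^2, py^2, pz^2)
  } else {
    proj <- sep(px * d[1], py * d[2], pz * d[3])
    t <- pmin(pmax(proj / L2, 0), 1)
    d2 <- sep(px^2, py^2, pz^2) - 2 * t * proj + t^2 * L2
  }
  array(d2 <= r^2, n)
}

#' Voxelize an analytic shape
#'
#' Renders a [shape_spec()] as a [labeled_volume()] (label 1) on an
#' anisotropic grid sized to the shape plus a background margin, with the
#' analytic ground truth attached.
#'
#' @param spec a [shape_spec()].
#' @param voxel_size `(dx, dy, dz)` nm.
#' @param margin background margin in voxels on every side (default 3).
#' @return A [labeled_volume()] with attribute `truth`.
#' @export
voxelize <- function(spec, voxel_size = c(10, 10, 30), margin = 3) {
  stopifnot(inherits(spec, "shape_spec"))
  voxel_size <- as.numeric(voxel_size)
  segs <- spec$segments
  lo <- apply(rbind(segs[, 1:3, drop = FALSE] - segs[, 7],
                    segs[, 4:6, drop = FALSE] - segs[, 7]), 2, min)
  hi <- apply(rbind(segs[, 1:3, drop = FALSE] + segs[, 7],
                    segs[, 4:6, drop = FALSE] + segs[, 7]), 2, max)
  n <- ceiling((hi - lo) / voxel_size) + 2 * margin
  orig <- lo - margin * voxel_size
  xs <- orig[1] + (seq_len(n[1]) - 0.5) * voxel_size[1]
  ys <- orig[2] + (seq_len(n[2]) - 0.5) * voxel_size[2]
  zs <- orig[3] + (seq_len(n[3]) - 0.5) * voxel_size[3]
  m <- array(FALSE, n)
  for (s in seq_len(nrow(segs)))
    m <- m | segment_mask(segs[s, ], xs, ys, zs)
  vol <- labeled_volume(array(as.integer(m), n), voxel_size)
  attr(vol, "truth") <- c(spec$truth, list(origin = orig))
  vol
}

#' Synthetic muscle-fiber volume with sarcomere-registered mitochondria
#'
#' Places non-touching labeled mitochondria at z-band planes of a
#' simulated fiber (longitudinal axis = z): per the target mix, each is
#' transversely branched (a capsule across the fiber bridging 1-3
#' myofibrils), equally branched (a globular sphere), or longitudinally
#' branched (a capsule along the fiber crossing sarcomeric features).
#' A chosen fraction of organelles carries a nanotunnel (dumbbell or
#' free-ended protrusion). Every organelle keeps at least one background
#' voxel of separation so connected-component extraction is unambiguous
#' (each has its own continuous outer membrane); an overfull layout is an
#' error.
#'
#' @param n_mitochondria total count.
#' @param mix length-3 proportions (transverse, equal, longitudinal).
#' @param nanotunnel_rate nanotunnels per 100 mitochondria (default 2.1,
#'   the healthy-control rate).
#' @param sarcomere_length nm (default 2000).
#' @param myofibril_width nm (default 1000).
#' @param n_sarcomeres z-band planes span this many sarcomeres.
#' @param fiber_width transverse extent of the simulated block (nm,
#'   default 15000); more organelles than fit its z-band planes without
#'   contact is an error.
#' @param voxel_size `(dx, dy, dz)` nm.
#' @param seed mandatory RNG seed.
#' @return A [labeled_volume()] with attribute `truth`: per-organelle
#'   data.frame (label, class, branch counts, analytic volume/SA where
#'   defined, nanotunnel geometry) and `zband_positions`.
#' @export
generate_fiber_volume <- function(n_mitochondria = 24,
                                  mix = c(0.404, 0.506, 0.091),
                                  nanotunnel_rate = 2.1,
                                  sarcomere_length = 2000,
                                  myofibril_width = 1000,
                                  n_sarcomeres = 2,
                                  fiber_width = 15000,
                                  voxel_size = c(20, 20, 40),
                                  seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  mix <- mix / sum(mix)
  s <- sarcomere_length; w <- myofibril_width
  classes <- sample(c("transverse", "equal", "longitudinal"),
                    n_mitochondria, replace = TRUE, prob = mix)
  n_nt <- round(nanotunnel_rate * n_mitochondria / 100)
  nt_idx <- if (n_nt > 0) sample(n_mitochondria, n_nt) else integer()
  # lattice: one organelle per cell; cells sized for the largest shape
  cell_xy <- 3.6 * w
  cell_z <- 1.4 * s
  planes <- seq_len(n_sarcomeres + 1) - 1
  n_cols <- ceiling(sqrt(n_mitochondria / length(planes)))
  if (n_cols * cell_xy > fiber_width)
    stop("density too high: cannot place ", n_mitochondria,
         " organelles without contact in a ", fiber_width,
         " nm fiber", call. = FALSE)
  slots <- expand.grid(ix = seq_len(n_cols), iy = seq_len(n_cols),
                       iz = seq_along(planes))
  slots <- slots[seq_len(n_mitochondria), ]
  shapes <- vector("list", n_mitochondria)
  truth <- vector("list", n_mitochondria)
  for (q in seq_len(n_mitochondria)) {
    cls <- classes[q]
    center <- c((slots$ix[q] - 0.5) * cell_xy,
                (slots$iy[q] - 0.5) * cell_xy,
                planes[slots$iz[q]] * s +
                  (slots$ix[q] %% 2) * 0)  # organelles sit at z-bands
    nt_here <- q %in% nt_idx
    if (nt_here) {
      free <- runif(1) < 0.19   # observed free-ended fraction
      sp <- shape_spec("nanotunnel_dumbbell", r_body = 350,
                       tube_length = 800, tube_diameter = 100,
                       free_ended = free, axis = "x")
      counts <- branch_counts(0, 0, 0, 0)
      tr <- data.frame(class = "equal", myofibrils_bridged = 0,
                       sarcomeres = 0, half_sarcomeres = 0, z_bands = 0,
                       sa_true = NA_real_, v_true = NA_real_,
                       has_nanotunnel = TRUE,
                       nt_length = 800, nt_diameter = 100,
                       nt_status = if (free) "free_ended" else
                         "connecting")
    } else if (cls == "equal") {
      r <- runif(1, 180, 300)
      sp <- shape_spec("sphere", r = r)
      tr <- data.frame(class = cls, myofibrils_bridged = 0,
                       sarcomeres = 0, half_sarcomeres = 0, z_bands = 0,
                       sa_true = 4 * pi * r^2, v_true = 4 / 3 * pi * r^3,
                       has_nanotunnel = FALSE, nt_length = NA_real_,
                       nt_diameter = NA_real_, nt_status = NA_character_)
    } else if (cls == "transverse") {
      m_br <- sample(1:3, 1)
      extent <- (m_br + 0.3) * w
      r <- runif(1, 120, 200)
      sp <- shape_spec("capsule", r = r, length = extent - 2 * r,
                       axis = sample(c("x", "y"), 1))
      tr <- data.frame(class = cls, myofibrils_bridged = m_br,
                       sarcomeres = 0, half_sarcomeres = 0, z_bands = 0,
                       sa_true = 2 * pi * r * (extent - 2 * r) +
                         4 * pi * r^2,
                       v_true = pi * r^2 * (extent - 2 * r) +
                         4 / 3 * pi * r^3,
                       has_nanotunnel = FALSE, nt_length = NA_real_,
                       nt_diameter = NA_real_, nt_status = NA_character_)
    } else {
      feat <- sample(c("zband", "half", "sarc"), 1,
                     prob = c(0.5, 0.3, 0.2))
      extent <- switch(feat, zband = 0.35 * s, half = 0.6 * s,
                       sarc = 1.1 * s)
      r <- runif(1, 120, 200)
      sp <- shape_spec("capsule", r = r, length = extent - 2 * r,
                       axis = "z")
      tr <- data.frame(class = cls, myofibrils_bridged = 0,
                       sarcomeres = as.integer(feat == "sarc"),
                       half_sarcomeres = as.integer(feat == "half"),
                       z_bands = as.integer(feat == "zband"),
                       sa_true = 2 * pi * r * (extent - 2 * r) +
                         4 * pi * r^2,
                       v_true = pi * r^2 * (extent - 2 * r) +
                         4 / 3 * pi * r^3,
                       has_nanotunnel = FALSE, nt_length = NA_real_,
                       nt_diameter = NA_real_, nt_status = NA_character_)
    }
    shapes[[q]] <- list(spec = sp, center = center)
    tr$label <- q
    truth[[q]] <- tr
  }
  # bounds and grid
  ext <- c(n_cols * cell_xy, n_cols * cell_xy,
           n_sarcomeres * s + cell_z)
  orig <- c(0, 0, -cell_z / 2)
  n <- ceiling(ext / voxel_size)
  xs <- orig[1] + (seq_len(n[1]) - 0.5) * voxel_size[1]
  ys <- orig[2] + (seq_len(n[2]) - 0.5) * voxel_size[2]
  zs <- orig[3] + (seq_len(n[3]) - 0.5) * voxel_size[3]
  labels <- array(0L, n)
  for (q in seq_len(n_mitochondria)) {
    segs <- shapes[[q]]$spec$segments
    segs[, 1:3] <- sweep(segs[, 1:3, drop = FALSE], 2,
                         -shapes[[q]]$center)
    segs[, 4:6] <- sweep(segs[, 4:6, drop = FALSE], 2,
                         -shapes[[q]]$center)
    # rasterize only within the shape's bounding box
    blo <- apply(rbind(segs[, 1:3, drop = FALSE] - segs[, 7],
                       segs[, 4:6, drop = FALSE] - segs[, 7]), 2, min)
    bhi <- apply(rbind(segs[, 1:3, drop = FALSE] + segs[, 7],
                       segs[, 4:6, drop = FALSE] + segs[, 7]), 2, max)
    ri <- range(which(xs >= blo[1] & xs <= bhi[1]))
    rj <- range(which(ys >= blo[2] & ys <= bhi[2]))
    rk <- range(which(zs >= blo[3] & zs <= bhi[3]))
    ri <- seq(ri[1], ri[2]); rj <- seq(rj[1], rj[2])
    rk <- seq(rk[1], rk[2])
    m <- array(FALSE, c(length(ri), length(rj), length(rk)))
    for (sgi in seq_len(nrow(segs)))
      m <- m | segment_mask(segs[sgi, ], xs[ri], ys[rj], zs[rk])
    sub <- labels[ri, rj, rk]
    if (any(sub[m] != 0L))
      stop("density too high: organelles touch", call. = FALSE)
    sub[m] <- q
    labels[ri, rj, rk] <- sub
  }
  vol <- labeled_volume(labels, voxel_size)
  truth_df <- do.call(rbind, truth)
  attr(vol, "truth") <- list(
    organelles = truth_df,
    zband_positions = planes * s - orig[3],
    origin = orig)
  vol
}

#' Cohort specification for the hierarchical metric generator
#'
#' Defaults emulate the study conditions: 8 healthy controls and 6
#' patients, 3 muscle fibers (cells) per subject, ~50 traced mitochondria
#' per fiber; lognormal per-mitochondrion volume and MCI with variance
#' split across person / cell / within-cell levels at the reported
#' log-scale SDs (volume 0.28 / 0.14 / 0.81, MCI 0.43 / 0.26 / 0.68);
#' control nanotunnel rate 2.1 per 100 mitochondria vs 38 in disease; the
#' disease MCI distribution shifted so a target fraction (0.46) of its
#' mass lies below the control 10th percentile.
#'
#' @param n_control,n_disease subjects per group.
#' @param cells_per_subject,mito_per_cell hierarchy sizes.
#' @param vol_meanlog,vol_sds log-volume center (log um^3) and level SDs
#'   `(person, cell, within)`.
#' @param mci_meanlog,mci_sds same for log MCI (above the spherical
#'   floor).
#' @param disease_simple_mass fraction of the disease MCI distribution
#'   below the control q10 (0 < mass < 1).
#' @param nt_rate_control,nt_rate_disease nanotunnels per 100.
#' @param seed mandatory RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 8, n_disease = 6,
                        cells_per_subject = 3, mito_per_cell = 50,
                        vol_meanlog = log(0.25),
                        vol_sds = c(person = 0.28, cell = 0.14,
                                    within = 0.81),
                        mci_meanlog = log(1.1),
                        mci_sds = c(person = 0.43, cell = 0.26,
                                    within = 0.68),
                        disease_simple_mass = 0.46,
                        nt_rate_control = 2.1, nt_rate_disease = 38,
                        seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (disease_simple_mass <= 0 || disease_simple_mass >= 1)
    stop("infeasible disease simple-mass target", call. = FALSE)
  stopifnot(all(vol_sds >= 0), all(mci_sds >= 0),
            nt_rate_control >= 0, nt_rate_disease >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort of per-mitochondrion metrics
#'
#' Hierarchical lognormal draws: for each metric,
#' `log m = mu + b_person + b_cell + e` with independent Gaussian levels
#' at the spec's SDs. MCI is a spherical floor `9/(4 pi)` plus a
#' lognormal excess. The disease group's MCI location is shifted so that
#' (in distribution) `disease_simple_mass` of its mitochondria fall below
#' the control population's theoretical 10th percentile; its nanotunnel
#' counts are Poisson at the elevated rate. Ground-truth parameters are
#' attached for parameter-recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list: `metrics` (per-mitochondrion data.frame: subject_id,
#'   cell_id, organelle_id, group, mci, volume_um3),
#'   `nanotunnel_counts` (per subject), `truth` (the generating
#'   parameters, incl. the theoretical control q10 used for the shift).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  floor_mci <- 9 / (4 * pi)
  draw_group <- function(n_subj, prefix, mci_mu) {
    rows <- list()
    for (si in seq_len(n_subj)) {
      bp_v <- rnorm(1, 0, spec$vol_sds["person"])
      bp_m <- rnorm(1, 0, spec$mci_sds["person"])
      for (ci in seq_len(spec$cells_per_subject)) {
        bc_v <- rnorm(1, 0, spec$vol_sds["cell"])
        bc_m <- rnorm(1, 0, spec$mci_sds["cell"])
        nm <- spec$mito_per_cell
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%02d", prefix, si),
          cell_id = sprintf("c%d", ci),
          organelle_id = seq_len(nm),
          group = if (prefix == "ctl") "control" else "disease",
          volume_um3 = exp(spec$vol_meanlog + bp_v + bc_v +
                             rnorm(nm, 0, spec$vol_sds["within"])),
          mci = floor_mci + exp(mci_mu + bp_m + bc_m +
                                  rnorm(nm, 0, spec$mci_sds["within"])))
      }
    }
    do.call(rbind, rows)
  }
  sd_tot <- sqrt(sum(spec$mci_sds^2))
  q10_log <- spec$mci_meanlog + sd_tot * qnorm(0.10)
  mu_disease <- q10_log - sd_tot * qnorm(spec$disease_simple_mass)
  ctl <- draw_group(spec$n_control, "ctl", spec$mci_meanlog)
  dis <- draw_group(spec$n_disease, "pat", mu_disease)
  metrics <- rbind(ctl, dis)
  subj <- unique(metrics[, c("subject_id", "group")])
  n_per_subj <- spec$cells_per_subject * spec$mito_per_cell
  rate <- ifelse(subj$group == "control", spec$nt_rate_control,
                 spec$nt_rate_disease)
  nt <- data.frame(subject_id = subj$subject_id,
                   n_nanotunnels = rpois(nrow(subj),
                                         rate * n_per_subj / 100))
  list(metrics = metrics, nanotunnel_counts = nt,
       truth = list(spec = spec, q10_log_control = q10_log,
                    mu_mci_disease = mu_disease,
                    floor_mci = floor_mci))
}

#' Generate per-individual feature vectors with chosen group effects
#'
#' Direct generator of cohort summary features (the eight signature
#' features) for signature-recovery experiments: every feature is drawn
#' around the same baseline in both groups except those named in
#' `effects`, which are shifted in the disease group. With effects on
#' `pct_simple` and `nanotunnels_per_100` only, those two are the only
#' informative features, mirroring the reported disease signature.
#'
#' @param n_control,n_disease individuals per group.
#' @param effects named numeric: additive disease shifts on selected
#'   features (default: `pct_simple` +36, `nanotunnels_per_100` +35.9 —
#'   the reported control-vs-disease contrasts).
#' @param noise_sd relative between-individual noise (default 0.15).
#' @param seed mandatory RNG seed.
#' @return data.frame of summaries compatible with
#'   [assemble_features()].
#' @export
generate_feature_cohort <- function(n_control = 8, n_disease = 6,
                                    effects = c(pct_simple = 36,
                                                nanotunnels_per_100 = 35.9),
                                    noise_sd = 0.15, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  base <- c(pct_simple = 10, pct_complex = 10, pct_small = 10,
            pct_large = 10, median_mci = 1.8, median_volume = 0.25,
            volume_density_pct = 2.6, nanotunnels_per_100 = 2.1)
  stopifnot(all(names(effects) %in% names(base)))
  n <- n_control + n_disease
  grp <- rep(c("control", "disease"), c(n_control, n_disease))
  out <- data.frame(subject_id = sprintf("i%02d", seq_len(n)),
                    group = grp)
  for (f in names(base)) {
    mu <- rep(base[[f]], n)
    if (f %in% names(effects))
      mu[grp == "disease"] <- mu[grp == "disease"] + effects[[f]]
    out[[f]] <- pmax(mu * (1 + rnorm(n, 0, noise_sd)), 0)
  }
  out
}
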