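#' Pipeline defaults
#'
#' All tunable constants of the pipeline, overridable from a YAML file
#' ([load_config()]) or per call. Units are nm unless stated otherwise.
#'
#' \describe{
#'   \item{voxel_size}{`(dx, dy, dz)` nm; default `(10, 10, 30)`.}
#'   \item{exclude_border}{drop organelles touching the volume boundary
#'     (their surfaces are interrupted at the block edges).}
#'   \item{min_voxels}{organelles below this voxel count are retained but
#'     flagged unreliable for MCI (default 20): at 30 nm sections tiny
#'     objects mesh unstably.}
#'   \item{smooth_sigma}{Gaussian pre-filter for isosurfacing, in voxel
#'     units per axis (default 1.5); 0 disables.}
#'   \item{laplacian_passes}{optional Laplacian mesh smoothing passes
#'     (default 0).}
#'   \item{volume_tolerance}{relative mesh-vs-voxel volume discrepancy
#'     above which an organelle is flagged (default 0.1).}
#'   \item{myofibril_width, sarcomere_length}{geometric MBI defaults,
#'     1000 nm and 2000 nm.}
#'   \item{nanotunnel_d_max, nanotunnel_l_min}{detection thresholds,
#'     250 nm and 50 nm, bracketing reported nanotunnel dimensions.}
#'   \item{membrane_correction}{external-to-lumen diameter correction,
#'     24 nm (2 nm OMM + 2 nm IMM + 8 nm intermembrane space, both sides).}
#'   \item{nucleoid_diameter}{mtDNA nucleoid size for passability, 110 nm.}
#'   \item{kurtosis}{`"raw"` (non-excess, Gaussian = 3) or `"excess"`.}
#' }
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    voxel_size = c(10, 10, 30),
    exclude_border = FALSE,
    min_voxels = 20,
    smooth_sigma = 1.5,
    laplacian_passes = 0,
    volume_tolerance = 0.1,
    myofibril_width = 1000,
    sarcomere_length = 2000,
    nanotunnel_d_max = 250,
    nanotunnel_l_min = 50,
    membrane_correction = 24,
    nucleoid_diameter = 110,
    kurtosis = "raw"
  )
}

#' Load configuration
#'
#' Reads a YAML key-value file and merges it over [default_config()];
#' explicit `overrides` take precedence over both.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides named list, highest precedence (e.g. CLI flags).
#' @return Named list with the full configuration.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      bad <- setdiff(names(user), names(cfg))
      if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "),
             "\nvalid keys: ", paste(names(cfg), collapse = ", "),
             call. = FALSE)
      cfg[names(user)] <- user
    }
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  cfg
}

metrics_columns <- c(
  "subject_id", "cell_id", "organelle_id", "group", "compartment",
  "volume_um3", "sa_um2", "mci", "sphericity", "mbi", "mbi_class",
  "spans_sarcomere", "n_nanotunnels")

#' Write / read a per-organelle metrics table
#'
#' CSV with a fixed column order and a `#`-comment header documenting
#' units. Rows are keyed by (subject_id, cell_id, organelle_id); the key
#' must be unique.
#'
#' @param table data.frame of per-organelle metrics.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_metrics_table <- function(table, path) {
  key <- interaction(table$subject_id, table$cell_id, table$organelle_id,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, cell_id, organelle_id) key", call. = FALSE)
  done <- !is.na(table$volume_um3)
  if (any(done & (table$volume_um3 <= 0 | table$sa_um2 <= 0)))
    stop("completed rows must have positive volume and surface area",
         call. = FALSE)
  miss <- setdiff(metrics_columns, names(table))
  for (m in miss) table[[m]] <- NA
  extra <- setdiff(names(table), metrics_columns)
  table <- table[, c(metrics_columns, extra)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mitomorph3d metrics: volume_um3 in um^3, sa_um2 in um^2; mci, sphericity, mbi dimensionless", con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
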