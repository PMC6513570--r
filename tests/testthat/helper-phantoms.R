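# analytic phantom helpers shared across tests

sphere_volume <- function(r, voxel_size = c(10, 10, 30), margin = 3)
  voxelize(shape_spec("sphere", r = r), voxel_size, margin)

capsule_volume <- function(r, len, axis = "z",
                           voxel_size = c(10, 10, 30), margin = 3)
  voxelize(shape_spec("capsule", r = r, length = len, axis = axis),
           voxel_size, margin)

sphere_sa <- function(r) 4 * pi * r^2
sphere_v <- function(r) 4 / 3 * pi * r^3
capsule_sa <- function(r, len) 2 * pi * r * len + 4 * pi * r^2
capsule_v <- function(r, len) pi * r^2 * len + 4 / 3 * pi * r^3

mask_of <- function(vol) vol$labels > 0L

# mesh + measure a phantom in one go
measure_phantom <- function(vol, smooth_sigma = 1.5) {
  mesh <- mesh_from_mask(mask_of(vol), vol$voxel_size,
                         smooth_sigma = smooth_sigma)
  list(sa = mesh_surface_area(mesh), v = mesh_volume(mesh), mesh = mesh)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
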