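# Voxel-center coordinates for a grid: three arrays broadcastable to the grid.
grid_coords <- function(grid_shape) {
  list(
    x = array(rep(seq_len(grid_shape[1]), times = prod(grid_shape[2:3])), grid_shape),
    y = array(rep(rep(seq_len(grid_shape[2]), each = grid_shape[1]),
                  times = grid_shape[3]), grid_shape),
    z = array(rep(seq_len(grid_shape[3]), each = prod(grid_shape[1:2])), grid_shape)
  )
}

# Logical mask of a parametric shape on the grid.
shape_mask <- function(geometry, coords) {
  ell <- function(center, radii) {
    ((coords$x - center[1]) / radii[1])^2 +
      ((coords$y - center[2]) / radii[2])^2 +
      ((coords$z - center[3]) / radii[3])^2 <= 1
  }
  switch(geometry$type,
    sphere = ,
    ellipsoid = ell(geometry$center, geometry$radii),
    shell = ell(geometry$center, geometry$radii) &
      !ell(geometry$center, geometry$inner_scale * geometry$radii),
    abort(paste0("unknown geometry type: ", geometry$type))
  )
}

#' Render a phantom specification into labeled ground-truth volumes
#'
#' Renders every compartment onto the voxel grid, producing an integer label
#' volume and matching ground-truth TSC volume. Non-fill compartments must be
#' pairwise disjoint; a `fill` compartment (e.g. white matter) claims the
#' voxels of its shape left unclaimed by all other compartments. Rendering is
#' purely geometric and deterministic; `seed` is accepted for interface
#' symmetry with the stochastic stages.
#'
#' @param spec A `natsc_phantom_spec` (see [phantom_spec()],
#'   [default_phantom_spec()]).
#' @param seed Integer, unused by the deterministic renderer.
#' @return A `natsc_phantom` list: `label_volume` (3-D integer array, 0 =
#'   background), `truth_tsc_volume` (3-D array, mmol/L), `truth_params`
#'   (tibble keyed by `label_id`), `voxel_size`, and the originating `spec`.
#' @export
build_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "natsc_phantom_spec"))
  coords <- grid_coords(spec$grid_shape)
  labels <- array(0L, spec$grid_shape)
  owner <- array(NA_character_, spec$grid_shape)

  is_fill <- vapply(spec$compartments, function(co) isTRUE(co$fill), logical(1))
  for (co in spec$compartments[!is_fill]) {
    m <- shape_mask(co$geometry, coords)
    clash <- m & labels != 0L
    if (any(clash)) {
      other <- owner[which(clash)[1]]
      abort(paste0("compartments overlap: '", co$name, "' and '", other, "'"))
    }
    if (!any(m)) abort(paste0("compartment '", co$name, "' renders zero voxels"))
    labels[m] <- co$label_id
    owner[m] <- co$name
  }
  for (co in spec$compartments[is_fill]) {
    m <- shape_mask(co$geometry, coords) & labels == 0L
    if (!any(m)) abort(paste0("compartment '", co$name, "' renders zero voxels"))
    labels[m] <- co$label_id
  }

  tsc_by_label <- numeric(max(labels) + 1L)  # index = label + 1; background 0
  for (co in spec$compartments) tsc_by_label[co$label_id + 1L] <- co$true_tsc
  truth_tsc <- array(tsc_by_label[labels + 1L], spec$grid_shape)

  params <- purrr::map_dfr(spec$compartments, function(co) {
    tibble(label_id = co$label_id, name = co$name, true_tsc = co$true_tsc,
           t2_short = co$t2_short, t2_long = co$t2_long,
           short_fraction = co$short_fraction)
  })

  structure(
    list(label_volume = labels, truth_tsc_volume = truth_tsc,
         truth_params = params, voxel_size = spec$voxel_size, spec = spec),
    class = "natsc_phantom"
  )
}

#' @export
print.natsc_phantom <- function(x, ...) {
  counts <- table(x$label_volume[x$label_volume > 0])
  cat("<natsc_phantom> ", paste(dim(x$label_volume), collapse = " x "),
      " voxels at ", x$voxel_size, " mm\n", sep = "")
  info <- x$truth_params
  info$voxels <- as.integer(counts[as.character(info$label_id)])
  print(as_tibble(info), n = nrow(info))
  invisible(x)
}

# Voxel count of the intracranial volume for a rendered phantom.
icv_voxel_count <- function(phantom) {
  sum(phantom$label_volume %in% phantom$spec$icv_labels)
}
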