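#' Shape specifications for synthetic scenes
#'
#' Continuous-geometry primitives used by [rasterize_scene()]. All positions
#' and sizes are in nm, in `(z, y, x)` order. A voxel belongs to a shape iff
#' its physical center lies inside the continuous shape (center-in-shape
#' rasterization, which keeps voxel-count volume estimates unbiased).
#'
#' * `shape_sphere`: ball of the given diameter (a Type I mitochondrion).
#' * `shape_capsule`: cylinder with hemispherical caps; `length_nm` is the
#'   end-to-end extent including caps (Type II/III tubules).
#' * `shape_moas`: mitochondria-on-a-string: `n_beads` spherical beads joined
#'   by thin cylindrical necks. Defaults follow the nominal MOAS geometry --
#'   beads about 0.5 um across joined by necks about 65 nm across. Beads are
#'   modeled as spheres rather than literal teardrops: the classifier consumes
#'   bead/neck radii, for which the teardrop taper is immaterial.
#'
#' @param diameter_nm,length_nm,bead_diameter_nm,neck_diameter_nm,neck_length_nm
#'   shape dimensions in nm.
#' @param n_beads number of beads (>= 2).
#' @param center_nm shape center `(z, y, x)` in nm.
#' @param axis unit axis direction `(z, y, x)`; default along x.
#' @return A `shape_spec` list.
#' @name shape_specs
NULL

#' @rdname shape_specs
#' @export
shape_sphere <- function(diameter_nm, center_nm) {
  stopifnot(diameter_nm > 0, length(center_nm) == 3)
  structure(list(kind = "sphere", d = diameter_nm, center = as.numeric(center_nm)),
            class = "shape_spec")
}

#' @rdname shape_specs
#' @export
shape_capsule <- function(length_nm, diameter_nm, center_nm, axis = c(0, 0, 1)) {
  stopifnot(length_nm > diameter_nm, diameter_nm > 0, length(center_nm) == 3)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = "capsule", length = length_nm, d = diameter_nm,
                 center = as.numeric(center_nm), axis = axis),
            class = "shape_spec")
}

#' @rdname shape_specs
#' @export
shape_moas <- function(n_beads, bead_diameter_nm = 500, neck_diameter_nm = 65,
                       neck_length_nm = 400, center_nm, axis = c(0, 0, 1)) {
  stopifnot(n_beads >= 2, neck_diameter_nm < bead_diameter_nm,
            neck_length_nm > 0, length(center_nm) == 3)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = "moas", n_beads = as.integer(n_beads),
                 bead_d = bead_diameter_nm, neck_d = neck_diameter_nm,
                 neck_len = neck_length_nm, center = as.numeric(center_nm),
                 axis = axis),
            class = "shape_spec")
}

# end-to-end length of a shape along its axis
shape_length <- function(s) {
  switch(s$kind,
         sphere = s$d,
         capsule = s$length,
         moas = (s$n_beads - 1) * (s$bead_d + s$neck_len) + s$bead_d)
}

# maximal radius perpendicular to the axis
shape_radius <- function(s) {
  switch(s$kind, sphere = s$d / 2, capsule = s$d / 2, moas = s$bead_d / 2)
}

# bead centers of a MOAS, rows (z,y,x) nm
moas_bead_centers <- function(s) {
  tot <- shape_length(s)
  step <- s$bead_d + s$neck_len
  first <- s$center - s$axis * (tot / 2 - s$bead_d / 2)
  t(vapply(seq_len(s$n_beads) - 1L,
           function(i) first + s$axis * (i * step), numeric(3)))
}

shape_bbox <- function(s) {
  r <- shape_radius(s)
  seg_half <- switch(s$kind,
    sphere = c(0, 0, 0),
    capsule = abs(s$axis) * (s$length / 2 - s$d / 2),
    moas = abs(s$axis) * (shape_length(s) / 2 - s$bead_d / 2))
  rbind(lo = s$center - seg_half - r, hi = s$center + seg_half + r)
}

#' Place an ER tube at a controlled gap from a mitochondrion
#'
#' Positions a short ER tubule (a thin capsule parallel to the target's axis)
#' so that the surface-to-surface distance to the target shape equals
#' `gap_nm`, used to probe the contact-site criterion. The placement is made
#' along one transverse grid axis at the target's surface so that, when the
#' target center sits on the voxel-center lattice, the rasterized
#' surface-to-surface distance is controlled to within half a voxel (and is
#' exact when `gap_nm` is a multiple of the spacing along the offset axis).
#'
#' @param target_id index of the target shape in the scene's shape list.
#' @param gap_nm surface-to-surface distance in nm (>= 0).
#' @param patch_extent_nm length of the ER tube apposed to the target.
#' @param tube_diameter_nm ER tube diameter.
#' @param offset_axis `"y"` or `"z"`: transverse grid axis along which the
#'   tube is offset from the target surface.
#' @param along_frac position of the patch center along the target axis, as a
#'   fraction of the target length in (0, 1); 0.5 = mid-shape.
#' @return An `er_placement` list.
#' @export
er_placement <- function(target_id, gap_nm, patch_extent_nm = 400,
                         tube_diameter_nm = 100, offset_axis = c("y", "z"),
                         along_frac = 0.5) {
  offset_axis <- match.arg(offset_axis)
  stopifnot(gap_nm >= 0, patch_extent_nm > 0, tube_diameter_nm > 0,
            along_frac > 0, along_frac < 1)
  structure(list(target_id = as.integer(target_id), gap = gap_nm,
                 extent = patch_extent_nm, tube_d = tube_diameter_nm,
                 offset_axis = offset_axis, along_frac = along_frac),
            class = "er_placement")
}

#' Scene specification for the synthetic generator
#'
#' @param spacing voxel spacing `(z, y, x)` nm; the default matches the
#'   acquisition geometry of 50 nm sections at 8 nm pixels.
#' @param shapes list of [shape_specs] (the mitochondria).
#' @param er list of [er_placement()]s.
#' @param dim optional grid dimensions `(nz, ny, nx)`; computed from the
#'   shapes plus `margin` voxels per side when omitted.
#' @param margin background margin in voxels when auto-sizing (>= 2 unless a
#'   boundary-touching fixture is requested).
#' @param allow_boundary permit shapes to touch or exceed the grid.
#' @param seed integer recorded in the ground truth (the rasterizer itself is
#'   deterministic).
#' @return A `scene_spec`.
#' @export
scene_spec <- function(spacing = c(50, 8, 8), shapes, er = list(), dim = NULL,
                       margin = 3L, allow_boundary = FALSE, seed = NULL) {
  stopifnot(length(spacing) == 3, all(spacing > 0), length(shapes) >= 1)
  structure(list(spacing = as.numeric(spacing), shapes = shapes, er = er,
                 dim = dim, margin = as.integer(margin),
                 allow_boundary = allow_boundary, seed = seed),
            class = "scene_spec")
}

# snap a physical coordinate to the nearest voxel-center along one axis
snap_center <- function(v, h) (round(v / h - 0.5) + 0.5) * h

# logical mask of a shape over index ranges zr/yr/xr (1-based grid indices)
rasterize_shape <- function(s, spacing, zr, yr, xr) {
  zc <- (zr - 0.5) * spacing[1]
  yc <- (yr - 0.5) * spacing[2]
  xc <- (xr - 0.5) * spacing[3]
  dims <- c(length(zr), length(yr), length(xr))
  if (s$kind == "sphere") {
    d2 <- outer(outer((zc - s$center[1])^2, (yc - s$center[2])^2, "+"),
                (xc - s$center[3])^2, "+")
    return(array(d2 <= (s$d / 2)^2, dims))
  }
  Z <- array(rep(zc, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(yc, each = dims[1]), times = dims[3]), dims)
  X <- array(rep(xc, each = dims[1] * dims[2]), dims)
  seg_d2 <- function(p1, p2) {
    u <- p2 - p1
    L2 <- sum(u^2)
    wz <- Z - p1[1]; wy <- Y - p1[2]; wx <- X - p1[3]
    if (L2 == 0) return(wz^2 + wy^2 + wx^2)
    t <- (wz * u[1] + wy * u[2] + wx * u[3]) / L2
    t[t < 0] <- 0; t[t > 1] <- 1
    (wz - t * u[1])^2 + (wy - t * u[2])^2 + (wx - t * u[3])^2
  }
  if (s$kind == "capsule") {
    half <- s$length / 2 - s$d / 2
    p1 <- s$center - s$axis * half
    p2 <- s$center + s$axis * half
    return(seg_d2(p1, p2) <= (s$d / 2)^2)
  }
  # moas: union of bead spheres and neck cylinders between bead centers
  bc <- moas_bead_centers(s)
  mask <- array(FALSE, dims)
  br2 <- (s$bead_d / 2)^2
  for (i in seq_len(nrow(bc))) {
    d2 <- (Z - bc[i, 1])^2 + (Y - bc[i, 2])^2 + (X - bc[i, 3])^2
    mask <- mask | (d2 <= br2)
  }
  nr2 <- (s$neck_d / 2)^2
  for (i in seq_len(nrow(bc) - 1L)) {
    mask <- mask | (seg_d2(bc[i, ], bc[i + 1L, ]) <= nr2)
  }
  mask
}

# resolve an ER placement into a capsule shape + achieved-gap bookkeeping
resolve_er_placement <- function(p, shapes, spacing) {
  s <- shapes[[p$target_id]]
  ax <- if (p$offset_axis == "y") 2L else 1L
  h <- spacing[ax]
  if (s$kind == "capsule" || s$kind == "moas") {
    if (!isTRUE(all.equal(abs(s$axis), c(0, 0, 1))))
      stop("ER placement requires the target axis to lie along x")
  }
  Rt <- shape_radius(s)
  half_len <- shape_length(s) / 2
  x_at <- s$center[3] + (p$along_frac - 0.5) * shape_length(s)
  center <- s$center
  center[3] <- x_at
  center[ax] <- s$center[ax] + Rt + p$gap + p$tube_d / 2
  tube <- shape_capsule(length_nm = p$extent + p$tube_d, diameter_nm = p$tube_d,
                        center_nm = center, axis = c(0, 0, 1))
  # achieved rasterized surface-to-surface distance at the tangency column:
  # iso-surfaces of binary masks sit midway between the last inside and first
  # outside voxel centers.
  surf_t <- s$center[ax] + Rt
  j_max <- floor(surf_t / h + 0.5)
  mid_t <- j_max * h
  surf_e <- center[ax] - p$tube_d / 2
  j_min <- ceiling(surf_e / h + 0.5)
  mid_e <- (j_min - 1) * h
  list(shape = tube, gap_requested = p$gap, gap_achieved = mid_e - mid_t,
       target_id = p$target_id)
}

#' Rasterize a synthetic scene into co-registered label volumes
#'
#' Produces one mitochondria and one ER label volume on the same grid, plus a
#' ground-truth record of every generated object and ER placement. Shapes of
#' the same class must not overlap (their labels would not be separable);
#' shapes exceeding the grid raise an error unless the scene allows boundary
#' fixtures.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `mito` and `er` ([label_volume()]s) and `truth`
#'   (list of data.frames `objects` and `er`, plus `seed` and `spacing`).
#' @export
rasterize_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$spacing
  ers <- lapply(spec$er, resolve_er_placement, shapes = spec$shapes, spacing = h)
  all_shapes <- c(spec$shapes, lapply(ers, `[[`, "shape"))
  bb <- vapply(all_shapes, shape_bbox, matrix(0, 2, 3))
  lo_nm <- apply(bb[1, , , drop = FALSE], 2, min)
  hi_nm <- apply(bb[2, , , drop = FALSE], 2, max)

  if (is.null(spec$dim)) {
    dims <- as.integer(ceiling(hi_nm / h) + spec$margin)
  } else {
    dims <- as.integer(spec$dim)
  }
  if (!spec$allow_boundary) {
    if (any(lo_nm < (spec$margin - 1) * h) || any(hi_nm > (dims - spec$margin + 1) * h))
      stop("generation error: shape exceeds grid (set allow_boundary for ",
           "boundary fixtures)")
  }

  paint <- function(vol_arr, shapes_list, what) {
    for (i in seq_along(shapes_list)) {
      s <- shapes_list[[i]]
      box <- shape_bbox(s)
      zr <- max(1L, floor(box[1, 1] / h[1])):min(dims[1], ceiling(box[2, 1] / h[1]) + 1L)
      yr <- max(1L, floor(box[1, 2] / h[2])):min(dims[2], ceiling(box[2, 2] / h[2]) + 1L)
      xr <- max(1L, floor(box[1, 3] / h[3])):min(dims[3], ceiling(box[2, 3] / h[3]) + 1L)
      m <- rasterize_shape(s, h, zr, yr, xr)
      sub <- vol_arr[zr, yr, xr, drop = FALSE]
      if (any(sub != 0L & m))
        stop("generation error: overlapping ", what, " shapes (ids not separable)")
      sub[m] <- i
      vol_arr[zr, yr, xr] <- sub
      if (!any(m)) warning(what, " shape ", i, " rasterized to zero voxels")
    }
    vol_arr
  }

  mito_arr <- paint(array(0L, dims), spec$shapes, "mitochondrion")
  er_arr <- paint(array(0L, dims), lapply(ers, `[[`, "shape"), "er")

  objects <- do.call(rbind, lapply(seq_along(spec$shapes), function(i) {
    s <- spec$shapes[[i]]
    data.frame(
      id = i, kind = s$kind,
      type_true = switch(s$kind,
                         sphere = if (s$d <= 500) "I" else "II",
                         capsule = if (s$length < 5000) "II" else "III",
                         moas = "IV"),
      length_nm = shape_length(s),
      diameter_nm = if (s$kind == "moas") s$bead_d else s$d,
      n_beads = if (s$kind == "moas") s$n_beads else NA_integer_,
      bead_diameter_nm = if (s$kind == "moas") s$bead_d else NA_real_,
      neck_diameter_nm = if (s$kind == "moas") s$neck_d else NA_real_,
      neck_length_nm = if (s$kind == "moas") s$neck_len else NA_real_
    )
  }))
  er_truth <- if (length(ers)) do.call(rbind, lapply(seq_along(ers), function(i) {
    e <- ers[[i]]
    data.frame(er_id = i, target_id = e$target_id,
               gap_requested_nm = e$gap_requested,
               gap_achieved_nm = e$gap_achieved,
               patch_extent_nm = spec$er[[i]]$extent,
               tube_diameter_nm = spec$er[[i]]$tube_d)
  })) else data.frame(er_id = integer(), target_id = integer(),
                      gap_requested_nm = numeric(), gap_achieved_nm = numeric(),
                      patch_extent_nm = numeric(), tube_diameter_nm = numeric())

  list(
    mito = label_volume(mito_arr, h, "mitochondrion", "synthetic scene"),
    er = label_volume(er_arr, h, "er", "synthetic scene"),
    truth = list(objects = objects, er = er_truth, seed = spec$seed,
                 spacing = h)
  )
}

#' Canonical validation panel
#'
#' A fixed scene containing one exemplar of each morphological type -- a
#' 0.4 um sphere (Type I), a 3 um capsule (Type II), a 6 um capsule
#' (Type III) and a 3-bead MOAS (Type IV) -- plus five ER tubes placed
#' against the Type II capsule at surface gaps of 10, 20, 24, 26 and 40 nm,
#' spanning the 25 nm contact criterion. Rasterized on an isotropic 8 nm grid
#' so that analytic size checks carry low discretization error. Fully
#' deterministic; `seed` is recorded in the ground truth.
#'
#' @param seed integer recorded in the ground-truth record.
#' @return As [rasterize_scene()].
#' @export
make_fixture_panel <- function(seed = 1L) {
  h <- c(8, 8, 8)
  y0 <- snap_center(420, h[2])
  zb <- function(v) snap_center(v, h[1])
  x_for <- function(len) snap_center(80 + len / 2, h[3])
  shapes <- list(
    shape_sphere(400, c(zb(260), y0, x_for(400))),
    shape_capsule(3000, 250, c(zb(700), y0, x_for(3000))),
    shape_capsule(6000, 250, c(zb(1050), y0, x_for(6000))),
    shape_moas(3, 500, 65, 400, c(zb(1600), y0, x_for(2300)))
  )
  gaps <- c(10, 20, 24, 26, 40)
  er <- lapply(seq_along(gaps), function(i) {
    er_placement(target_id = 2L, gap_nm = gaps[i], patch_extent_nm = 300,
                 tube_diameter_nm = 100, offset_axis = "y",
                 along_frac = 0.12 + 0.19 * (i - 1))
  })
  rasterize_scene(scene_spec(spacing = h, shapes = shapes, er = er,
                             margin = 3L, seed = as.integer(seed)))
}

#' Sample a synthetic mitochondrial population with known type composition
#'
#' Draws `n` objects with the stated type fractions (multinomial, seeded) and
#' per-type size jitter within class bounds, laid out in non-overlapping
#' bands along the section axis. Jitter ranges keep every object safely
#' inside its nominal class: spheres 0.32-0.48 um across; Type II tubules
#' 0.9-4.5 um; Type III tubules 5.3-6.5 um; MOAS with 2-4 beads of
#' 0.45-0.55 um joined by 60-70 nm necks of 0.3-0.7 um length.
#'
#' @param composition named fractions over types `I`, `II`, `III`, `IV`;
#'   must lie in \[0, 1\] and sum to 1.
#' @param n number of objects (>= 1).
#' @param seed integer seed; all randomness flows through it.
#' @param spacing voxel spacing `(z, y, x)` nm.
#' @param rasterize if `FALSE`, return the scene specification and ground
#'   truth without building the (possibly large) label arrays.
#' @return As [rasterize_scene()], or `list(spec, truth)` when
#'   `rasterize = FALSE`.
#' @export
sample_population <- function(composition, n, seed = 1L,
                              spacing = c(50, 8, 8), rasterize = TRUE) {
  if (length(n) != 1 || n < 1) stop("n must be >= 1")
  types <- c("I", "II", "III", "IV")
  comp <- setNames(numeric(4), types)
  comp[names(composition)] <- composition
  if (any(comp < 0) || any(comp > 1) || abs(sum(comp) - 1) > 1e-8)
    stop("composition fractions must lie in [0, 1] and sum to 1")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  drawn <- sample(types, n, replace = TRUE, prob = comp)
  params <- lapply(drawn, function(ty) {
    switch(ty,
      I = list(kind = "sphere", d = runif(1, 320, 480)),
      II = list(kind = "capsule", len = runif(1, 900, 4500),
                d = runif(1, 180, 300)),
      III = list(kind = "capsule", len = runif(1, 5300, 6500),
                 d = runif(1, 180, 300)),
      IV = list(kind = "moas", n_beads = sample(2:4, 1),
                bead_d = runif(1, 450, 550), neck_d = runif(1, 60, 70),
                neck_len = runif(1, 300, 700)))
  })

  ext_len <- vapply(params, function(p) switch(p$kind,
    sphere = p$d, capsule = p$len,
    moas = (p$n_beads - 1) * (p$bead_d + p$neck_len) + p$bead_d), numeric(1))
  ext_r <- vapply(params, function(p) switch(p$kind,
    sphere = p$d / 2, capsule = p$d / 2, moas = p$bead_d / 2), numeric(1))

  marg_nm <- 4 * spacing
  band_z <- max(2 * ext_r) + 2 * marg_nm[1]
  y_mid <- snap_center(max(ext_r) + marg_nm[2], spacing[2])
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params[[i]]
    zc <- snap_center((i - 0.5) * band_z, spacing[1])
    xc <- snap_center(marg_nm[3] + ext_len[i] / 2, spacing[3])
    ctr <- c(zc, y_mid, xc)
    shapes[[i]] <- switch(p$kind,
      sphere = shape_sphere(p$d, ctr),
      capsule = shape_capsule(p$len, p$d, ctr),
      moas = shape_moas(p$n_beads, p$bead_d, p$neck_d, p$neck_len, ctr))
  }
  spec <- scene_spec(spacing = spacing, shapes = shapes, margin = 3L,
                     seed = as.integer(seed))
  if (!rasterize) {
    truth <- data.frame(id = seq_len(n), type_true = drawn)
    return(list(spec = spec, truth = truth))
  }
  rasterize_scene(spec)
}
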