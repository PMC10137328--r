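# Shared fixtures, memoised across test files (testthat loads helpers once
# per run). Everything is generated in code; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

get_panel <- function() memo("panel", make_fixture_panel(seed = 1))

get_panel_classification <- function() {
  memo("panel_cls", classify_population(get_panel()$mito))
}

# snap a coordinate to the voxel-center lattice of spacing h
snapc <- function(v, h) (round(v / h - 0.5) + 0.5) * h

# small isotropic 2 nm scene: one capsule plus one ER tube at a given gap.
# Centers sit on the voxel-center lattice and the capsule radius is chosen so
# that even-valued gaps rasterize exactly (see the generator docs).
gap_fixture_2nm <- function(gap_nm) {
  memo(paste0("gap2nm_", gap_nm), {
    h <- c(2, 2, 2)
    zc <- snapc(110, 2)
    yc <- snapc(160, 2)
    sh <- list(shape_capsule(500, 150, c(zc, yc, 280)))
    er <- list(er_placement(1L, gap_nm, patch_extent_nm = 200,
                            tube_diameter_nm = 100))
    rasterize_scene(scene_spec(spacing = h, shapes = sh, er = er, margin = 3L))
  })
}

gap_fixture_contacts <- function(gap_nm, params = contact_params()) {
  key <- paste0("gap2nm_ct_", gap_nm, "_", params$max_gap_nm)
  memo(key, {
    sc <- gap_fixture_2nm(gap_nm)
    o <- extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
    detect_contacts(o, sc$er, params)
  })
}

# 3-bead MOAS at the nominal geometry on an 8 nm isotropic grid
get_moas_8nm <- function() {
  memo("moas8", {
    sc <- rasterize_scene(scene_spec(
      spacing = c(8, 8, 8),
      shapes = list(shape_moas(3, 500, 65, 400, c(snapc(300, 8), snapc(300, 8), snapc(1200, 8))))
    ))
    extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  })
}

get_moas_profile <- function() memo("moas8_prof", skeleton_profile(get_moas_8nm()))

# sphere d = 500 nm on an isotropic grid
get_sphere_8nm <- function() {
  memo("sphere8", {
    sc <- rasterize_scene(scene_spec(
      spacing = c(8, 8, 8),
      shapes = list(shape_sphere(500, rep(snapc(300, 8), 3)))
    ))
    extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  })
}

# capsule 2 um x 0.2 um on an isotropic grid
get_capsule_8nm <- function() {
  memo("capsule8", {
    sc <- rasterize_scene(scene_spec(
      spacing = c(8, 8, 8),
      shapes = list(shape_capsule(2000, 200, c(snapc(220, 8), snapc(220, 8), 1100)))
    ))
    extract_objects(sc$mito, exclude_boundary = FALSE)[[1]]
  })
}

# random 26-connected voxel blob grown from a seed voxel
random_blob <- function(n_vox, dims = c(24L, 24L, 24L), spacing = c(50, 8, 8),
                        seed = 1) {
  set.seed(seed)
  arr <- array(0L, dims)
  cur <- matrix(as.integer(dims %/% 2), 1)
  arr[cur] <- 1L
  frontier <- cur
  while (sum(arr) < n_vox && nrow(frontier) > 0) {
    i <- sample.int(nrow(frontier), 1)
    v <- frontier[i, ]
    d <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    w <- v + d
    if (all(w >= 2L) && all(w <= dims - 1L)) {
      if (arr[w[1], w[2], w[3]] == 0L) {
        arr[w[1], w[2], w[3]] <- 1L
        frontier <- rbind(frontier, w)
      }
    }
  }
  label_volume(arr, spacing)
}

# construct a skeleton_profile by hand (single path along x at given radii)
fake_profile <- function(radius_nm, step_nm = 50) {
  n <- length(radius_nm)
  nodes <- cbind(z = rep(0, n), y = rep(0, n), x = seq_len(n) * step_nm)
  structure(list(nodes = nodes, radius_nm = radius_nm,
                 paths = list(seq_len(n)), spacing_iso = 8,
                 low_confidence = FALSE),
            class = "skeleton_profile")
}

# brute-force farthest pair distance (um) over all voxel centers
brute_length_um <- function(obj) {
  ctr <- sweep(obj$voxels - 0.5, 2, obj$spacing, "*")
  max(stats::dist(ctr)) / 1e3
}
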