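#' Contact-site detection parameters
#'
#' @param max_gap_nm maximum mitochondrion-ER surface-to-surface distance for
#'   a face to count as juxtaposed (default 25 nm, the conventional MERCS
#'   criterion).
#' @param min_patch_faces minimum number of mesh faces in a reported patch.
#' @return object of class `contact_params`.
#' @export
contact_params <- function(max_gap_nm = 25, min_patch_faces = 1L) {
  stopifnot(max_gap_nm > 0, min_patch_faces >= 1)
  structure(list(max_gap_nm = max_gap_nm,
                 min_patch_faces = as.integer(min_patch_faces)),
            class = "contact_params")
}

# combined iso-surface mesh of all ER objects, with per-face ER object id
er_surface_mesh <- function(er_vol, smooth = 1L) {
  objs <- extract_objects(er_vol, exclude_boundary = FALSE)
  V <- NULL
  F <- NULL
  fid <- integer(0)
  for (o in objs) {
    m <- surface_mesh(o, smooth = smooth)
    off <- if (is.null(V)) 0L else nrow(V)
    V <- rbind(V, m$vertices)
    F <- rbind(F, m$faces + off)
    fid <- c(fid, rep(o$id, nrow(m$faces)))
  }
  if (is.null(V)) {
    V <- matrix(numeric(0), 0, 3)
    F <- matrix(integer(0), 0, 3)
  }
  list(vertices = V, faces = F, er_id = fid, objects = objs)
}

#' Per-face gap distances from a mitochondrion's surface to the ER
#'
#' For every face centroid of the mitochondrion's iso-surface mesh, the
#' distance (nm) to the nearest point of the ER iso-surface. Both surfaces
#' are sub-voxel interpolated meshes, so gaps are measured surface to
#' surface, not between voxel centers -- essential when the 25 nm criterion
#' is applied on grids with 50 nm sections. Distances beyond `cap_nm`
#' (default four times the contact criterion) are reported as `Inf`; with an
#' empty ER volume all gaps are `Inf`.
#'
#' @param mito_obj an `organelle_object` (mitochondrion).
#' @param er_vol the co-registered ER [label_volume()].
#' @param params [contact_params()].
#' @param smooth surface-mesh smoothing passes.
#' @param cap_nm optional search cap in nm.
#' @return list: `mesh` (the mitochondrion [surface_mesh()]), `gap_nm`
#'   (per face), `er_id` (nearest ER object per face, NA beyond cap),
#'   `er_mesh`.
#' @export
surface_gap_field <- function(mito_obj, er_vol, params = contact_params(),
                              smooth = 1L, cap_nm = NULL) {
  stopifnot(identical(mito_obj$dim, dim(er_vol$labels)),
            isTRUE(all.equal(mito_obj$spacing, er_vol$spacing)))
  mesh <- surface_mesh(mito_obj, smooth = smooth)
  erm <- er_surface_mesh(er_vol, smooth = smooth)
  spacing <- mito_obj$spacing
  half_diag <- 0.5 * sqrt(sum(spacing^2))
  cap <- cap_nm %||% (params$max_gap_nm + 4 * half_diag)
  nfm <- nrow(mesh$faces)
  gap <- rep(Inf, nfm)
  er_id <- rep(NA_integer_, nfm)
  if (nrow(erm$faces) == 0 || nfm == 0) {
    return(list(mesh = mesh, gap_nm = gap, er_id = er_id, er_mesh = erm))
  }
  # prescreen face centroids with a voxel distance transform to the ER over a
  # window around the ER volume: the transform (to ER voxel centers) never
  # underestimates the surface gap by more than half a voxel diagonal, so
  # faces beyond cap + half_diag cannot qualify and skip the exact (and on
  # dense meshes expensive) mesh-distance query
  d <- dim(er_vol$labels)
  er_idx <- which(er_vol$labels != 0L)
  av <- arrayInd(er_idx, d)
  pad <- as.integer(ceiling((cap + 2 * half_diag) / spacing)) + 1L
  lo <- pmax(as.integer(apply(av, 2, min)) - pad, 1L)
  hi <- pmin(as.integer(apply(av, 2, max)) + pad, d)
  dims_w <- hi - lo + 1L
  win <- array(TRUE, dims_w)
  win[cbind(av[, 1] - lo[1] + 1L, av[, 2] - lo[2] + 1L,
            av[, 3] - lo[3] + 1L)] <- FALSE
  edt_w <- cpp_edt(win, dims_w, spacing)
  ci <- floor(sweep(mesh$centroids, 2, spacing, "/")) + 1
  inw <- ci[, 1] >= lo[1] & ci[, 1] <= hi[1] &
         ci[, 2] >= lo[2] & ci[, 2] <= hi[2] &
         ci[, 3] >= lo[3] & ci[, 3] <= hi[3]
  d_a <- rep(Inf, nfm)
  d_a[inw] <- edt_w[cbind(ci[inw, 1] - lo[1] + 1L, ci[inw, 2] - lo[2] + 1L,
                          ci[inw, 3] - lo[3] + 1L)]
  cand <- which(d_a <= cap + half_diag)
  if (length(cand)) {
    q <- cpp_point_mesh_dist(mesh$centroids[cand, , drop = FALSE],
                             erm$vertices, erm$faces, cap)
    gap[cand] <- q$dist
    er_id[cand] <- ifelse(is.na(q$tri), NA_integer_, erm$er_id[q$tri])
  }
  list(mesh = mesh, gap_nm = gap, er_id = er_id, er_mesh = erm)
}

#' Detect mitochondria-ER contact sites
#'
#' Faces of the mitochondrial surface mesh whose gap to the ER is at most
#' `max_gap_nm` are contact faces; contact faces are grouped into patches by
#' shared-edge adjacency, split by ER object id (one mitochondrion apposed to
#' two ER tubules yields two distinct MERCS). Each patch reports:
#'
#' * `area_um2`: summed face areas;
#' * `length_nm`: maximum pairwise distance between member-face centroids
#'   (the end-to-end extent of the contact);
#' * `volume_um3`: summed volume of the ER voxels of the partner object
#'   whose boundary lies within the gap criterion of this mitochondrion,
#'   attributed to the nearest patch;
#' * `mean_gap_nm`: mean face gap.
#'
#' @inheritParams surface_gap_field
#' @return data.frame of contact sites (possibly 0 rows): `mito_id`, `er_id`,
#'   `patch_id`, `n_faces`, `area_um2`, `length_nm`, `volume_um3`,
#'   `mean_gap_nm`. Attribute `gap_field` carries the underlying
#'   [surface_gap_field()] result.
#' @export
detect_contacts <- function(mito_obj, er_vol, params = contact_params(),
                            smooth = 1L) {
  gf <- surface_gap_field(mito_obj, er_vol, params, smooth = smooth)
  empty <- data.frame(mito_id = integer(), er_id = integer(),
                      patch_id = integer(), n_faces = integer(),
                      area_um2 = numeric(), length_nm = numeric(),
                      volume_um3 = numeric(), mean_gap_nm = numeric())
  sel <- is.finite(gf$gap_nm) & gf$gap_nm <= params$max_gap_nm
  if (!any(sel)) {
    attr(empty, "gap_field") <- gf
    return(empty)
  }
  grp <- ifelse(is.na(gf$er_id), 0L, gf$er_id)
  patch <- cpp_edge_components(gf$mesh$faces, grp, sel)
  ids <- sort(unique(patch[patch > 0L]))

  # ER-side contact volume: ER voxels whose boundary (center minus half a
  # voxel diagonal) lies within the criterion of this mitochondrion
  spacing <- mito_obj$spacing
  half_diag <- 0.5 * sqrt(sum(spacing^2))
  vox_vol_um3 <- prod(spacing) / 1e9
  er_ids_here <- unique(gf$er_id[sel])
  vol_by_patch <- setNames(numeric(length(ids)), ids)
  contact_centroids <- gf$mesh$centroids[sel, , drop = FALSE]
  contact_patch <- patch[sel]
  for (eid in er_ids_here) {
    eo <- Filter(function(o) o$id == eid, gf$er_mesh$objects)[[1]]
    # cheap prefilter: distance transform to the mitochondrion's voxel
    # centers over a window around this ER object, so only ER voxels that
    # can possibly qualify are offered to the exact mesh-distance query
    pad <- as.integer(ceiling((params$max_gap_nm + 3 * half_diag) / spacing))
    lo <- as.integer(apply(eo$voxels, 2, min) - pad)
    hi <- as.integer(apply(eo$voxels, 2, max) + pad)
    dims_w <- hi - lo + 1L
    win <- array(TRUE, dims_w)
    mv <- mito_obj$voxels
    inw <- mv[, 1] >= lo[1] & mv[, 1] <= hi[1] &
           mv[, 2] >= lo[2] & mv[, 2] <= hi[2] &
           mv[, 3] >= lo[3] & mv[, 3] <= hi[3]
    if (!any(inw)) next
    mvw <- mv[inw, , drop = FALSE]
    win[cbind(mvw[, 1] - lo[1] + 1L, mvw[, 2] - lo[2] + 1L,
              mvw[, 3] - lo[3] + 1L)] <- FALSE
    edt_w <- cpp_edt(win, dims_w, spacing)
    ev <- eo$voxels
    dvox <- edt_w[cbind(ev[, 1] - lo[1] + 1L, ev[, 2] - lo[2] + 1L,
                        ev[, 3] - lo[3] + 1L)]
    cand <- which(dvox <= params$max_gap_nm + 2 * half_diag)
    if (!length(cand)) next
    ctr <- sweep(ev[cand, , drop = FALSE] - 0.5, 2, spacing, "*")
    q <- cpp_point_mesh_dist(ctr, gf$mesh$vertices, gf$mesh$faces,
                             params$max_gap_nm + half_diag)
    hit <- which(is.finite(q$dist) & q$dist <= params$max_gap_nm + half_diag)
    if (!length(hit)) next
    # attribute via the nearest mito face when it belongs to a patch of this
    # ER object; otherwise to the patch with the closest contact face
    p_vec <- patch[q$tri[hit]]
    direct <- p_vec > 0L & gf$er_id[q$tri[hit]] == eid
    if (any(direct)) {
      tb <- table(p_vec[direct])
      for (k in names(tb))
        vol_by_patch[k] <- vol_by_patch[k] + tb[[k]] * vox_vol_um3
    }
    for (i in hit[!direct]) {
      d2 <- rowSums(sweep(contact_centroids, 2, ctr[i, ], "-")^2)
      p <- contact_patch[which.min(d2)]
      vol_by_patch[as.character(p)] <- vol_by_patch[as.character(p)] + vox_vol_um3
    }
  }

  rows <- lapply(ids, function(pid) {
    f <- which(patch == pid)
    if (length(f) < params$min_patch_faces) return(NULL)
    cen <- gf$mesh$centroids[f, , drop = FALSE]
    len <- if (nrow(cen) > 1) cpp_max_pair(cen, 5000L, 1024L)[1] else 0
    data.frame(mito_id = mito_obj$id, er_id = gf$er_id[f[1]], patch_id = pid,
               n_faces = length(f),
               area_um2 = sum(gf$mesh$areas[f]) / 1e6,
               length_nm = len,
               volume_um3 = unname(vol_by_patch[as.character(pid)]),
               mean_gap_nm = mean(gf$gap_nm[f]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "gap_field") <- gf
  out
}

#' Per-mitochondrion MERCS coverage summary
#'
#' Coverage is the percentage of the mitochondrion's surface area lying
#' within the contact criterion of the ER: 100 times the summed contact-face
#' areas over the total surface area. Contact lengths are averaged over the
#' mitochondrion's patches.
#'
#' @param mito_rec one row of [measure_objects()] for the mitochondrion.
#' @param contacts the [detect_contacts()] table for the same object.
#' @return data.frame row: `mito_id`, `n_contacts`, `coverage_percent`,
#'   `mean_contact_length_nm`, `total_contact_volume_um3`.
#' @export
mercs_coverage <- function(mito_rec, contacts) {
  if (nrow(contacts) > 0 && any(contacts$mito_id != mito_rec$object_id))
    stop("contacts do not belong to this mitochondrion")
  data.frame(
    mito_id = mito_rec$object_id,
    n_contacts = nrow(contacts),
    coverage_percent = 100 * sum(contacts$area_um2) / mito_rec$SA_um2,
    mean_contact_length_nm = if (nrow(contacts)) mean(contacts$length_nm) else NA_real_,
    total_contact_volume_um3 = sum(contacts$volume_um3)
  )
}

#' Pool MERCS metrics by mitochondrial type
#'
#' Contact metrics are summarized for Types I-III pooled together and for
#' MOAS (Type IV) separately, reporting mean, SEM and n per pool. Pools with
#' no members are absent from the table rather than reported as zero.
#'
#' @param calls classification calls (`object_id`, `type`).
#' @param coverage_tbl rows from [mercs_coverage()] (matched on
#'   `mito_id` = `object_id`).
#' @return data.frame: `pool`, `metric`, `mean`, `sem`, `n`.
#' @export
mercs_by_type <- function(calls, coverage_tbl) {
  m <- merge(calls[, c("object_id", "type")], coverage_tbl,
             by.x = "object_id", by.y = "mito_id")
  if (!nrow(m))
    return(data.frame(pool = character(), metric = character(),
                      mean = numeric(), sem = numeric(), n = integer()))
  m$pool <- ifelse(m$type == "IV", "MOAS", "I-III")
  metrics <- c("coverage_percent", "mean_contact_length_nm",
               "total_contact_volume_um3")
  rows <- list()
  for (pool in unique(m$pool)) {
    sub <- m[m$pool == pool, ]
    for (met in metrics) {
      v <- sub[[met]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      s <- summarize_group(v)
      rows[[length(rows) + 1L]] <-
        data.frame(pool = pool, metric = met, mean = s$mean, sem = s$sem,
                   n = s$n)
    }
  }
  do.call(rbind, rows)
}
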