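#' Classification thresholds for mitochondrial types
#'
#' Length boundaries for the four morphological classes and the bead/neck
#' radius criteria for structural MOAS detection. Two presets are shipped:
#'
#' * `"methods2015"` (default): round Type I up to 0.5 um; Type II tubules
#'   0.5-5 um; Type III 5 um or longer.
#' * `"results2023"`: Type I below 1 um; Type II 1-5 um.
#'
#' The bead and neck radius defaults derive from the nominal MOAS geometry
#' (beads ~0.5 um across, necks ~65 nm across): `bead_min_radius_nm = 150`
#' accepts tapered beads, `neck_max_radius_nm = 45` accepts the ~32.5 nm neck
#' radius with allowance for distance-transform overestimate of about one
#' voxel; `neck_min_run_nm = 100` is a noise gate so that single-node radius
#' dips cannot trigger a MOAS call.
#'
#' @param preset `"methods2015"` or `"results2023"`.
#' @param type1_max_length_um,type2_max_length_um class length bounds (um).
#' @param bead_min_radius_nm minimum skeleton radius inside a bead (nm).
#' @param neck_max_radius_nm maximum skeleton radius inside a neck (nm).
#' @param neck_min_run_nm minimum arclength of a neck run (nm).
#' @param moas_min_beads minimum number of beads for a MOAS call (>= 2).
#' @param moas_max_neck_length_um necks longer than this are flagged (um).
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(preset = c("methods2015", "results2023"),
                                      type1_max_length_um = NULL,
                                      type2_max_length_um = 5.0,
                                      bead_min_radius_nm = 150,
                                      neck_max_radius_nm = 45,
                                      neck_min_run_nm = 100,
                                      moas_min_beads = 2L,
                                      moas_max_neck_length_um = 5.0) {
  preset <- match.arg(preset)
  if (is.null(type1_max_length_um))
    type1_max_length_um <- if (preset == "methods2015") 0.5 else 1.0
  th <- list(preset = preset,
             type1_max_length_um = type1_max_length_um,
             type2_max_length_um = type2_max_length_um,
             bead_min_radius_nm = bead_min_radius_nm,
             neck_max_radius_nm = neck_max_radius_nm,
             neck_min_run_nm = neck_min_run_nm,
             moas_min_beads = as.integer(moas_min_beads),
             moas_max_neck_length_um = moas_max_neck_length_um)
  stopifnot(th$type1_max_length_um < th$type2_max_length_um,
            th$neck_max_radius_nm < th$bead_min_radius_nm,
            th$moas_min_beads >= 2L)
  structure(th, class = "classification_thresholds")
}

# maximal runs of a logical vector: data.frame(start, end)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect beads and necks along a skeleton radius profile
#'
#' Along each maximal skeleton path, contiguous runs of nodes with radius at
#' least `bead_min_radius_nm` are beads; contiguous runs with radius at most
#' `neck_max_radius_nm` whose arclength reaches `neck_min_run_nm` are neck
#' candidates, and a neck counts only if bead runs exist on both sides of it
#' along its path. Necks longer than `moas_max_neck_length_um` still count
#' but are flagged. A single-node profile yields one bead (if its radius
#' passes the bead criterion) and no necks.
#'
#' @param profile a [skeleton_profile()].
#' @param th [classification_thresholds()].
#' @return list with `n_beads`, `n_necks`, `segments` (data.frame of runs
#'   with path id, arclength and radius range) and `flags`.
#' @export
detect_beads_and_necks <- function(profile, th = classification_thresholds()) {
  stopifnot(inherits(profile, "skeleton_profile"))
  r_all <- profile$radius_nm
  nodes <- profile$nodes
  flags <- character(0)

  if (nrow(nodes) == 1L) {
    nb <- if (r_all[1] >= th$bead_min_radius_nm) 1L else 0L
    return(list(n_beads = nb, n_necks = 0L,
                segments = data.frame(path = integer(), kind = character(),
                                      start = integer(), end = integer(),
                                      arclength_nm = numeric(),
                                      min_radius_nm = numeric(),
                                      max_radius_nm = numeric()),
                flags = "single_node"))
  }

  seen <- rep(FALSE, nrow(nodes))
  segs <- list()
  n_beads <- 0L
  n_necks <- 0L
  for (pi in seq_along(profile$paths)) {
    p <- profile$paths[[pi]]
    # secondary paths terminate on a node of an earlier path; drop shared
    # nodes so junctions are not double counted
    keep <- !seen[p]
    seen[p] <- TRUE
    p <- p[keep]
    if (length(p) < 1L) next
    r <- r_all[p]
    pos <- nodes[p, , drop = FALSE]
    steps <- c(0, sqrt(rowSums(diff(pos)^2)))
    arc <- cumsum(steps)
    run_len <- function(run) arc[run$end] - arc[run$start]

    beads <- runs_of(r >= th$bead_min_radius_nm)
    necks <- runs_of(r <= th$neck_max_radius_nm)
    if (nrow(necks)) {
      ok <- logical(nrow(necks))
      long <- logical(nrow(necks))
      for (k in seq_len(nrow(necks))) {
        len <- run_len(necks[k, ])
        if (len < th$neck_min_run_nm) next
        before <- any(beads$end < necks$start[k])
        after <- any(beads$start > necks$end[k])
        ok[k] <- before && after
        long[k] <- ok[k] && len > th$moas_max_neck_length_um * 1000
      }
      if (any(long)) flags <- c(flags, "neck_run_exceeds_max_length")
      necks <- necks[ok, , drop = FALSE]
    }
    n_beads <- n_beads + nrow(beads)
    n_necks <- n_necks + nrow(necks)
    mk <- function(df, kind) {
      if (!nrow(df)) return(NULL)
      data.frame(path = pi, kind = kind, start = df$start, end = df$end,
                 arclength_nm = vapply(seq_len(nrow(df)),
                                       function(k) run_len(df[k, ]), numeric(1)),
                 min_radius_nm = vapply(seq_len(nrow(df)),
                                        function(k) min(r[df$start[k]:df$end[k]]),
                                        numeric(1)),
                 max_radius_nm = vapply(seq_len(nrow(df)),
                                        function(k) max(r[df$start[k]:df$end[k]]),
                                        numeric(1)))
    }
    segs <- c(segs, list(mk(beads, "bead"), mk(necks, "neck")))
  }
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(segs))
    segs <- data.frame(path = integer(), kind = character(), start = integer(),
                       end = integer(), arclength_nm = numeric(),
                       min_radius_nm = numeric(), max_radius_nm = numeric())
  list(n_beads = n_beads, n_necks = n_necks, segments = segs, flags = flags)
}

#' Classify one mitochondrion into Type I-IV
#'
#' Decision order: (1) structural MOAS test from the skeleton radius profile
#' (at least `moas_min_beads` beads joined by at least one qualifying neck)
#' assigns Type IV regardless of length; otherwise the object is classified
#' by its length: Type I up to `type1_max_length_um` (closed upper bound),
#' Type II up to but excluding `type2_max_length_um`, Type III at
#' `type2_max_length_um` ("5 um or longer") and beyond.
#'
#' @param rec one row of [measure_objects()] for the object.
#' @param profile the object's [skeleton_profile()].
#' @param th [classification_thresholds()].
#' @return data.frame row: `object_id`, `type`, `n_beads`, `n_necks`,
#'   `decisive_rule`, `flags`.
#' @export
classify_mitochondrion <- function(rec, profile,
                                   th = classification_thresholds()) {
  det <- detect_beads_and_necks(profile, th)
  len <- rec$length_um
  if (det$n_beads >= th$moas_min_beads && det$n_necks >= 1L) {
    type <- "IV"
    rule <- sprintf("%d beads / %d necks (MOAS)", det$n_beads, det$n_necks)
  } else if (len <= th$type1_max_length_um) {
    type <- "I"
    rule <- sprintf("length %.3f um <= %.2f um", len, th$type1_max_length_um)
  } else if (len < th$type2_max_length_um) {
    type <- "II"
    rule <- sprintf("length %.3f um in (%.2f, %.2f) um", len,
                    th$type1_max_length_um, th$type2_max_length_um)
  } else {
    type <- "III"
    rule <- sprintf("length %.3f um >= %.2f um", len, th$type2_max_length_um)
  }
  data.frame(object_id = rec$object_id, type = type, n_beads = det$n_beads,
             n_necks = det$n_necks, decisive_rule = rule,
             flags = paste(det$flags, collapse = ";"))
}

#' Classify every mitochondrion in a label volume
#'
#' Extracts objects (boundary exclusion on), measures them, builds skeleton
#' profiles and assigns each object a type; returns per-object calls and the
#' per-type composition (counts and fractions of the classified population).
#'
#' @param vol a mitochondria [label_volume()].
#' @param th [classification_thresholds()].
#' @param smooth surface-mesh smoothing passes for the morphometry table.
#' @return list with `calls` (per-object data.frame), `composition` (one row
#'   per type I-IV with `count` and `fraction`), `records` (morphometry
#'   table) and `preset` (the active threshold preset).
#' @export
classify_population <- function(vol, th = classification_thresholds(),
                                smooth = 1L) {
  stopifnot(inherits(vol, "label_volume"))
  objs <- extract_objects(vol, exclude_boundary = TRUE)
  types <- c("I", "II", "III", "IV")
  if (!length(objs)) {
    return(list(calls = data.frame(object_id = integer(), type = character(),
                                   n_beads = integer(), n_necks = integer(),
                                   decisive_rule = character(),
                                   flags = character()),
                composition = data.frame(type = types, count = 0L,
                                         fraction = NA_real_),
                records = measure_objects(list()), preset = th$preset))
  }
  records <- measure_objects(objs, smooth = smooth)
  calls <- do.call(rbind, lapply(seq_along(objs), function(i) {
    classify_mitochondrion(records[i, ], skeleton_profile(objs[[i]]), th)
  }))
  counts <- vapply(types, function(t) sum(calls$type == t), integer(1))
  composition <- data.frame(type = types, count = counts,
                            fraction = counts / nrow(calls))
  list(calls = calls, composition = composition, records = records,
       preset = th$preset)
}
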