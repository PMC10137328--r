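#' Run the full pipeline and write a report bundle
#'
#' Extracts and measures all mitochondria (boundary exclusion on),
#' classifies them, detects MERCS against the ER volume when one is given,
#' and writes a deterministic report directory: morphometry, classification,
#' composition, contacts, coverage and pooled-statistics CSVs plus a JSON
#' manifest recording counts, active thresholds/preset, contact parameters
#' and seed. With no ER volume the contact sections are marked absent in the
#' manifest and the returned status is `"partial"`.
#'
#' @param out_dir output directory (created if needed).
#' @param mito mitochondria [label_volume()].
#' @param er optional co-registered ER [label_volume()].
#' @param th [classification_thresholds()].
#' @param params [contact_params()].
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param smooth surface-mesh smoothing passes.
#' @return Invisibly, a list with `status` (`"complete"` or `"partial"`),
#'   `manifest` and the output file paths.
#' @export
build_report <- function(out_dir, mito, er = NULL,
                         th = classification_thresholds(),
                         params = contact_params(), seed = NULL,
                         smooth = 1L) {
  stopifnot(inherits(mito, "label_volume"))
  if (!is.null(er) && !is_coregistered(mito, er))
    stop("mito and er volumes are not co-registered")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cp <- classify_population(mito, th, smooth = smooth)
  objs <- extract_objects(mito, exclude_boundary = TRUE)

  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(cp$records, "morphometry.csv")
  wr(cp$calls, "classification.csv")
  wr(cp$composition, "composition.csv")

  sections <- list(morphometry = TRUE, classification = TRUE,
                   contacts = !is.null(er))
  contacts_all <- NULL
  coverage_all <- NULL
  pooled <- NULL
  if (!is.null(er)) {
    contacts_all <- do.call(rbind, lapply(seq_along(objs), function(i) {
      detect_contacts(objs[[i]], er, params, smooth = smooth)
    }))
    coverage_all <- do.call(rbind, lapply(seq_along(objs), function(i) {
      rec <- cp$records[cp$records$object_id == objs[[i]]$id, ]
      mercs_coverage(rec, contacts_all[contacts_all$mito_id == objs[[i]]$id, , drop = FALSE])
    }))
    pooled <- mercs_by_type(cp$calls, coverage_all)
    wr(contacts_all, "contacts.csv")
    wr(coverage_all, "coverage.csv")
    wr(pooled, "pooled_stats.csv")
  }

  manifest <- list(
    package = "mitomorph",
    seed = seed,
    n_mitochondria = nrow(cp$calls),
    n_excluded_boundary = attr(objs, "n_excluded"),
    composition = setNames(as.list(cp$composition$count), cp$composition$type),
    thresholds = unclass(th),
    contact_params = if (is.null(er)) NULL else unclass(params),
    contact_volume_definition = if (is.null(er)) NULL else
      "ER-side: volume of ER voxels whose boundary lies within max_gap_nm of the mitochondrion surface",
    sections = sections,
    spacing_nm = mito$spacing
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths[["manifest.json"]] <- mp

  invisible(list(status = if (is.null(er)) "partial" else "complete",
                 manifest = manifest, paths = paths))
}
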