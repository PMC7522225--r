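# Disk interchange: TIFF heatmaps, cohort manifest and colorbar tables.

#' Write a colorbar definition as CSV
#'
#' @param cbar a [colorbar()].
#' @param path output CSV path (columns value, R, G, B; the first row with
#'   `value = NA` is the background colour).
#' @export
write_colorbar <- function(cbar, path) {
  stopifnot(inherits(cbar, "colorbar"))
  df <- data.frame(value = c(NA, cbar$values),
                   R = c(cbar$background[1], cbar$colors[, 1]),
                   G = c(cbar$background[2], cbar$colors[, 2]),
                   B = c(cbar$background[3], cbar$colors[, 3]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a colorbar definition from CSV
#'
#' @param path CSV written by [write_colorbar()].
#' @return a [colorbar()].
#' @export
read_colorbar <- function(path) {
  df <- read.csv(path)
  bg_row <- is.na(df$value)
  bg <- if (any(bg_row)) as.integer(df[which(bg_row)[1], c("R", "G", "B")])
        else c(0L, 0L, 0L)
  df <- df[!bg_row, , drop = FALSE]
  colorbar(df$value, as.matrix(df[, c("R", "G", "B")]), background = bg)
}

#' Write a synthetic cohort to disk
#'
#' Renders every subject/layer map through the colorbar to an 8-bit RGB
#' TIFF, and writes a manifest CSV (subject, group, laterality, layer,
#' file, fovea centre, pixel spacing) plus the colorbar CSV.
#'
#' @param cohort list of subjects from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param cbar a [colorbar()]; must span the cohort's value range.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, cbar = default_colorbar()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (subj in cohort) {
    for (ly in names(subj$maps)) {
      map <- subj$maps[[ly]]
      fname <- sprintf("%s_%s.tif", subj$subject_id, ly)
      img <- render_heatmap(map, cbar)
      tiff::writeTIFF(img / 255, file.path(dir, fname),
                      bits.per.sample = 8L)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, group = subj$group,
        laterality = subj$laterality, layer = ly, file = fname,
        center_row = map$center[1], center_col = map$center[2],
        pixel_spacing = map$pixel_spacing, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_colorbar(cbar, file.path(dir, "colorbar.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort back from disk
#'
#' Decodes every manifest entry's TIFF through the colorbar into a
#' [thickness_map()] and reassembles the per-subject structure.
#'
#' @param dir directory written by [write_cohort()] (or a manifest path).
#' @param cbar optional [colorbar()]; defaults to the directory's
#'   `colorbar.csv`.
#' @return list of subjects shaped like [generate_cohort()] output.
#' @export
read_cohort <- function(dir, cbar = NULL) {
  manifest_path <- if (grepl("\\.csv$", dir)) dir else
    file.path(dir, "manifest.csv")
  base <- dirname(manifest_path)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (is.null(cbar)) cbar <- read_colorbar(file.path(base, "colorbar.csv"))
  subjects <- list()
  for (id in unique(manifest$subject_id)) {
    rows <- manifest[manifest$subject_id == id, , drop = FALSE]
    maps <- list()
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      img <- tiff::readTIFF(file.path(base, r$file))
      maps[[r$layer]] <- decode_thickness_image(
        img, cbar, pixel_spacing = r$pixel_spacing,
        center = c(r$center_row, r$center_col), laterality = r$laterality)
    }
    subjects[[length(subjects) + 1L]] <- structure(
      list(subject_id = id, group = rows$group[1],
           laterality = rows$laterality[1], maps = maps),
      class = "synthetic_subject")
  }
  subjects
}

#' Write per-subject pixel samples as a long CSV
#'
#' @param samples list of [pixel_sample()]s.
#' @param path output CSV (columns subject_id, layer, value).
#' @export
write_pixel_samples <- function(samples, path) {
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(subject_id = s$subject_id, layer = s$layer,
               value = s$values, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read pixel samples from a long CSV
#'
#' @param path CSV written by [write_pixel_samples()].
#' @return list of [pixel_sample()]s, one per (subject, layer).
#' @export
read_pixel_samples <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[, c("subject_id", "layer")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$subject_id == keys$subject_id[i] & df$layer == keys$layer[i]
    pixel_sample(df$value[sel], subject_id = keys$subject_id[i],
                 layer = keys$layer[i])
  })
}
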