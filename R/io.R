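# NIfTI / CSV ingestion and serialization. Columns of every
# subject-by-voxel matrix follow the mask's TRUE voxels in R's native
# array order (first index fastest), which is also the NIfTI on-disk
# order — patterns written here re-ingest bit-exactly.

#' Read a binary NIfTI mask
#'
#' @param path NIfTI file whose nonzero voxels define the analysis mask.
#' @return Logical array of the mask grid.
#' @export
load_mask <- function(path) {
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (!all(arr %in% c(0, 1))) {
    stop("mask is not binary: ", path, call. = FALSE)
  }
  m <- arr > 0
  if (!any(m)) stop("mask selects no voxels: ", path, call. = FALSE)
  m
}

#' Load a cohort from a subject manifest and a mask
#'
#' The manifest is a comma-separated table with header columns `id`,
#' `path`, `group` and optionally `age`. Every volume must share the
#' mask's grid. Rows are ingested in manifest order.
#'
#' @param manifest Path to the manifest CSV (or a data.frame).
#' @param mask Path to the binary mask volume (or a logical array).
#' @return An [image_matrix]; when the manifest has an `age` column the
#'   ages are attached as `attr(, "ages")`.
#' @export
load_cohort <- function(manifest, mask) {
  tab <- if (is.data.frame(manifest)) manifest else
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "path", "group")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- if (is.character(mask)) load_mask(mask) else mask
  vals <- matrix(NA_real_, nrow(tab), sum(m))
  for (i in seq_len(nrow(tab))) {
    f <- tab$path[i]
    if (!file.exists(f)) stop("missing image file: ", f, call. = FALSE)
    arr <- as.array(RNifti::readNifti(f))
    if (!identical(dim(arr), dim(m))) {
      stop("grid mismatch with mask: ", f, call. = FALSE)
    }
    v <- arr[m]
    if (!all(is.finite(v))) {
      stop("non-finite voxel inside mask: ", f, call. = FALSE)
    }
    vals[i, ] <- v
  }
  im <- image_matrix(vals, tab$id, tab$group,
                     mask_ref = if (is.character(mask)) mask else
                       "in-memory mask")
  if ("age" %in% names(tab)) attr(im, "ages") <- as.numeric(tab$age)
  im
}

# place a masked voxel vector back on the mask grid (unmasked voxels 0)
unmask <- function(vec, mask) {
  arr <- array(0, dim(mask))
  arr[mask] <- vec
  arr
}

#' Write a pattern as NIfTI plus a key-value sidecar
#'
#' @param pattern A [readout_pattern].
#' @param mask Logical mask array (or path) defining the column order.
#' @param path Output NIfTI path; metadata goes to `<path>.txt`.
#' @return `path`, invisibly.
#' @export
save_pattern_nifti <- function(pattern, mask, path) {
  stopifnot(inherits(pattern, "readout_pattern"))
  m <- if (is.character(mask)) load_mask(mask) else mask
  if (sum(m) != length(pattern$b)) {
    stop("mask voxel count does not match pattern length", call. = FALSE)
  }
  RNifti::writeNifti(RNifti::asNifti(unmask(pattern$b, m)), path)
  meta <- c(n_patients = pattern$n_patients,
            n_controls = pattern$n_controls,
            se2 = pattern$se2, nce = pattern$nce, norm2 = pattern$norm2)
  writeLines(sprintf("%s: %.17g", names(meta), meta),
             paste0(path, ".txt"))
  invisible(path)
}

#' Read a pattern written by [save_pattern_nifti()]
#'
#' @param path NIfTI path (sidecar expected at `<path>.txt`).
#' @param mask Logical mask array (or path).
#' @return A `readout_pattern`.
#' @export
load_pattern_nifti <- function(path, mask) {
  m <- if (is.character(mask)) load_mask(mask) else mask
  arr <- as.array(RNifti::readNifti(path))
  if (!identical(dim(arr), dim(m))) {
    stop("pattern grid does not match mask", call. = FALSE)
  }
  kv <- read_keyvalue(paste0(path, ".txt"))
  structure(
    list(b = arr[m], n_patients = as.integer(kv[["n_patients"]]),
         n_controls = as.integer(kv[["n_controls"]]),
         se2 = kv[["se2"]], nce = kv[["nce"]], norm2 = kv[["norm2"]],
         degenerate = kv[["nce"]] >= 1),
    class = "readout_pattern"
  )
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, ":\\s*")
  vals <- as.numeric(vapply(parts, `[`, "", 2))
  names(vals) <- vapply(parts, `[`, "", 1)
  as.list(vals)
}

#' Write an NPV basis as a 4-D NIfTI plus eigenvalue table
#'
#' Components are stacked along the 4th dimension; the centering vector
#' is written as `<prefix>_center.nii.gz` and the eigenvalues (with the
#' source-sample size) as `<prefix>_eigenvalues.csv`.
#'
#' @param basis An [fast_pca()] basis.
#' @param mask Logical mask array (or path).
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
save_basis_nifti <- function(basis, mask, prefix) {
  stopifnot(inherits(basis, "npv_basis"))
  m <- if (is.character(mask)) load_mask(mask) else mask
  k <- nrow(basis$components)
  flat <- array(0, c(prod(dim(m)), k))
  for (i in seq_len(k)) flat[as.vector(m), i] <- basis$components[i, ]
  arr <- array(flat, c(dim(m), k))
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(unmask(basis$center, m)),
                     paste0(prefix, "_center.nii.gz"))
  utils::write.csv(
    data.frame(component = seq_len(k), eigenvalue = basis$eigenvalues,
               n_source = basis$n_source),
    paste0(prefix, "_eigenvalues.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read an NPV basis written by [save_basis_nifti()]
#'
#' @param prefix Path prefix used at save time.
#' @param mask Logical mask array (or path).
#' @return An `npv_basis`.
#' @export
load_basis_nifti <- function(prefix, mask) {
  m <- if (is.character(mask)) load_mask(mask) else mask
  arr <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  k <- dim(arr)[4]
  flat <- array(arr, c(prod(dim(m)), k))
  comp <- t(flat[as.vector(m), , drop = FALSE])
  center <- as.array(RNifti::readNifti(paste0(prefix,
                                              "_center.nii.gz")))[m]
  tab <- utils::read.csv(paste0(prefix, "_eigenvalues.csv"))
  structure(
    list(components = comp, eigenvalues = tab$eigenvalue,
         center = center, n_source = tab$n_source[1]),
    class = "npv_basis"
  )
}

#' Write a cohort as per-subject NIfTI volumes plus a manifest
#'
#' @param images An [image_matrix].
#' @param mask Logical mask array.
#' @param dir Output directory (created if needed).
#' @param ages Optional per-subject ages for the manifest.
#' @return Path of the written manifest CSV.
#' @export
save_cohort_nifti <- function(images, mask, dir, ages = NULL) {
  stopifnot(inherits(images, "image_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dim(mask))),
                     mask_path)
  paths <- character(nrow(images$values))
  for (i in seq_len(nrow(images$values))) {
    paths[i] <- file.path(dir, paste0(images$subject_ids[i], ".nii.gz"))
    RNifti::writeNifti(
      RNifti::asNifti(unmask(images$values[i, ], mask)), paths[i])
  }
  tab <- data.frame(id = images$subject_ids, path = paths,
                    group = images$labels)
  if (!is.null(ages)) tab$age <- ages
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(tab, manifest, row.names = FALSE)
  manifest
}

#' Filter a manifest to loosely age-matched subjects
#'
#' Keeps subjects whose age lies in the closed interval
#' `[min(reference_ages) - window, max(reference_ages) + window]` — the
#' usual way a multi-center PCA control sample is matched to the age
#' range of the read-out cohort.
#'
#' @param manifest data.frame with an `age` column.
#' @param reference_ages Ages of the read-out cohort.
#' @param window Margin in years (default 5).
#' @return The filtered data.frame.
#' @export
age_match_filter <- function(manifest, reference_ages, window = 5) {
  if (!"age" %in% names(manifest)) {
    stop("manifest has no 'age' column", call. = FALSE)
  }
  lo <- min(reference_ages) - window
  hi <- max(reference_ages) + window
  manifest[manifest$age >= lo & manifest$age <= hi, , drop = FALSE]
}

#' Write a plain-text provenance record next to CLI outputs
#'
#' @param path Output file.
#' @param config Named list of run parameters.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config) {
  lines <- c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("codenoise_version: %s",
            as.character(utils::packageVersion("codenoise"))),
    sprintf("r_version: %s", R.version.string),
    vapply(names(config), function(k) {
      sprintf("%s: %s", k, paste(format(config[[k]]), collapse = " "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
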