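#' Subject-by-voxel image matrix
#'
#' Container for a set of image-derived scalar maps: one row per subject,
#' one column per masked voxel. This is the common currency of the package;
#' read-out patterns, NPV bases and denoising all operate on the masked,
#' flattened column space that an `image_matrix` defines.
#'
#' @param values Numeric matrix, rows = subjects, columns = masked voxels.
#'   All entries must be finite.
#' @param subject_ids Character vector of unique subject identifiers
#'   (defaults to `s1, s2, ...`).
#' @param labels Per-subject group tag, each one of `"patient"`,
#'   `"control"` or `"unlabeled"`.
#' @param mask_ref Optional identifier linking the columns to voxel
#'   coordinates (e.g. the path or digest of the mask volume).
#'
#' @return An object of class `image_matrix`: a list with fields `values`,
#'   `subject_ids`, `labels`, `mask_ref`.
#' @export
image_matrix <- function(values, subject_ids = NULL, labels = NULL,
                         mask_ref = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("image_matrix: non-finite entries in 'values'", call. = FALSE)
  }
  n <- nrow(values)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n || anyDuplicated(subject_ids)) {
    stop("'subject_ids' must be unique and match the number of rows",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("unlabeled", n)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("'labels' must have one entry per subject", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("patient", "control", "unlabeled"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values, subject_ids = subject_ids, labels = labels,
         mask_ref = mask_ref),
    class = "image_matrix"
  )
}

#' @export
print.image_matrix <- function(x, ...) {
  tab <- table(factor(x$labels, c("patient", "control", "unlabeled")))
  cat(sprintf("image_matrix: %d subjects x %d voxels\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  patients: %d  controls: %d  unlabeled: %d\n",
              tab[["patient"]], tab[["control"]], tab[["unlabeled"]]))
  if (!is.na(x$mask_ref)) cat("  mask_ref:", x$mask_ref, "\n")
  invisible(x)
}

#' @export
dim.image_matrix <- function(x) dim(x$values)

#' Subset an image matrix by subject
#'
#' @param im An [image_matrix].
#' @param i Row index (integer, logical, or subject-id character vector).
#' @return An [image_matrix] with the selected subjects, columns unchanged.
#' @export
im_subset <- function(im, i) {
  stopifnot(inherits(im, "image_matrix"))
  if (is.character(i)) i <- match(i, im$subject_ids)
  if (anyNA(i)) stop("unknown subject id in subset", call. = FALSE)
  image_matrix(im$values[i, , drop = FALSE], im$subject_ids[i],
               im$labels[i], im$mask_ref)
}

#' Extract one labeled group from an image matrix
#'
#' @param im An [image_matrix].
#' @param label One of `"patient"`, `"control"`, `"unlabeled"`.
#' @return An [image_matrix] restricted to subjects carrying `label`.
#' @export
im_group <- function(im, label = c("patient", "control", "unlabeled")) {
  label <- match.arg(label)
  im_subset(im, which(im$labels == label))
}

# shared guard: two matrices must live in the same (masked) column space
check_same_space <- function(a, b, what = "inputs") {
  ja <- if (inherits(a, "image_matrix")) ncol(a$values) else length(a)
  jb <- if (inherits(b, "image_matrix")) ncol(b$values) else length(b)
  if (ja != jb) {
    stop(sprintf("%s do not share a column space (%d vs %d voxels)",
                 what, ja, jb), call. = FALSE)
  }
  invisible(TRUE)
}

# unbiased per-voxel variances (divisor N - 1), centered to avoid cancellation
col_vars <- function(x) {
  n <- nrow(x)
  xc <- x - rep(colMeans(x), each = n)
  colSums(xc^2) / (n - 1)
}
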