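#' Lateral-radiograph landmark set for one disc level
#'
#' Holds the 2-D landmarks from which the disc height index is computed:
#' up to three disc-height chords (anterior, middle, posterior) and the
#' endpoint pairs of the two adjacent vertebral bodies along their long axes.
#' Coordinates may be in mm or pixels; the index is a ratio, so any single
#' consistent unit works.
#'
#' @param disc_chords list of 1-3 point pairs, each a 2x2 numeric matrix
#'   (rows are points, columns x/y).
#' @param cranial_vertebra,caudal_vertebra 2x2 matrices: endpoints of each
#'   adjacent vertebral body's long axis.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(disc_chords, cranial_vertebra, caudal_vertebra) {
  as_pair <- function(m, what) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(2L, 2L)) || any(!is.finite(m))) {
      stop_input("invalid landmark: %s must be a finite 2x2 point pair", what)
    }
    if (all(m[1, ] == m[2, ])) {
      stop_input("invalid landmark: %s endpoints coincide", what)
    }
    m
  }
  if (!is.list(disc_chords) || length(disc_chords) < 1L ||
      length(disc_chords) > 3L) {
    stop_input("`disc_chords` must be a list of 1-3 point pairs")
  }
  chords <- lapply(seq_along(disc_chords), function(i) {
    as_pair(disc_chords[[i]], sprintf("disc chord %d", i))
  })
  structure(
    list(disc_chords = chords,
         cranial_vertebra = as_pair(cranial_vertebra, "cranial vertebra"),
         caudal_vertebra = as_pair(caudal_vertebra, "caudal vertebra")),
    class = "landmark_set"
  )
}

#' Disc height index from radiographic landmarks
#'
#' Disc height is the mean length of the supplied disc-height chords
#' (anterior/middle/posterior when all three are given); the denominator is
#' the mean of the two adjacent vertebral body lengths. The index is the
#' ratio, a dimensionless quantity invariant to rigid motion and global
#' scaling of the landmark set.
#'
#' @param landmarks a [landmark_set()].
#' @return Single numeric DHI value.
#' @export
disc_height_index <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  chord_len <- vapply(landmarks$disc_chords,
                      function(m) euclid_len(m[1, ], m[2, ]), numeric(1))
  v1 <- euclid_len(landmarks$cranial_vertebra[1, ],
                   landmarks$cranial_vertebra[2, ])
  v2 <- euclid_len(landmarks$caudal_vertebra[1, ],
                   landmarks$caudal_vertebra[2, ])
  if (v1 <= 0 || v2 <= 0) {
    stop_input("invalid landmark: zero-length vertebra segment")
  }
  mean(chord_len) / mean(c(v1, v2))
}

#' Normalize a longitudinal DHI series to its pre-operative value
#'
#' Each disc's DHI trajectory is expressed relative to its own pre-operative
#' value, which therefore maps to exactly 1. The operation is idempotent and
#' unit-free (pixel and mm series normalize identically).
#'
#' @param dhi numeric DHI values, one per timepoint.
#' @param timepoints ordered timepoint labels, same length as `dhi`.
#' @param preop label (or index) of the pre-operative timepoint; defaults to
#'   the first timepoint.
#' @return data.frame with columns `timepoint`, `dhi`, `dhi_normalized`.
#' @export
normalize_dhi <- function(dhi, timepoints = seq_along(dhi),
                          preop = timepoints[1]) {
  if (length(dhi) != length(timepoints)) {
    stop_input("`dhi` and `timepoints` must have the same length")
  }
  idx <- match(preop, timepoints)
  if (is.na(idx)) {
    stop_input("normalization error: pre-operative timepoint %s not found",
               format(preop))
  }
  ref <- dhi[idx]
  if (!is.finite(ref) || ref <= 0) {
    stop_input("normalization error: pre-operative DHI missing or non-positive")
  }
  data.frame(timepoint = timepoints, dhi = dhi, dhi_normalized = dhi / ref,
             stringsAsFactors = FALSE)
}
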