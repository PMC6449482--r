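# Rigid-body superposition (Kabsch, SVD with reflection guard) and the
# universal P-loop channel residue nomenclature: residues in the pore domain
# are labelled by repeat (1-4), segment code (k = S4-S5 linker, o = S5,
# p = P1 helix, i = S6) and an index within the segment, so that symmetric
# positions in the four repeats share labels across channels.

.SEGMENT_CODES <- c("k", "o", "p", "i")

#' Construct a universal residue label
#' @param repeat_ repeat domain, 1-4.
#' @param segment_code one of \code{"k"}, \code{"o"}, \code{"p"}, \code{"i"}.
#' @param index position within the segment.
#' @return a \code{universal_label}.
#' @export
universal_label <- function(repeat_, segment_code, index) {
  stopifnot(repeat_ %in% 1:4, segment_code %in% .SEGMENT_CODES)
  structure(list(repeat_ = as.integer(repeat_), segment_code = segment_code,
                 index = as.integer(index)), class = "universal_label")
}

#' @export
format.universal_label <- function(x, ...)
  sprintf("%d%s%d", x$repeat_, x$segment_code, x$index)

#' @export
print.universal_label <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Load a label map
#'
#' A label map assigns, per (repeat, segment code), the residue number of the
#' segment's index-origin position, so that
#' \code{resid = anchor + index - index_origin}.  The packaged default map
#' (\code{label_map()} with no arguments) covers the alpha-1 subunit of the
#' human cardiac L-type calcium channel; anchors without a direct literature
#' attestation are marked provisional in the data file.
#'
#' @param path TSV with columns \code{repeat}, \code{segment}, \code{index_origin},
#'   \code{index_max}, \code{anchor_resid}, \code{provisional}.
#' @return a \code{label_map}: data.frame of anchors.
#' @export
label_map <- function(path = system.file("extdata", "label_map_cav12.tsv",
                                         package = "channelmcm")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("repeat.", "segment", "index_origin", "index_max", "anchor_resid")
  names(df)[names(df) == "repeat."] <- "repeat_"
  stopifnot(all(c("repeat_", "segment", "index_origin", "index_max",
                  "anchor_resid") %in% names(df)))
  structure(df, class = c("label_map", "data.frame"))
}

#' Build a label map in code (used for toy systems)
#' @param entries data.frame with columns \code{repeat_}, \code{segment},
#'   \code{index_origin}, \code{index_max}, \code{anchor_resid} and optionally
#'   \code{segment_id} (the molecular-system segment each labelled range
#'   lives in).
#' @export
as_label_map <- function(entries) {
  structure(as.data.frame(entries, stringsAsFactors = FALSE),
            class = c("label_map", "data.frame"))
}

.map_row <- function(map, repeat_, segment_code) {
  i <- which(map$repeat_ == repeat_ & map$segment == segment_code)
  if (length(i) != 1)
    stop("label map has no entry for repeat ", repeat_, " segment ",
         segment_code)
  map[i, ]
}

#' Convert a universal label to a residue number (and back)
#'
#' @param label a \code{universal_label}.
#' @param map a \code{label_map}.
#' @return \code{label_to_resid}: integer residue number.
#' @export
label_to_resid <- function(label, map) {
  row <- .map_row(map, label$repeat_, label$segment_code)
  if (label$index < row$index_origin || label$index > row$index_max)
    stop("label index ", label$index, " outside declared range [",
         row$index_origin, ", ", row$index_max, "] for segment ",
         label$repeat_, label$segment_code)
  as.integer(row$anchor_resid + label$index - row$index_origin)
}

#' @rdname label_to_resid
#' @param resid residue number.
#' @return \code{resid_to_label}: a \code{universal_label}, or an error if
#'   the residue is not inside any declared range.
#' @export
resid_to_label <- function(resid, map) {
  for (i in seq_len(nrow(map))) {
    row <- map[i, ]
    idx <- resid - row$anchor_resid + row$index_origin
    if (idx >= row$index_origin && idx <= row$index_max)
      return(universal_label(row$repeat_, row$segment, idx))
  }
  stop("residue ", resid, " is not inside any labelled segment")
}

#' Select atoms by universal labels
#'
#' @param system a \code{molecular_system}.
#' @param repeat_set integer vector of repeats.
#' @param segment_code one of \code{"k"}, \code{"o"}, \code{"p"}, \code{"i"}.
#' @param index_range integer vector (e.g. \code{3:11}).
#' @param map a \code{label_map}; if it has a \code{segment_id} column, atoms
#'   are looked up in that system segment, otherwise across all segments by
#'   residue number.
#' @param atom atom name, default alpha carbon.
#' @return integer atom indices ordered by (repeat, index).
#' @export
select_by_labels <- function(system, repeat_set, segment_code, index_range,
                             map, atom = "CA") {
  out <- integer(0)
  misses <- character(0)
  for (rp in sort(unique(repeat_set))) {
    row <- .map_row(map, rp, segment_code)
    for (ix in index_range) {
      if (ix < row$index_origin || ix > row$index_max) {
        misses <- c(misses, sprintf("%d%s%d", rp, segment_code, ix))
        next
      }
      resid <- row$anchor_resid + ix - row$index_origin
      segid <- if ("segment_id" %in% names(map)) row$segment_id else
        unique(system$atoms$segment[system$atoms$resid == resid])
      idx <- which(system$atoms$segment %in% segid &
                     system$atoms$resid == resid & system$atoms$name == atom)
      if (length(idx) != 1) {
        misses <- c(misses, sprintf("%d%s%d", rp, segment_code, ix))
      } else {
        out <- c(out, idx)
      }
    }
  }
  if (length(misses))
    stop("unresolvable labels: ", paste(misses, collapse = ", "))
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMS deviation of
#' paired coordinates, optionally restricted to a selection, and reports
#' per-atom deviations of the full coordinate sets after the fit.
#'
#' @param mobile,reference n x 3 coordinate matrices (paired rows).
#' @param selection integer rows used to compute the fit (default all).
#' @return a \code{superposition}: list with \code{rotation} (3 x 3, proper),
#'   \code{translation}, \code{rmsd} (over the selection), \code{deviations}
#'   (per atom, full set) and \code{transformed} (mobile after the fit).
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  stopifnot(nrow(mobile) == nrow(reference))
  if (length(selection) < 3) stop("superposition needs at least 3 atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity guard
  if (min(svd(A0)$d) < 1e-8 * max(svd(A0)$d, 1))
    stop("selection is degenerate (collinear or coincident atoms)")
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  transformed <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, `+`)
  dev <- sqrt(rowSums((transformed - reference)^2))
  structure(list(rotation = R, translation = cb - as.vector(R %*% ca),
                 rmsd = sqrt(mean(dev[selection]^2)), deviations = dev,
                 transformed = transformed, selection = selection),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over %d atoms (det R = %+.0f)\n",
              x$rmsd, length(x$selection), det(x$rotation)))
  invisible(x)
}

#' RMSD between two coordinate sets without fitting
#' @param a,b n x 3 matrices.
#' @param selection optional row subset.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = seq_len(nrow(a))) {
  sqrt(mean(rowSums((a[selection, , drop = FALSE] -
                       b[selection, , drop = FALSE])^2)))
}
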