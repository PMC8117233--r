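#' Scotoma specification
#'
#' Gaze-contingent visual field defect geometry.  `size_deg` is read as a
#' diameter (common clinical usage): a central defect occludes the closed
#' disk of radius `size_deg/2` around the fovea, a peripheral defect
#' occludes everything outside that disk, and a hemifield defect occludes
#' the right half of retinotopic space (`r_x > 0`, strictly).
#'
#' @param kind One of `"none"`, `"central"`, `"peripheral"`, `"hemifield"`.
#' @param size_deg Defect diameter in degrees, used by `central` and as the
#'   spared-hole diameter by `peripheral` (default 10); ignored otherwise.
#' @return An object of class `scotoma_spec`.
#' @export
scotoma_spec <- function(kind = c("none", "central", "peripheral", "hemifield"),
                         size_deg = 10) {
  if (length(kind) != 1 || !kind %in% c("none", "central", "peripheral",
                                        "hemifield")) {
    stop("invalid specification: unknown scotoma kind", call. = FALSE)
  }
  if (kind %in% c("central", "peripheral") &&
      (!is.numeric(size_deg) || size_deg <= 0)) {
    stop("invalid specification: `size_deg` must be positive", call. = FALSE)
  }
  structure(list(kind = kind, size_deg = size_deg), class = "scotoma_spec")
}

#' Ordered defect classes
#'
#' Canonical ordering of the four defect classes, used for shape labels and
#' tie-breaking (lowest index wins).
#' @return Character vector of length 4.
#' @export
scotoma_kinds <- function() c("none", "central", "peripheral", "hemifield")

.scotoma_kind_code <- function(kind) {
  match(kind, scotoma_kinds()) - 1L
}

#' Is the stimulus occluded?
#'
#' Occlusion depends only on the retinotopic position of the stimulus,
#' `r = s - p` (stimulus relative to the fovea): central occludes for
#' `||r|| <= size/2` (closed disk), peripheral for `||r|| > size/2`,
#' hemifield for `r_x > 0`, none never.
#'
#' @param s_x,s_y Stimulus position, degrees.  Vectorized.
#' @param p_x,p_y Gaze position, degrees.
#' @param spec A [scotoma_spec()].
#' @return Logical vector.
#' @export
is_occluded <- function(s_x, s_y, p_x, p_y, spec) {
  stopifnot(inherits(spec, "scotoma_spec"))
  if (any(!is.finite(c(s_x, s_y, p_x, p_y)))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  rx <- s_x - p_x
  ry <- s_y - p_y
  switch(spec$kind,
    none = rep(FALSE, length(rx)),
    central = sqrt(rx^2 + ry^2) <= spec$size_deg / 2,
    peripheral = sqrt(rx^2 + ry^2) > spec$size_deg / 2,
    hemifield = rx > 0
  )
}

#' Ground-truth occlusion labels for a tracking record
#'
#' Recomputes the per-sample a-priori occlusion flag from the stored gaze
#' and stimulus traces and the record's scotoma specification.  This is the
#' binary series used both for ground-truth map reconstruction and as the
#' point-wise training output of the network.
#'
#' @param record A `tracking_record`.
#' @return Integer vector of 0/1 flags, one per sample.
#' @export
ground_truth_labels <- function(record) {
  stopifnot(inherits(record, "tracking_record"))
  ns <- lengths(record[c("s_x", "s_y", "p_x", "p_y")])
  if (length(unique(ns)) != 1) {
    stop("malformed record: gaze and stimulus traces differ in length",
         call. = FALSE)
  }
  as.integer(is_occluded(record$s_x, record$s_y, record$p_x, record$p_y,
                         record$scotoma))
}
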