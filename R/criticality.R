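#' Area-weighted percentile threshold of a surface field
#'
#' The threshold is the smallest value v such that the summed area of
#' elements with value <= v reaches pct % of the total area, with linear
#' interpolation between adjacent distinct values of the weighted CDF. With
#' equal areas this reduces to an ordinary percentile. Critical-value
#' thresholds in lumen analyses conventionally use the 33rd percentile for
#' "low is bad" indices (TAWSS) and the 66th for "high is bad" indices
#' (OSI, transWSS, TSVI).
#'
#' @param values finite numeric vector (per node or per cell).
#' @param weights positive element areas, same length (equal if omitted).
#' @param pct percentile in (0, 100).
#' @return scalar threshold in descriptor units.
#' @export
percentile_threshold <- function(values, weights = NULL, pct) {
  if (!length(values)) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) stop("length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  if (pct <= 0 || pct >= 100) stop("pct must be in (0, 100)")
  # aggregate tied values so the CDF steps at each distinct value
  v <- sort(unique(values))
  cw <- unname(cumsum(rowsum(weights, group = match(values, v))[, 1]))
  target <- pct / 100 * cw[length(cw)]
  k <- which(cw >= target - 1e-12 * cw[length(cw)])[1]
  if (k == 1L) return(v[1L])
  # linear interpolation across the CDF step between adjacent distinct values
  frac <- (target - cw[k - 1L]) / (cw[k] - cw[k - 1L])
  v[k - 1L] + frac * (v[k] - v[k - 1L])
}

#' Critical-area mask from a threshold rule
#'
#' Strict inequality: an element is critical when value < threshold for a
#' "low" rule (e.g. TAWSS) or value > threshold for a "high" rule (OSI,
#' transWSS, TSVI). Equality is non-critical.
#'
#' @param values numeric vector per element.
#' @param threshold finite scalar.
#' @param direction "low" or "high".
#' @return object of class `critical_mask`: logical `mask` plus the
#'   generating `threshold` and `direction`.
#' @export
critical_mask <- function(values, threshold, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  m <- if (direction == "low") values < threshold else values > threshold
  structure(list(mask = m, threshold = threshold, direction = direction),
            class = "critical_mask")
}

#' Percentage of ROI area flagged critical
#'
#' @param mask a [critical_mask()] (or plain logical vector).
#' @param roi integer element indices of the ROI (all elements if NULL).
#' @param areas element areas, same length as the mask.
#' @return percentage in `[0, 100]`.
#' @export
roi_area_fraction <- function(mask, roi = NULL, areas) {
  m <- if (inherits(mask, "critical_mask")) mask$mask else mask
  if (length(m) != length(areas)) stop("mask/areas length mismatch")
  if (is.null(roi)) roi <- seq_along(m)
  if (!length(roi)) stop("empty ROI")
  if (min(roi) < 1L || max(roi) > length(m)) stop("ROI indices out of range")
  100 * sum(areas[roi][m[roi]]) / sum(areas[roi])
}

#' Area-weighted Dice similarity index between two critical masks
#'
#' 100 x 2 area(A and B) / (area(A) + area(B)); returns 100 when both masks
#' are empty (identical by convention). Used to compare critical-area maps,
#' e.g. across boundary-condition strategies.
#'
#' @param maskA,maskB [critical_mask()] objects or logical vectors on the
#'   same surface.
#' @param areas element areas.
#' @return percentage in `[0, 100]`.
#' @export
similarity_index <- function(maskA, maskB, areas) {
  a <- if (inherits(maskA, "critical_mask")) maskA$mask else maskA
  b <- if (inherits(maskB, "critical_mask")) maskB$mask else maskB
  if (length(a) != length(b) || length(a) != length(areas)) {
    stop("masks and areas must live on the same surface")
  }
  denom <- sum(areas[a]) + sum(areas[b])
  if (denom == 0) return(100)
  100 * 2 * sum(areas[a & b]) / denom
}

#' Default threshold rules for the four wall indices
#'
#' TAWSS low at the 33rd percentile; OSI, transWSS and TSVI high at the 66th.
#'
#' @return data.frame with columns `descriptor`, `direction`, `pct`.
#' @export
default_threshold_rules <- function() {
  data.frame(descriptor = c("tawss", "osi", "transwss", "tsvi"),
             direction = c("low", "high", "high", "high"),
             pct = c(33, 66, 66, 66),
             stringsAsFactors = FALSE)
}

#' Criticality report: thresholds and per-ROI critical-area fractions
#'
#' For each rule, computes the area-weighted percentile threshold over the
#' whole-domain distribution of the descriptor, masks critical elements, and
#' reports the percentage of critical area in each ROI (the machine twin of a
#' per-index / per-ROI critical-area table).
#'
#' @param fields named list of per-element numeric vectors (all on the same
#'   support, node- or cell-based — tag it via `support`).
#' @param areas element areas matching the fields.
#' @param rules data.frame as [default_threshold_rules()]; rules whose
#'   descriptor is absent from `fields` raise an error.
#' @param rois named list of integer element-index vectors; a "whole" ROI
#'   covering every element is always prepended.
#' @param support "cell" or "node", recorded in the report.
#' @return object of class `criticality_report`: `table` (descriptor,
#'   direction, pct, threshold, roi, pct_area), `masks` (named list of
#'   [critical_mask()]), `support`.
#' @export
criticality_report <- function(fields, areas, rules = default_threshold_rules(),
                               rois = NULL, support = "cell") {
  missing_f <- setdiff(rules$descriptor, names(fields))
  if (length(missing_f)) {
    stop("descriptor(s) missing from fields: ", paste(missing_f, collapse = ", "))
  }
  all_rois <- c(list(whole = seq_along(areas)), rois)
  if (anyDuplicated(names(all_rois))) stop("duplicate ROI names")
  rows <- list()
  masks <- list()
  for (i in seq_len(nrow(rules))) {
    d <- rules$descriptor[i]
    vals <- fields[[d]]
    if (length(vals) != length(areas)) {
      stop("field '", d, "' does not match the element count")
    }
    thr <- percentile_threshold(vals, areas, rules$pct[i])
    mk <- critical_mask(vals, thr, rules$direction[i])
    masks[[d]] <- mk
    for (rn in names(all_rois)) {
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = d, direction = rules$direction[i], pct = rules$pct[i],
        threshold = thr, roi = rn,
        pct_area = roi_area_fraction(mk, all_rois[[rn]], areas),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), masks = masks,
                 support = support),
            class = "criticality_report")
}

#' @export
print.criticality_report <- function(x, ...) {
  cat("criticality_report (", x$support, "-based):\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
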