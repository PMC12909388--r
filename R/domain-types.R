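#' Image calibration
#'
#' Bundles the physical scale of the micrograph and the elapsed time between
#' the two fluorochrome administrations. Every physical quantity downstream
#' (rates in um/day, thicknesses in um) enters through this object; pixel
#' geometry itself is unit-free.
#'
#' @param um_per_px physical scale in micrometres per pixel (> 0).
#' @param delta_days days elapsed between the first (alizarin) and second
#'   (oxytetracycline) label administration (> 0). Labelling protocols in this
#'   model use 12-14 days; values outside 1-60 trigger a warning but are
#'   accepted.
#' @return An object of class `calibration`.
#' @examples
#' calibration(um_per_px = 0.5, delta_days = 13)
#' @export
calibration <- function(um_per_px, delta_days) {
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1,
            is.numeric(delta_days), length(delta_days) == 1)
  if (!is.finite(um_per_px) || um_per_px <= 0) {
    stop("um_per_px must be a finite positive number", call. = FALSE)
  }
  if (!is.finite(delta_days) || delta_days <= 0) {
    stop("delta_days must be a finite positive number", call. = FALSE)
  }
  if (delta_days < 1 || delta_days > 60) {
    warning(sprintf("delta_days = %g is outside the expected 1-60 day range",
                    delta_days))
  }
  structure(list(um_per_px = um_per_px, delta_days = delta_days),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g um/px, %g days between labels\n",
              x$um_per_px, x$delta_days))
  invisible(x)
}

DISK_LEVELS <- c("Dd", "D1", "D2", "D3", "D4", "D5", "P1", "P2")
VERTEBRA_LEVELS <- paste0("V", 1:6)

#' Anatomical level labels within a multi-tether construct
#'
#' Disk spaces are labelled D1 (most distal instrumented) through D5 (most
#' proximal instrumented), with Dd the distal-adjacent and P1, P2 the
#' proximal-adjacent uninstrumented spaces. Vertebrae are V1 (most distal) to
#' V6 (most proximal).
#'
#' @param code level code, one of `Dd, D1..D5, P1, P2` (disks) or `V1..V6`
#'   (vertebrae).
#' @return An object of class `level_label` with fields `kind`
#'   (`"disk"`/`"vertebra"`) and `code`.
#' @examples
#' level_label("D5")
#' is_instrumented(level_label("Dd"))
#' @export
level_label <- function(code) {
  stopifnot(is.character(code), length(code) == 1)
  if (code %in% DISK_LEVELS) {
    kind <- "disk"
  } else if (code %in% VERTEBRA_LEVELS) {
    kind <- "vertebra"
  } else {
    stop(sprintf("unknown level code '%s' (expected %s)", code,
                 paste(c(DISK_LEVELS, VERTEBRA_LEVELS), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(kind = kind, code = code), class = "level_label")
}

#' @rdname level_label
#' @param level a `level_label` or bare level code.
#' @export
is_instrumented <- function(level) {
  code <- if (inherits(level, "level_label")) level$code else level_label(level)$code
  code %in% c(paste0("D", 1:5), VERTEBRA_LEVELS)
}

#' @export
print.level_label <- function(x, ...) {
  cat(sprintf("<level> %s (%s%s)\n", x$code, x$kind,
              if (is_instrumented(x)) ", instrumented" else ""))
  invisible(x)
}

#' Which physis of a vertebra, relative to the disk it abuts
#'
#' @param side `"proximal"` or `"distal"`.
#' @return validated side string.
#' @export
physis_side <- function(side) {
  match.arg(side, c("proximal", "distal"))
}
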