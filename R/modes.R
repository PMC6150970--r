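#' Canonical travel-mode labels
#'
#' The five travel modes recognised by the classifier, in canonical order.
#' The order is fixed: confusion matrices are laid out in it and prediction
#' ties are broken towards the earlier mode.
#'
#' @return Character vector of the five mode names.
#' @export
mode_levels <- function() {
  c("walk", "cycle", "vehicle", "train", "stationary")
}

#' Coerce a vector to a travel-mode factor
#'
#' @param x character or factor vector of mode names.
#' @return Factor with levels `mode_levels()`.
#' @export
as_mode <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% mode_levels())
  if (any(bad)) {
    stop("unknown mode label(s): ", paste(unique(x[bad]), collapse = ", "),
         "; valid modes are: ", paste(mode_levels(), collapse = ", "))
  }
  factor(x, levels = mode_levels())
}

# questionnaire category -> training category
.reported_mode_map <- c(
  "walk"                      = "walk",
  "jog"                       = "walk",
  "cycle"                     = "cycle",
  "bicycle"                   = "cycle",
  "car/van driver"            = "vehicle",
  "car/van passenger"         = "vehicle",
  "taxi"                      = "vehicle",
  "motorcycle/moped/scooter"  = "vehicle",
  "bus/minibus/coach"         = "vehicle",
  "train (overground)"        = "train",
  "train (over ground)"       = "train",
  "underground"               = "train",
  "tube"                      = "train",
  "stationary"                = "stationary"
)

#' Re-categorise a reported commute mode into a training category
#'
#' Collapses the questionnaire travel categories into the five modes the
#' classifier is trained on: walk stays walk; bicycle becomes cycle;
#' car/van driver or passenger, taxi, motorcycle and bus/minibus/coach all
#' become vehicle; overground train and underground both become train.
#' Matching is case-insensitive and ignores surrounding whitespace.
#'
#' @param reported character vector of reported commute modes.
#' @return Factor of travel modes with levels `mode_levels()`.
#' @export
#' @examples
#' map_reported_mode(c("Underground", "Bus/minibus/coach", "Walk"))
map_reported_mode <- function(reported) {
  key <- tolower(trimws(as.character(reported)))
  out <- .reported_mode_map[key]
  if (anyNA(out)) {
    stop("unknown reported mode(s): ",
         paste(unique(reported[is.na(out)]), collapse = ", "),
         "; valid inputs: ", paste(names(.reported_mode_map), collapse = ", "))
  }
  as_mode(unname(out))
}
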