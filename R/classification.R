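MORPH_CLASSES <- c("filament", "rod", "punctum", "swollen")

#' Classification rules for the four morphology classes
#'
#' The two published thresholds are the 11 µm filament extension and the
#' 0.6 µm punctum/swollen radius boundary. "Round" is operationalized as
#' circularity >= 0.8 and aspect ratio <= 2; the swollen class additionally
#' requires solidity >= 0.9 as a shape surrogate for intensity compactness.
#' The radius of a round object is its equivalent-circle radius
#' \code{r_eq = sqrt(A/pi)} by default; half the minimum Feret diameter can
#' be selected instead.
#'
#' @param filament_min_extension_um Extension above which an object is a
#'   filament (strict inequality); default 11 µm.
#' @param round_radius_um Radius separating puncta (below, strict) from
#'   swollen (at or above); default 0.6 µm.
#' @param round_min_circularity Minimum circularity of a "round" object.
#' @param round_max_ar Maximum aspect ratio of a "round" object.
#' @param swollen_min_solidity Minimum solidity of a swollen object.
#' @param radius_feature Which radius the 0.6 µm rule uses:
#'   \code{"equivalent"} (r_eq) or \code{"feret"} (MLE/2).
#' @return An object of class \code{classification_rules}.
#' @export
classification_rules <- function(filament_min_extension_um = 11,
                                 round_radius_um = 0.6,
                                 round_min_circularity = 0.8,
                                 round_max_ar = 2.0,
                                 swollen_min_solidity = 0.9,
                                 radius_feature = c("equivalent", "feret")) {
  radius_feature <- match.arg(radius_feature)
  vals <- c(filament_min_extension_um, round_radius_um,
            round_min_circularity, round_max_ar, swollen_min_solidity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all classification thresholds must be finite and > 0")
  if (round_min_circularity > 1)
    stop("`round_min_circularity` must be <= 1")
  structure(list(filament_min_extension_um = filament_min_extension_um,
                 round_radius_um = round_radius_um,
                 round_min_circularity = round_min_circularity,
                 round_max_ar = round_max_ar,
                 swollen_min_solidity = swollen_min_solidity,
                 radius_feature = radius_feature),
            class = "classification_rules")
}

#' Classify one object from its features
#'
#' Rules are evaluated sequentially in a fixed order and the first match
#' wins, so every valid feature vector receives exactly one class:
#' \enumerate{
#'   \item punctum: round (C >= round_min_circularity and
#'     AR <= round_max_ar) and radius < round_radius_um;
#'   \item swollen: round, solidity >= swollen_min_solidity and
#'     radius >= round_radius_um;
#'   \item filament: extension E > filament_min_extension_um;
#'   \item rod: everything else (the intermediate phenotype between
#'     fragmented puncta and networked filaments).
#' }
#'
#' @param f A one-row data frame (or list) of object features with fields
#'   \code{C}, \code{AR}, \code{S}, \code{E} and \code{r_eq} (and
#'   \code{MLE} when \code{radius_feature = "feret"}).
#' @param rules A \code{\link{classification_rules}} object.
#' @return A single character value, one of \code{"filament"},
#'   \code{"rod"}, \code{"punctum"}, \code{"swollen"}.
#' @export
classify_object <- function(f, rules = classification_rules()) {
  f <- as.list(f)
  keep <- intersect(c("C", "AR", "S", "E", "r_eq", "MLE"), names(f))
  classify_features(as.data.frame(f[keep]), rules)[1L]
}

#' Classify a table of object features
#'
#' Vectorized, deterministic and order-preserving version of
#' \code{\link{classify_object}}.
#'
#' @param features Data frame with columns \code{C}, \code{AR}, \code{S},
#'   \code{E}, \code{r_eq} (and \code{MLE} if used as radius source).
#' @param rules A \code{\link{classification_rules}} object.
#' @return Character vector of classes, one per row of \code{features}.
#' @export
classify_features <- function(features, rules = classification_rules()) {
  if (nrow(features) == 0L) return(character(0L))
  r <- if (rules$radius_feature == "equivalent") features$r_eq
       else features$MLE / 2
  round_ <- features$C >= rules$round_min_circularity &
            features$AR <= rules$round_max_ar
  cls <- rep("rod", nrow(features))
  cls[features$E > rules$filament_min_extension_um] <- "filament"
  swo <- round_ & features$S >= rules$swollen_min_solidity &
         r >= rules$round_radius_um
  cls[swo] <- "swollen"
  cls[round_ & r < rules$round_radius_um] <- "punctum"
  cls
}

#' Classify every object of a cell
#'
#' @param objects List of segmented objects (for their labels); may be
#'   \code{NULL} to use the labels in \code{features}.
#' @param features Feature table from \code{\link{measure_objects}}.
#' @param rules A \code{\link{classification_rules}} object.
#' @return \code{features} with a \code{class} column appended; row order
#'   is preserved.
#' @export
classify_cell <- function(objects = NULL, features,
                          rules = classification_rules()) {
  features$class <- classify_features(features, rules)
  features
}
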