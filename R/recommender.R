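#' Structured fracture descriptor
#'
#' The facts about a detected fracture that the treatment rule engine
#' consumes: which long bone, which diaphyseal third, whether the fracture is
#' impacted, open-fracture status with its Gustilo-Anderson grade, skeletal
#' maturity and neurovascular status, plus free-form morphology tags
#' (displacement, comminution, complexity) that are carried through for audit
#' but do not alter the treatment mapping.
#'
#' @param bone One of `"femur"`, `"leg"` (fibula/tibia), `"humerus"`,
#'   `"forearm"` (ulna/radius).
#' @param third One of `"proximal"`, `"mid"`, `"distal"`.
#' @param impacted Logical; impacted fractures are treated by immobilization.
#' @param open_fracture Logical.
#' @param gustilo_grade `"I"`, `"II"`, `"IIIA"`, `"IIIB"`, `"IIIC"`, or
#'   `"none"` for closed fractures (required iff closed).
#' @param skeletally_mature Logical; the rule set covers adults only.
#' @param neurovascular_intact Logical; distal neurovascular status.
#' @param tags Optional character vector of morphology labels.
#' @return A `fracture_descriptor` object.
#' @export
fracture_descriptor <- function(bone = c("femur", "leg", "humerus", "forearm"),
                                third = c("proximal", "mid", "distal"),
                                impacted = FALSE,
                                open_fracture = FALSE,
                                gustilo_grade = "none",
                                skeletally_mature = TRUE,
                                neurovascular_intact = TRUE,
                                tags = character()) {
  bone <- match.arg(bone)
  third <- match.arg(third)
  gustilo_grade <- match.arg(gustilo_grade,
                             c("none", "I", "II", "IIIA", "IIIB", "IIIC"))
  if (open_fracture && gustilo_grade == "none")
    stop("open fractures require a Gustilo-Anderson grade", call. = FALSE)
  if (!open_fracture && gustilo_grade != "none")
    stop("closed fractures must have gustilo_grade = \"none\"", call. = FALSE)
  structure(list(bone = bone, third = third, impacted = isTRUE(impacted),
                 open_fracture = isTRUE(open_fracture),
                 gustilo_grade = gustilo_grade,
                 skeletally_mature = isTRUE(skeletally_mature),
                 neurovascular_intact = isTRUE(neurovascular_intact),
                 tags = as.character(tags)),
            class = "fracture_descriptor")
}

#' Diaphyseal third of a fracture box
#'
#' Partitions the bone's axial (vertical image) extent into three equal
#' intervals and selects the one containing the box's axial centre. The
#' boundaries are half-open: fractions in `[0, 1/3)` are proximal,
#' `[1/3, 2/3)` mid, `[2/3, 1]` distal. `orientation` states which image end
#' is the anatomically proximal end, since radiograph orientation is not
#' guaranteed.
#'
#' @param box Numeric `(x_min, y_min, x_max, y_max)`.
#' @param bone_extent Numeric `(y_start, y_end)` of the bone along the image
#'   y axis.
#' @param orientation `"low_y"` (proximal end at the top of the image,
#'   default) or `"high_y"`.
#' @return `"proximal"`, `"mid"`, or `"distal"`.
#' @examples
#' locate_third(c(10, 40, 30, 60), c(0, 300))  # proximal
#' @export
locate_third <- function(box, bone_extent, orientation = c("low_y", "high_y")) {
  orientation <- match.arg(orientation)
  stopifnot(length(bone_extent) == 2L, bone_extent[2] > bone_extent[1])
  yc <- (box[2] + box[4]) / 2
  if (yc < bone_extent[1] || yc > bone_extent[2])
    stop("box centre lies outside the bone extent", call. = FALSE)
  f <- (yc - bone_extent[1]) / (bone_extent[2] - bone_extent[1])
  if (orientation == "high_y") f <- 1 - f
  if (f < 1 / 3) "proximal" else if (f < 2 / 3) "mid" else "distal"
}

#' Eligibility gate for the treatment rule engine
#'
#' The rule set is defined under three assumptions: patients are skeletally
#' mature, distal neurovascular status is intact (limb salvage possible), and
#' open fractures are at most Gustilo-Anderson grade IIIA. Descriptors
#' violating any assumption are rejected with a reason; rejection is a return
#' value, not an error.
#'
#' @param d A [fracture_descriptor()].
#' @return List with `eligible` (logical) and, when ineligible, `reason`.
#' @export
check_eligibility <- function(d) {
  stopifnot(inherits(d, "fracture_descriptor"))
  if (!d$skeletally_mature)
    return(list(eligible = FALSE, reason = "skeletally immature patient"))
  if (!d$neurovascular_intact)
    return(list(eligible = FALSE, reason = "distal neurovascular status compromised"))
  if (d$gustilo_grade %in% c("IIIB", "IIIC"))
    return(list(eligible = FALSE,
                reason = sprintf("open fracture beyond Gustilo IIIA (grade %s)",
                                 d$gustilo_grade)))
  list(eligible = TRUE)
}

# (bone, third) -> treatment lookup. Impacted fractures short-circuit to
# Casting before this table is consulted.
.treatment_table <- list(
  femur   = c(proximal = "ORIF FAD",   mid = "ORIF IMN", distal = "ORIF Plate"),
  leg     = c(proximal = "ORIF Plate", mid = "ORIF IMN", distal = "ORIF Plate"),
  humerus = c(proximal = "ORIF Plate", mid = "ORIF IMN", distal = "ORIF Plate"),
  forearm = c(proximal = "ORIF Plate", mid = "ORIF Plate", distal = "ORIF Plate"))

.treatment_classes <- c("ORIF FAD" = "I", "ORIF IMN" = "II",
                        "ORIF Plate" = "III", "Casting" = "IV")

#' Treatment recommendation for a fracture descriptor
#'
#' Deterministic hierarchical rule engine mapping an eligible descriptor to
#' one of four treatment classes: I ORIF with a fixed-angle device, II ORIF
#' with an intramedullary nail, III ORIF with plate osteosynthesis, IV
#' casting. Rule order: (1) any impacted fracture is immobilized (class IV);
#' (2) otherwise the (bone, diaphyseal third) pair selects the surgical
#' method — proximal femur takes a fixed-angle device, mid-shaft femur, leg
#' and humerus take an intramedullary nail, and all remaining locations
#' (including the whole forearm) take a plate. Each decision records the
#' ordered list of rules that fired, for audit. These labels benchmark
#' automated annotation; they are not clinical advice.
#'
#' @param d A [fracture_descriptor()]; must pass [check_eligibility()].
#' @return A `recommendation` object: `treatment_class` (`"I"`..`"IV"`),
#'   `treatment` (method name), `fired_rules` (character, ordered).
#' @examples
#' recommend(fracture_descriptor("femur", "mid"))     # II, ORIF IMN
#' recommend(fracture_descriptor("humerus", "distal", impacted = TRUE))
#' @export
recommend <- function(d) {
  elig <- check_eligibility(d)
  if (!elig$eligible)
    stop(sprintf("ineligible descriptor: %s", elig$reason), call. = FALSE)
  fired <- c("eligibility: passed (mature, neurovascular intact, Gustilo <= IIIA)")
  if (d$impacted) {
    treatment <- "Casting"
    fired <- c(fired, "impacted fracture -> immobilization (Casting)")
  } else {
    treatment <- .treatment_table[[d$bone]][[d$third]]
    fired <- c(fired,
               sprintf("location rule: %s / %s third -> %s", d$bone, d$third,
                       treatment))
  }
  if (length(d$tags))
    fired <- c(fired, sprintf("morphology tags noted (no rule): %s",
                              paste(d$tags, collapse = ", ")))
  structure(list(treatment_class = .treatment_classes[[treatment]],
                 treatment = treatment, fired_rules = fired),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("Class %s: %s\n", x$treatment_class, x$treatment))
  cat(paste0("  - ", x$fired_rules, collapse = "\n"), "\n")
  invisible(x)
}
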