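#' Ellipsoid volume from three diameters
#'
#' Fruit and endocarp volumes are estimated as ellipsoids from their length,
#' width and height (all diameters, in mm): V = (4/3) pi (L/2)(W/2)(H/2).
#'
#' @param length,width,height Positive diameters in mm (vectorised).
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(2, 2, 2) # sphere of radius 1
#' @export
ellipsoid_volume <- function(length, width, height) {
  if (any(c(length, width, height) <= 0, na.rm = TRUE)) {
    stop("all dimensions must be > 0", call. = FALSE)
  }
  (4 / 3) * pi * (length / 2) * (width / 2) * (height / 2)
}

#' Pulp volume fraction of a fruit
#'
#' The pulp is the part of the fruit not occupied by the endocarp:
#' (V_fruit - V_endocarp) / V_fruit.
#'
#' @param fruit_vol,endocarp_vol Volumes in the same units, with
#'   `0 < endocarp_vol <= fruit_vol`.
#' @return Fraction in `[0, 1)`.
#' @export
pulp_volume_fraction <- function(fruit_vol, endocarp_vol) {
  if (any(endocarp_vol <= 0, na.rm = TRUE)) stop("endocarp volume must be > 0", call. = FALSE)
  if (any(endocarp_vol > fruit_vol, na.rm = TRUE)) {
    stop("endocarp volume exceeds fruit volume (inconsistent measurement)", call. = FALSE)
  }
  (fruit_vol - endocarp_vol) / fruit_vol
}

#' Endocarp flatness (width / height)
#'
#' Cross-sectional shape of the endocarp: 1 means round, values above 1 mean
#' flattened (wider than high).
#'
#' @param width,height Positive cross-sectional diameters in mm.
#' @return The width/height ratio.
#' @export
endocarp_flatness <- function(width, height) {
  if (any(c(width, height) <= 0, na.rm = TRUE)) stop("dimensions must be > 0", call. = FALSE)
  width / height
}

#' Protein content from Kjeldahl nitrogen
#'
#' The conventional conversion protein = 6.25 x N, with N a mass fraction.
#'
#' @param N Nitrogen as a fraction of fresh pulp mass (>= 0).
#' @return Protein fraction of fresh mass.
#' @export
protein_from_nitrogen <- function(N) {
  if (any(N < 0, na.rm = TRUE)) stop("nitrogen fraction must be >= 0", call. = FALSE)
  6.25 * N
}

#' Carbohydrate content by difference
#'
#' Carbohydrates are the remainder of fresh pulp mass after moisture, lipid,
#' protein and ash are accounted for.
#'
#' @param moisture,lipid,protein,ash Fractions of fresh mass, each in
#'   `[0, 1]`, summing to at most 1.
#' @return Carbohydrate fraction of fresh mass.
#' @export
carbohydrate_by_difference <- function(moisture, lipid, protein, ash) {
  parts <- cbind(moisture, lipid, protein, ash)
  if (any(parts < 0 | parts > 1, na.rm = TRUE)) {
    stop("all components must be fractions in [0, 1]", call. = FALSE)
  }
  tot <- moisture + lipid + protein + ash
  if (any(tot > 1 + 1e-9, na.rm = TRUE)) {
    stop("components sum to more than 1 of fresh mass", call. = FALSE)
  }
  1 - tot
}

#' Convert a fresh-mass fraction to a dry-mass fraction
#'
#' @param component Fraction of fresh mass (must not exceed `1 - moisture`).
#' @param moisture Moisture fraction of fresh mass, in `[0, 1)`.
#' @return The component as a fraction of dry mass.
#' @examples
#' fresh_to_dry(0.10, 0.50) # 0.2 of dry mass
#' @export
fresh_to_dry <- function(component, moisture) {
  if (any(moisture >= 1 | moisture < 0, na.rm = TRUE)) {
    stop("moisture must be in [0, 1)", call. = FALSE)
  }
  if (any(component > 1 - moisture + 1e-9, na.rm = TRUE)) {
    stop("component exceeds the dry fraction 1 - moisture", call. = FALSE)
  }
  component / (1 - moisture)
}

#' Derive per-fruit analysis traits from raw measurements
#'
#' Takes one row per fruit with raw dimensions and composition and adds the
#' derived variables used downstream: fruit and endocarp ellipsoid volumes,
#' pulp volume fraction, endocarp flatness, protein (from `nitrogen` if a
#' `protein` column is absent), and carbohydrate by difference. All
#' composition columns are fresh-mass fractions.
#'
#' @param fruits A data frame with columns `fruit_length`, `fruit_width`,
#'   `fruit_height`, `endocarp_length`, `endocarp_width`, `endocarp_height`,
#'   `moisture`, `lipid`, `ash`, and either `protein` or `nitrogen`.
#' @return The input as a tibble with columns `fruit_volume`,
#'   `endocarp_volume`, `pulp_volume`, `flatness`, `protein`, `carbohydrate`
#'   added.
#' @export
derive_fruit_traits <- function(fruits) {
  fruits <- tibble::as_tibble(fruits)
  need <- c("fruit_length", "fruit_width", "fruit_height",
            "endocarp_length", "endocarp_width", "endocarp_height",
            "moisture", "lipid", "ash")
  miss <- setdiff(need, names(fruits))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"protein" %in% names(fruits)) {
    if (!"nitrogen" %in% names(fruits)) {
      stop("need a 'protein' or 'nitrogen' column", call. = FALSE)
    }
    fruits$protein <- protein_from_nitrogen(fruits$nitrogen)
  }
  dplyr::mutate(
    fruits,
    fruit_volume = ellipsoid_volume(.data$fruit_length, .data$fruit_width, .data$fruit_height),
    endocarp_volume = ellipsoid_volume(.data$endocarp_length, .data$endocarp_width, .data$endocarp_height),
    pulp_volume = pulp_volume_fraction(.data$fruit_volume, .data$endocarp_volume),
    flatness = endocarp_flatness(.data$endocarp_width, .data$endocarp_height),
    carbohydrate = carbohydrate_by_difference(.data$moisture, .data$lipid, .data$protein, .data$ash)
  )
}

#' Species-level trait means
#'
#' Averages per-fruit derived traits within species. Derivations are applied
#' per fruit first and averaged second.
#'
#' @param fruits A data frame of per-fruit traits with a species column.
#' @param species Name of the species column (default `"species"`).
#' @return A tibble with one row per species and the mean of every numeric
#'   column.
#' @export
species_trait_means <- function(fruits, species = "species") {
  fruits <- tibble::as_tibble(fruits)
  if (!species %in% names(fruits)) stop("no column '", species, "'", call. = FALSE)
  fruits[[species]] <- normalize_taxa(fruits[[species]])
  dplyr::summarise(
    dplyr::group_by(fruits, dplyr::across(dplyr::all_of(species))),
    dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}
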