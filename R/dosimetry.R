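## Environmental dosimetry: convert survey-meter exposure rates (uR/h) to
## annual absorbed dose (mGy/y) with an occupancy-weighted indoor/outdoor
## combination, and stratify subjects into the study's dose groups.

#' Conversion factor from uR/h to mGy/y
#'
#' `0.8763 x 24 h x 365 d x 1e-5`, the roentgen-to-gray air-kerma
#' conversion accumulated over a year, conventionally quoted as 0.0767.
#'
#' @return the conversion factor (numeric scalar).
#' @export
dose_conversion_factor <- function() 0.8763 * 24 * 365 * 1e-5

#' Annual absorbed dose from indoor/outdoor exposure rates
#'
#' Occupancy-weighted mean exposure rate converted to mGy/y:
#' `(indoor * f + outdoor * (1 - f)) * 0.0767` with `f` the indoor
#' occupancy fraction. Internal dose from ingested or inhaled
#' radionuclides is out of scope.
#'
#' @param indoor_rate,outdoor_rate exposure rates in uR/h (>= 0),
#'   vectorised.
#' @param occupancy_indoor indoor occupancy fraction in `[0, 1]`.
#' @param conversion_factor uR/h-to-mGy/y factor; defaults to the rounded
#'   conventional value 0.0767.
#' @return annual absorbed dose in mGy/y.
#' @export
annual_dose <- function(indoor_rate, outdoor_rate, occupancy_indoor,
                        conversion_factor = 0.0767) {
  stop_if(any(indoor_rate < 0) || any(outdoor_rate < 0),
          "exposure rates must be >= 0")
  stop_if(any(occupancy_indoor < 0 | occupancy_indoor > 1),
          "'occupancy_indoor' must be in [0, 1]")
  (indoor_rate * occupancy_indoor +
     outdoor_rate * (1 - occupancy_indoor)) * conversion_factor
}

#' Assign dose groups from annual absorbed dose
#'
#' Group I (normal-level natural radiation area) below 1.5 mGy/y; high-
#' level groups II (1.5-5.0], III (5.0-14.0] and IV (> 14.0). The printed
#' bounds 5.01 and 14.01 are treated as the continuous cuts 5.0 and 14.0
#' since doses are real-valued. Exactly 1.5 mGy/y is assigned to Group II
#' by default (`boundary_1.5 = "HLNRA"`); set `boundary_1.5 = "NLNRA"` to
#' keep it in Group I, since published definitions quote the boundary both
#' ways.
#'
#' @param dose annual dose in mGy/y (>= 0), vectorised.
#' @param boundary_1.5 which stratum owns exactly 1.5 mGy/y.
#' @return character vector of group labels I-IV.
#' @export
assign_group <- function(dose, boundary_1.5 = c("HLNRA", "NLNRA")) {
  boundary_1.5 <- match.arg(boundary_1.5)
  stop_if(any(!is.finite(dose)) || any(dose < 0),
          "'dose' must be finite and >= 0")
  in_I <- if (boundary_1.5 == "HLNRA") dose < 1.5 else dose <= 1.5
  ifelse(in_I, "I",
         ifelse(dose <= 5, "II",
                ifelse(dose <= 14, "III", "IV")))
}

#' Annotate a dosimetry table with annual dose and dose group
#'
#' @param dose_table data frame: subject, indoor_rate, outdoor_rate,
#'   occupancy_indoor (as produced by [sim_dosimetry()] or read from TSV).
#' @param conversion_factor see [annual_dose()].
#' @param boundary_1.5 see [assign_group()].
#' @return the table with annual_dose (mGy/y) and group columns appended.
#' @export
stratify_doses <- function(dose_table, conversion_factor = 0.0767,
                           boundary_1.5 = "HLNRA") {
  need <- c("subject", "indoor_rate", "outdoor_rate", "occupancy_indoor")
  stop_if(!all(need %in% names(dose_table)),
          "dose table must have columns: %s", paste(need, collapse = ", "))
  dose_table$annual_dose <- annual_dose(dose_table$indoor_rate,
                                        dose_table$outdoor_rate,
                                        dose_table$occupancy_indoor,
                                        conversion_factor)
  dose_table$group <- assign_group(dose_table$annual_dose,
                                   boundary_1.5 = boundary_1.5)
  dose_table
}
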