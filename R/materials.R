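#' Thermophysical properties of blood and the suspended nanoparticle species
#'
#' Built-in material table for the tri-hybrid suspension: the blood base fluid
#' and the three nanoparticle species (ferric oxide, zinc, gold). Columns are
#' the density `rho` (kg/m^3), thermal conductivity `k` (W/m K), specific heat
#' `cp` (J/kg K), thermal expansion coefficient `beta_T` (1/K, common scale
#' factor omitted -- only ratios to the base fluid enter the model) and the
#' `shape` tag that selects the viscosity/conductivity correlation set.
#'
#' The shape tags follow the coefficient sets used by the governing mixture
#' equations: Fe3O4 pairs with the spherical set, Zn with the cylindrical set
#' (13.5/904.4, Hamilton-Crosser factor 3.9) and Au with the platelet set
#' (37.1/612.6, factor 4.7). See the methods vignette for why the shape
#' *labels* of Zn and Au are sometimes quoted the other way around.
#'
#' @return A tibble with one row per material and columns
#'   `name`, `rho`, `k`, `cp`, `beta_T`, `shape`.
#' @export
#' @examples
#' thnf_materials()
thnf_materials <- function() {
  tibble::tibble(
    name   = c("blood", "Fe3O4", "Zn", "Au"),
    rho    = c(1053, 5200, 7140, 19300),
    k      = c(0.492, 6, 116, 318),
    cp     = c(3594, 670, 389, 129),
    beta_T = c(0.8, 1.3, 3.5, 1.41),
    shape  = c("base_fluid", "spherical", "cylindrical", "platelet")
  )
}

.thnf_shapes <- c("spherical", "cylindrical", "platelet")

#' Validate a material table
#'
#' Checks the structural invariants of a material table: required columns,
#' strictly positive properties, exactly one `base_fluid` row and known shape
#' tags for the particle rows.
#'
#' @param materials A data frame as returned by [thnf_materials()].
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_materials <- function(materials) {
  materials <- tibble::as_tibble(materials)
  needed <- c("name", "rho", "k", "cp", "beta_T", "shape")
  missing <- setdiff(needed, names(materials))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("material table is missing column(s): ", paste(missing, collapse = ", ")),
      class = "thnflow_materials_error"
    )
  }
  for (col in c("rho", "k", "cp", "beta_T")) {
    if (!is.numeric(materials[[col]]) || any(!is.finite(materials[[col]])) ||
        any(materials[[col]] <= 0)) {
      rlang::abort(
        paste0("material property '", col, "' must be finite and > 0"),
        class = "thnflow_materials_error"
      )
    }
  }
  if (sum(materials$shape == "base_fluid") != 1) {
    rlang::abort("material table needs exactly one base_fluid row",
      class = "thnflow_materials_error")
  }
  bad <- setdiff(materials$shape, c("base_fluid", .thnf_shapes))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("unknown shape tag(s): ", paste(bad, collapse = ", ")),
      class = "thnflow_materials_error"
    )
  }
  invisible(materials)
}

#' Read or write a material table as CSV
#'
#' Plain-CSV persistence for material tables with the column layout of
#' [thnf_materials()]. Numeric values survive a write/read cycle bit-exactly
#' (shortest round-trip decimal representation).
#'
#' @param path File path of the CSV.
#' @param materials A material table to write.
#' @return `read_materials()` returns the validated tibble;
#'   `write_materials()` returns `materials` invisibly.
#' @export
read_materials <- function(path) {
  materials <- readr::read_csv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      rho = readr::col_double(),
      k = readr::col_double(),
      cp = readr::col_double(),
      beta_T = readr::col_double(),
      shape = readr::col_character()
    )
  )
  validate_materials(materials)
  materials
}

#' @rdname read_materials
#' @export
write_materials <- function(materials, path) {
  validate_materials(materials)
  readr::write_csv(tibble::as_tibble(materials), path)
  invisible(materials)
}
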