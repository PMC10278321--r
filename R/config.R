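#' Read a needle/manometer/fluid catalog
#'
#' The catalog is a Debian-control-format (DCF) file of records separated
#' by blank lines.  Needle records carry `Name`, `Gauge`, `Length_mm` and
#' optionally `Inner_diameter_mm`, `Outer_diameter_mm`,
#' `Resistance_cm_s_per_ml`; a `manometer` record carries
#' `Bore_diameter_mm` and a `fluid` record `Density_g_per_ml` and
#' `Viscosity_mPa_s`.  All millimetre quantities are converted to the
#' canonical cm system here, once; viscosity is converted from mPa.s to
#' cmH2O.s.  The bundled bench catalog ships at
#' `system.file("extdata", "needles.dcf", package = "csfmanometry")`.
#'
#' @param path path to the DCF catalog.
#' @return a list with components `needles` (named list of
#'   [needle_spec()]), `manometer` (a [manometer_spec()] or `NULL`) and
#'   `fluid` (a [fluid_properties()], defaulted when absent).
#' @export
read_assembly_config <- function(path) {
  recs <- read.dcf(path)
  num <- function(row, field) {
    if (!field %in% colnames(recs)) return(NULL)
    v <- recs[row, field]
    if (is.na(v)) NULL else as.numeric(v)
  }
  needles <- list()
  manometer <- NULL
  fluid <- fluid_properties()
  for (i in seq_len(nrow(recs))) {
    kind <- recs[i, "Record"]
    if (kind == "needle") {
      nd <- needle_spec(
        name = recs[i, "Name"],
        gauge = if ("Gauge" %in% colnames(recs)) recs[i, "Gauge"] else NA,
        length = mm_to_cm(num(i, "Length_mm")),
        inner_diameter = if (!is.null(num(i, "Inner_diameter_mm")))
          mm_to_cm(num(i, "Inner_diameter_mm")) else NULL,
        outer_diameter = if (!is.null(num(i, "Outer_diameter_mm")))
          mm_to_cm(num(i, "Outer_diameter_mm")) else NULL,
        resistance = num(i, "Resistance_cm_s_per_ml"))
      needles[[nd$name]] <- nd
    } else if (kind == "manometer") {
      manometer <- manometer_spec(mm_to_cm(num(i, "Bore_diameter_mm")))
    } else if (kind == "fluid") {
      fluid <- fluid_properties(
        density = num(i, "Density_g_per_ml"),
        viscosity = viscosity_cmh2o_s(num(i, "Viscosity_mPa_s")))
    } else {
      stop("unknown catalog record type: ", kind, call. = FALSE)
    }
  }
  list(needles = needles, manometer = manometer, fluid = fluid)
}
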