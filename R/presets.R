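# Preset vegetation-index registry: 10 visible-band indices usable with
# both RGB and MS sensors, 11 indices requiring red-edge/near-infrared
# bands (MS only). Expressions are kept in canonical band variables so a
# preset evaluates directly on band bindings.

.PRESET_RGB <- list(
  BGI   = "b/g",
  BRI   = "b/r",
  CIVE  = "r*0.441-g*0.811+b*0.385+18.78745",
  EXG   = "(g*2-r-b)/(r+g+b)",
  EXR   = "(r*1.4-g)/(r+g+b)",
  # EE is defined as EXG + EXR; stored expanded over bands
  EE    = "(g*2-r-b)/(r+g+b)+(r*1.4-g)/(r+g+b)",
  NDI   = "(g-r)/(g+r)",
  RGBI  = "r/g",
  RGBVI = "(g*g-b*r)/(g*g+b*r)",
  VARI  = "(g-r)/(g+r-b)"
)

.PRESET_MS <- list(
  ARI    = "(1/g)-(1/re)",
  DVI    = "nir-r",
  GNDVI  = "(nir-g)/(nir+g)",
  MCARI1 = "1.2*(2.5*(nir-r)-1.3*(nir-g))",
  # as preset: no final division by 2 (a documented MSAVI_std variant has it)
  MSAVI  = "nir*2+1-sqrt((nir*2+1)^2-8*(nir-r))",
  MSR    = "(nir/r-1)/(nir/r+1)",
  NDRE   = "(nir-re)/(nir+re)",
  NDVI   = "(nir-r)/(nir+r)",
  RDVI   = "(nir-r)/sqrt(nir+r)",
  OSAVI  = "1.16*(nir-r)/(nir+r+0.16)",
  RVI    = "nir/r"
)

# registry variants beyond the 21 presets
.PRESET_EXTRA <- list(
  MSAVI_std = "(nir*2+1-sqrt((nir*2+1)^2-8*(nir-r)))/2"
)

.build_registry <- function() {
  reg <- new.env(parent = emptyenv())
  for (nm in names(.PRESET_RGB)) {
    f <- parse_formula(nm, .PRESET_RGB[[nm]])
    assign(paste0(nm, ":RGB"), f, envir = reg)
    assign(paste0(nm, ":MS"), f, envir = reg)
  }
  for (nm in names(.PRESET_MS))
    assign(paste0(nm, ":MS"), parse_formula(nm, .PRESET_MS[[nm]]),
           envir = reg)
  for (nm in names(.PRESET_EXTRA))
    assign(paste0(nm, ":MS"), parse_formula(nm, .PRESET_EXTRA[[nm]]),
           envir = reg)
  reg
}

.preset_registry <- .build_registry()

#' Preset vegetation-index formulas
#'
#' `get_preset()` returns one of the 21 preset index formulas by name and
#' sensor class; indices needing red-edge or near-infrared bands are
#' refused for RGB sensors. `list_presets()` enumerates the registry.
#'
#' Presets (visible-band, RGB or MS): BGI, BRI, CIVE, EXG, EXR, EE, NDI,
#' RGBI, RGBVI, VARI. MS-only: ARI, DVI, GNDVI, MCARI1, MSAVI, MSR, NDRE,
#' NDVI, RDVI, OSAVI, RVI. `MSAVI` carries no final division by two;
#' the conventional form is registered separately as `MSAVI_std` (not
#' counted among the 21 presets).
#'
#' @param name index name, e.g. `"NDVI"`.
#' @param sensor `"RGB"` or `"MS"`.
#' @return a [parse_formula()] object.
#' @examples
#' get_preset("EXG", "RGB")$expression
#' @export
get_preset <- function(name, sensor = c("RGB", "MS")) {
  sensor <- match.arg(sensor)
  key <- paste0(name, ":", sensor)
  if (!exists(key, envir = .preset_registry, inherits = FALSE)) {
    if (sensor == "RGB" &&
        exists(paste0(name, ":MS"), envir = .preset_registry,
               inherits = FALSE))
      stop("index '", name, "' requires nir/re bands (MS sensor)")
    stop("unknown preset index '", name, "' for sensor ", sensor)
  }
  get(key, envir = .preset_registry, inherits = FALSE)
}

#' @rdname get_preset
#' @param include_variants include documented variants such as
#'   `MSAVI_std` beyond the 21 presets.
#' @return for `list_presets()`: data.frame with columns `name`, `sensor`
#'   (the most permissive sensor class) and `expression`.
#' @export
list_presets <- function(include_variants = FALSE) {
  rows <- rbind(
    data.frame(name = names(.PRESET_RGB), sensor = "RGB/MS",
               expression = unlist(.PRESET_RGB), stringsAsFactors = FALSE),
    data.frame(name = names(.PRESET_MS), sensor = "MS",
               expression = unlist(.PRESET_MS), stringsAsFactors = FALSE))
  if (include_variants)
    rows <- rbind(rows, data.frame(
      name = names(.PRESET_EXTRA), sensor = "MS",
      expression = unlist(.PRESET_EXTRA), stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}
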