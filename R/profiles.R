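#' Ordinal staining levels
#'
#' The decision tree works on four ordinal marker levels: Neg (0), Low (1),
#' Med (2) and High (3), obtained by cutting a marker distribution at its
#' first quartile, median and third quartile.
#'
#' @format Named integer vector of length 4.
#' @export
caf_levels <- c(Neg = 0L, Low = 1L, Med = 2L, High = 3L)

#' Marker panels
#'
#' The FACS panel is FAP, CD29, SMA, PDPN and PDGFRB. On tissue sections PDPN
#' has no working IHC antibody and is replaced by FSP1 (both markers stain the
#' same cells by FACS), giving the IHC panel. Tile-level maps use the four
#' markers imaged on serial sections (FAP, CD29, FSP1, SMA).
#'
#' @param panel One of `"FACS"`, `"IHC"`, `"tile"`.
#' @return Character vector of marker names.
#' @export
caf_panel <- function(panel = c("FACS", "IHC", "tile")) {
  panel <- match.arg(panel)
  switch(panel,
    FACS = c("FAP", "CD29", "SMA", "PDPN", "PDGFRB"),
    IHC  = c("FAP", "CD29", "SMA", "FSP1", "PDGFRB"),
    tile = c("FAP", "CD29", "SMA", "FSP1")
  )
}

#' Canonical CAF subset level profiles
#'
#' The four CAF subsets are defined by combinatorial ordinal levels of the
#' marker panel:
#' \itemize{
#'   \item CAF-S1: FAP High, CD29 Med-High, SMA High, PDPN High, PDGFRB High
#'   \item CAF-S2: FAP Neg, CD29 Low, SMA Neg-Low, PDPN Low, PDGFRB Low
#'   \item CAF-S3: FAP Neg-Low, CD29 Med, SMA Neg-Low, PDPN Low, PDGFRB Low-Med
#'   \item CAF-S4: FAP Low-Med, CD29 High, SMA High, PDPN Low, PDGFRB Med
#' }
#' Composite levels ("Med-High") are encoded as admissible-level sets. FSP1
#' inherits PDPN's admissible sets on the IHC/tile panels.
#'
#' @param panel Marker panel, see [caf_panel()].
#' @return Named list (CAF-S1..CAF-S4) of named lists mapping each panel
#'   marker to an integer vector of admissible levels.
#' @examples
#' caf_profiles()[["CAF-S1"]]$FAP  # 3 (High)
#' @export
caf_profiles <- function(panel = c("FACS", "IHC", "tile")) {
  panel <- match.arg(panel)
  base <- list(
    "CAF-S1" = list(FAP = 3L,    CD29 = 2:3, SMA = 3L,   PDPN = 3L, PDGFRB = 3L),
    "CAF-S2" = list(FAP = 0L,    CD29 = 1L,  SMA = 0:1,  PDPN = 1L, PDGFRB = 1L),
    "CAF-S3" = list(FAP = 0:1,   CD29 = 2L,  SMA = 0:1,  PDPN = 1L, PDGFRB = 1:2),
    "CAF-S4" = list(FAP = 1:2,   CD29 = 3L,  SMA = 3L,   PDPN = 1L, PDGFRB = 2L)
  )
  markers <- caf_panel(panel)
  lapply(base, function(p) {
    p$FSP1 <- p$PDPN  # FSP1 stains the same cells as PDPN
    stopifnot(all(markers %in% names(p)))
    p[markers]
  })
}

#' Subset names and map palette
#'
#' Fixed rendering palette for tile maps: CAF-S1 red, CAF-S2 orange, CAF-S3
#' green, CAF-S4 blue, epithelium black.
#'
#' @return Named character vector of hex colours.
#' @export
caf_palette <- function() {
  c("CAF-S1" = "#FF0000", "CAF-S2" = "#FFA500", "CAF-S3" = "#00A000",
    "CAF-S4" = "#0000FF", "epithelium" = "#000000")
}

caf_subsets <- function() paste0("CAF-S", 1:4)

# Tie-break priority when match scores and ordinal distances are equal.
# Reflects the myofibroblast emphasis of the stratification; configurable in
# classify_record().
caf_priority_default <- function() c("CAF-S1", "CAF-S4", "CAF-S3", "CAF-S2")
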