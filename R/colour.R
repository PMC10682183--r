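## Red/white colony-screen colour transform and the binary prion classifier.
##
## In the engineered assay strain, free soluble monomer blocks expression of
## the enzyme that clears a red adenine-pathway intermediate, so cells rich
## in free monomer are red and cells whose monomer is sequestered into
## amyloid are white.

## round half away from zero to the 8-bit channel
round_half_away <- function(x) floor(x + 0.5)

#' Colour of a cell from its free-monomer concentration
#'
#' Gamma transform between white (`C_M <= C_M_min`, RGB 255/255/255) and
#' red (`C_M >= C_M_max`, RGB 255/0/0): with the clipped fraction
#' `x = (C_M - C_M_min) / (C_M_max - C_M_min)`, the green and blue
#' channels are `round(255 * (1 - x^gamma))` (rounding half away from
#' zero) and the red channel is always 255.  `gamma = 1` is an affine
#' map; `gamma > 1` and `gamma < 1` bend the response either side of it.
#'
#' @param C_M free monomer concentration (M); vectorised.
#' @param params a [colour_params()].
#' @return a tibble with integer columns `R`, `G`, `B`.
#' @export
colour_of <- function(C_M, params) {
  x <- (C_M - params$C_M_min) / (params$C_M_max - params$C_M_min)
  x <- pmin(pmax(x, 0), 1)
  g <- as.integer(round_half_away(255 * (1 - x^params$gamma)))
  g[C_M >= params$C_M_max] <- 0L
  tibble::tibble(R = rep(255L, length(g)), G = g, B = g)
}

#' Binary prion classification
#'
#' Applies the configured marker/threshold classifier to each cell of a
#' census table.  Amyloid markers (`C_MA1`, `N_A1`, `C_MA2`, `N_A2`)
#' classify a cell prion-positive when the marker is at or above the
#' threshold; the `C_M` marker classifies prion-positive when the free
#' monomer falls *below* the threshold, since prion-containing cells
#' sequester their monomer into amyloid.
#'
#' @param census a census tibble (see [colony_census()]) or any data
#'   frame carrying the marker column.
#' @param params a [colour_params()].
#' @return logical vector, `TRUE` for prion-positive.
#' @export
classify_prion <- function(census, params) {
  m <- params$marker
  if (!m %in% COLOUR_MARKERS) {
    stop("unknown marker '", m, "'; valid markers: ",
         paste(COLOUR_MARKERS, collapse = ", "))
  }
  if (!m %in% names(census)) stop("census lacks marker column '", m, "'")
  v <- census[[m]]
  if (m == "C_M") v < params$classifier_threshold
  else v >= params$classifier_threshold
}
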