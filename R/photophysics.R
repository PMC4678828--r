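#' Photophysical rendering table
#'
#' Describes how each occupancy state emits into the donor and acceptor
#' camera channels, in units of the unbound donor intensity (normalized to
#' 1). Five render states are distinguished:
#'
#' * `S1`: unbound DNA. Donor fully bright; the apparent FRET of ~0.1 is
#'   modelled as donor crosstalk into the acceptor channel, so
#'   `I_D = 1` and `I_A = E/(1-E)`.
#' * `S2a`: one monomer bound away from the donor dye. True FRET at
#'   `E = 0.85`, total intensity unchanged.
#' * `S2b`: one monomer bound next to the donor dye: same FRET level but a
#'   2-fold PIFE enhancement of total brightness.
#' * `S3`: two monomers bound sequentially; the adjacent identically
#'   labelled acceptors self-quench (acceptor dark) while the donor keeps
#'   the 2-fold PIFE enhancement.
#' * `S4`: ssDNA coated in a single observed step; same signature as `S3`.
#'
#' A newly bound first monomer is PIFE-proximal (`S2b`) with probability
#' `p_near`, drawn once per binding event. Photobleaching is exponential:
#' the donor clock runs from trace start at `donor_bleach`; the acceptor
#' clock restarts at every binding event (each arriving protein carries a
#' fresh dye) at `acceptor_bleach`. Camera noise is additive Gaussian per
#' channel with standard deviation `noise_sigma` (fraction of the unbound
#' donor intensity).
#'
#' @param fret Named per-state FRET efficiencies in `[0, 1]`.
#' @param pife Named per-state donor quantum-yield multipliers (>= 1).
#' @param acceptor_dark Named logicals: acceptor forced to background.
#' @param crosstalk Named logicals: treat `fret` as donor crosstalk (donor
#'   stays at full brightness) rather than true transfer.
#' @param p_near Probability a binding event is PIFE-proximal (`S2b`).
#' @param donor_bleach,acceptor_bleach Bleach rates (s^-1); 0 disables.
#' @param noise_sigma Additive Gaussian noise sd per channel (fraction of
#'   unbound donor intensity).
#' @param background Length-2 numeric, additive background per channel
#'   (donor, acceptor).
#' @param brightness Global brightness scale applied to both channels
#'   (before background).
#'
#' @return An object of class `photophysics`: a list with an `emission`
#'   tibble (columns `state`, `donor`, `acceptor`) and the scalar fields.
#' @examples
#' phys <- photophysics()
#' phys$emission
#' @export
photophysics <- function(fret = c(S1 = 0.1, S2a = 0.85, S2b = 0.85,
                                  S3 = 0, S4 = 0),
                         pife = c(S1 = 1, S2a = 1, S2b = 2, S3 = 2, S4 = 2),
                         acceptor_dark = c(S1 = FALSE, S2a = FALSE,
                                           S2b = FALSE, S3 = TRUE,
                                           S4 = TRUE),
                         crosstalk = c(S1 = TRUE, S2a = FALSE, S2b = FALSE,
                                       S3 = FALSE, S4 = FALSE),
                         p_near = 0.5,
                         donor_bleach = 0.018,
                         acceptor_bleach = 0.07,
                         noise_sigma = 0.1,
                         background = c(donor = 0, acceptor = 0),
                         brightness = 1) {
  st <- render_states
  for (v in list(fret, pife, acceptor_dark, crosstalk)) {
    if (!all(st %in% names(v))) {
      abort("Per-state fields must be named vectors covering S1, S2a, S2b, S3, S4.")
    }
  }
  fret <- fret[st]; pife <- pife[st]
  acceptor_dark <- acceptor_dark[st]; crosstalk <- crosstalk[st]
  if (any(fret < 0 | fret > 1)) abort("FRET efficiencies must lie in [0, 1].")
  if (any(pife < 1)) abort("PIFE factors must be >= 1.")
  if (p_near < 0 || p_near > 1) abort("`p_near` must lie in [0, 1].")
  if (donor_bleach < 0 || acceptor_bleach < 0) {
    abort("Bleach rates must be >= 0.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (brightness <= 0) abort("`brightness` must be > 0.")
  if (length(background) != 2) abort("`background` must have two entries.")

  donor <- ifelse(crosstalk | acceptor_dark, pife, pife * (1 - fret))
  acceptor <- ifelse(acceptor_dark, 0,
                     ifelse(crosstalk, pife * fret / (1 - fret), pife * fret))
  structure(
    list(
      emission = tibble(state = st, fret = unname(fret),
                        pife = unname(pife),
                        acceptor_dark = unname(acceptor_dark),
                        donor = unname(donor), acceptor = unname(acceptor)),
      p_near = p_near,
      donor_bleach = donor_bleach,
      acceptor_bleach = acceptor_bleach,
      noise_sigma = noise_sigma,
      background = unname(background),
      brightness = brightness
    ),
    class = "photophysics"
  )
}

render_states <- c("S1", "S2a", "S2b", "S3", "S4")

#' @export
print.photophysics <- function(x, ...) {
  cat("<photophysics>\n")
  print(x$emission)
  cat(sprintf("  p_near = %g; bleach D/A = %g / %g s^-1; noise sd = %g; brightness = %g\n",
              x$p_near, x$donor_bleach, x$acceptor_bleach, x$noise_sigma,
              x$brightness))
  invisible(x)
}
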