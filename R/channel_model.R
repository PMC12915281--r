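#' Detection channel model
#'
#' Gains, offsets, noise, spectral bleed-through, vignetting and signal
#' polarity for the four detection channels (cfp, yfp, vm, ca). Bleed-through
#' is a 4 x 4 matrix of linear mixing fractions: entry `[i, j]` is the
#' fraction of source channel `i`'s clean signal added into detected channel
#' `j` (diagonal 1; mixing is applied before noise). Vignetting is a radial
#' cosine falloff reaching `1 - vignette_strength` at the mask-edge radius,
#' emulating weaker edge signal from cardiac curvature. `vm_polarity` is the
#' sign of the Vm fluorescence deflection on depolarization (RH237-like dyes
#' deflect negatively; default -1). `depth` is the fractional modulation of
#' the resting fluorescence by a full-amplitude deflection; the default
#' noise SD on the mapping channels is 5% of the resulting deflection
#' amplitude (`gain * depth`).
#'
#' @param gain Counts per unit resting signal, named per channel.
#' @param offset Dark offset in counts (scalar or per channel).
#' @param noise_sd Additive Gaussian noise SD in counts, per channel.
#' @param bleedthrough 4 x 4 mixing matrix with dimnames in channel order
#'   `c("cfp","yfp","vm","ca")`; diagonal must be 1, off-diagonal in
#'   `[0, 0.5]`. Default: identity except a 0.05 Ca -> Vm fraction.
#' @param vignette_strength Radial attenuation at the mask edge, in `[0, 1]`.
#' @param vm_polarity +1 or -1.
#' @param depth Modulation depth for the vm and ca channels; 0 emulates an
#'   unloaded dye (channel carries only offset, bleed-through and noise).
#' @param quantize Round frames to integer counts (16-bit camera
#'   quantization). Disable for continuous-valued oracle comparisons.
#' @param fret_a,fret_b FRET transduction exponents: CFP responds as
#'   `dFRET^a` and YFP as `dFRET^-b`, so CFP rises and YFP falls as cAMP
#'   rises; with `a + b = 1` the CFP/YFP ratio equals dFRET exactly.
#' @return A `channel_model` object.
#' @export
channel_model <- function(gain = c(cfp = 2000, yfp = 2000, vm = 2000, ca = 2000),
                          offset = 100,
                          noise_sd = c(cfp = 10, yfp = 10, vm = 30, ca = 30),
                          bleedthrough = NULL,
                          vignette_strength = 0.3,
                          vm_polarity = -1,
                          depth = c(vm = 0.3, ca = 0.3),
                          fret_a = 0.5, fret_b = 0.5, quantize = TRUE) {
  ch <- c("cfp", "yfp", "vm", "ca")
  gain <- fill_by_channel(gain, ch, "gain")
  offset <- fill_by_channel(offset, ch, "offset")
  noise_sd <- fill_by_channel(noise_sd, ch, "noise_sd")
  if (is.null(bleedthrough)) {
    bleedthrough <- diag(4)
    dimnames(bleedthrough) <- list(ch, ch)
    bleedthrough["ca", "vm"] <- 0.05
  }
  if (!all(dim(bleedthrough) == c(4, 4)))
    config_error("bleedthrough must be a 4 x 4 matrix")
  if (is.null(dimnames(bleedthrough)))
    dimnames(bleedthrough) <- list(ch, ch)
  if (any(diag(bleedthrough) != 1))
    config_error("bleedthrough diagonal must be 1")
  off <- bleedthrough[row(bleedthrough) != col(bleedthrough)]
  if (any(off < 0 | off > 0.5))
    config_error("off-diagonal bleedthrough fractions must lie in [0, 0.5]")
  if (any(gain <= 0)) config_error("gains must be positive")
  if (any(noise_sd < 0)) config_error("noise_sd must be non-negative")
  if (vignette_strength < 0 || vignette_strength > 1)
    config_error("vignette_strength must lie in [0, 1]")
  if (!vm_polarity %in% c(-1, 1))
    config_error("vm_polarity must be +1 or -1")
  depth <- fill_by_channel(depth, c("vm", "ca"), "depth")
  if (any(depth < 0) || any(depth > 1))
    config_error("modulation depth must lie in [0, 1]")
  if (fret_a <= 0 || fret_b <= 0)
    config_error("FRET transduction exponents must be positive")
  structure(list(gain = gain, offset = offset, noise_sd = noise_sd,
                 bleedthrough = bleedthrough,
                 vignette_strength = vignette_strength,
                 vm_polarity = vm_polarity, depth = depth,
                 fret_a = fret_a, fret_b = fret_b,
                 quantize = isTRUE(quantize)),
            class = "channel_model")
}

fill_by_channel <- function(x, ch, what) {
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(ch)), ch))
  if (is.null(names(x)) && length(x) == length(ch))
    return(stats::setNames(as.numeric(x), ch))
  if (!all(ch %in% names(x)))
    config_error(sprintf("%s must name all of: %s", what,
                         paste(ch, collapse = ", ")))
  stats::setNames(as.numeric(x[ch]), ch)
}

# Radial cosine vignetting field over the grid: 1 at the mask centroid,
# 1 - strength at the most distant mask pixel.
vignette_field <- function(mask, strength) {
  rows <- nrow(mask); cols <- ncol(mask)
  if (strength == 0) return(matrix(1, rows, cols))
  rgrid <- matrix(seq_len(rows), rows, cols)
  cgrid <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  r0 <- mean(rgrid[mask]); c0 <- mean(cgrid[mask])
  r <- sqrt((rgrid - r0)^2 + (cgrid - c0)^2)
  rmax <- max(r[mask])
  1 - strength * (1 - cos(pi / 2 * pmin(r / rmax, 1)))
}
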