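#' Differential absorbance between two optical paths
#'
#' For two paths sharing the same source, the difference of decadic
#' absorbances cancels the incident intensity and reduces to
#' `dA = log10(i_ref / i_attenuated)`: the extra attenuation accumulated
#' along the longer path. With the near-reflection intensity as reference,
#' `dA >= 0` whenever the reference is at least as bright.
#'
#' @param i_ref Reference (brighter, shorter-path) intensity; > 0.
#' @param i_attenuated Attenuated (longer-path) intensity; > 0.
#' @return Absorbance difference (dimensionless, decadic). Vectorised.
#' @examples
#' differential_absorbance(1000, 100)  # = 1
#' @export
differential_absorbance <- function(i_ref, i_attenuated) {
  if (any(!is.finite(i_ref)) || any(!is.finite(i_attenuated)) ||
      any(i_ref <= 0) || any(i_attenuated <= 0)) {
    stop_nibgm("intensities must be finite and strictly positive",
               "nibgm_domain_error")
  }
  log10(i_ref / i_attenuated)
}

#' Compute the six differential absorbances of a record
#'
#' For each wavelength, the representative intensity of each DC channel is
#' the arithmetic mean over that wavelength's stable segment; the two
#' differential absorbances (near vs far reflection, near reflection vs
#' transmission) are then computed per wavelength. The six values are
#' returned in the fixed feature-vector order:
#' `da_nf_625, da_nt_625, da_nf_850, da_nt_850, da_nf_940, da_nt_940`.
#'
#' @param record A [device_record].
#' @param guard_s Guard band for stable-segment selection, seconds.
#' @return An object of class `absorbance_set`: named numeric vector of
#'   length 6.
#' @examples
#' rec <- generate_device_record(6, synth_config(seed = 4))
#' compute_absorbance_set(rec)
#' @export
compute_absorbance_set <- function(record, guard_s = 1.0) {
  segments <- extract_stable_segments(record, guard_s)
  out <- numeric(0)
  for (lam in as.character(WAVELENGTHS)) {
    seg <- segments[[lam]]
    if (is.null(seg)) {
      stop_nibgm(sprintf("record has no %s nm phase", lam),
                 "nibgm_segmentation_error")
    }
    idx <- seg$start:seg$end
    i_near <- mean(record$pd1_dc[idx])
    i_far <- mean(record$pd2_dc[idx])
    i_trans <- mean(record$pd3_dc[idx])
    out <- c(out,
             differential_absorbance(i_near, i_far),
             differential_absorbance(i_near, i_trans))
  }
  names(out) <- ABSORBANCE_NAMES
  class(out) <- c("absorbance_set", "numeric")
  out
}

#' @export
print.absorbance_set <- function(x, ...) {
  cat("Differential absorbances (decadic):\n")
  print(round(unclass(x), 6))
  invisible(x)
}
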