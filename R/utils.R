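# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' @importFrom stats approx rnorm runif sd var spline dgamma cor
#' @importFrom utils read.csv
NULL

# Conversion factor between mmol/L and mg/dL (molecular weight of glucose).
MGDL_PER_MMOL <- 18.016

# Names of the 12 entries of the optical feature vector, in the fixed order
# used throughout the package: six PPG features then the six differential
# absorbances (near-far then near-trans, per wavelength 625/850/940 nm).
FEATURE_NAMES <- c(
  "hr_mu", "hr_sigma", "kte_mu", "kte_sigma", "loge_mu", "loge_sigma",
  "da_nf_625", "da_nt_625", "da_nf_850", "da_nt_850", "da_nf_940", "da_nt_940"
)

PPG_FEATURE_NAMES <- FEATURE_NAMES[1:6]
ABSORBANCE_NAMES <- FEATURE_NAMES[7:12]

# Classed conditions so callers can distinguish configuration, format,
# preprocessing, feature and model errors programmatically.
stop_nibgm <- function(msg, class) {
  stop(structure(
    class = c(class, "nibgm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop_nibgm(sprintf("`%s` must be a single integer >= 1", name),
               "nibgm_config_error")
  }
  as.integer(x)
}
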