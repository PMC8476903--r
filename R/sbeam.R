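#' Construct the ground-truth beam-angle ranking score
#'
#' Builds the 360-element ranking vector over gantry angles 0..359 deg at
#' 1 deg steps. Each clinical angle is assigned score 1.0 and the one-hot
#' profile is spread by a circular Gaussian so nearby angles receive partial
#' credit; the Gaussian is peak-normalized, keeping every clinical angle at
#' exactly 1.0 and the whole vector inside \[0, 1\]. Overlapping peaks are
#' combined by the pointwise maximum.
#'
#' @param clinical_angles gantry angles in degrees, each in \[0, 360); may be
#'   empty (returns all zeros). Angles are rounded to the nearest degree and
#'   duplicates collapsed.
#' @param sigma Gaussian width in degrees (> 0); default 5.
#' @return numeric vector of length 360, scores for angles 0..359.
#' @export
make_sbeam <- function(clinical_angles, sigma = 5) {
  if (sigma <= 0) stop("sigma must be > 0")
  s <- numeric(360)
  if (!length(clinical_angles)) return(s)
  ang <- as.numeric(clinical_angles)
  if (any(ang < 0) || any(ang >= 360))
    stop("clinical angles must lie in [0, 360)")
  peaks <- unique(round(ang) %% 360)
  grid <- 0:359
  for (p in peaks) {
    d <- circ_dist(grid, p)
    s <- pmax(s, exp(-d^2 / (2 * sigma^2)))
  }
  s
}

#' Circularly shift a ranking vector (1D translation augmentation)
#'
#' Training-time augmentation: translates the reference ranking score by an
#' integer number of degrees, drawn uniformly from -2..2 when not supplied,
#' with circular wrap-around. A shift of +k moves a peak at angle a to
#' angle a + k (mod 360).
#'
#' @param sbeam numeric vector of length 360.
#' @param shift integer shift in degrees; if `NULL` (default) drawn uniformly
#'   from {-2, -1, 0, 1, 2} using the current RNG stream.
#' @return shifted numeric vector of length 360 (attribute `"shift"` records
#'   the shift applied).
#' @export
augment_sbeam <- function(sbeam, shift = NULL) {
  stopifnot(length(sbeam) == 360)
  if (is.null(shift))
    shift <- sample(-2:2, 1)
  k <- as.integer(shift)
  out <- sbeam[((0:359 - k) %% 360) + 1]
  attr(out, "shift") <- k
  out
}
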